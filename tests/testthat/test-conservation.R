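test_that("Jaccard records follow the category rules", {
  r <- jaccard_conservation(c("Twi_TP1", "Tin_TP1"), "Twi_TP1")
  expect_equal(r$J, 0.5)
  expect_equal(r$category, "strong")

  a <- c("Twi_TP1", "Mef2_TP3", "Bin_TP4")
  r2 <- jaccard_conservation(a, a)
  expect_equal(r2$J, 1.0)
  expect_equal(r2$category, "strong")

  # one event in each species is excluded regardless of match
  r3 <- jaccard_conservation("Twi_TP1", "Twi_TP1")
  expect_equal(r3$category, "excluded_singleton")
  expect_true(r3$singleton_match)
  r4 <- jaccard_conservation("Twi_TP1", "Tin_TP2")
  expect_equal(r4$category, "excluded_singleton")
  expect_false(r4$singleton_match)

  expect_error(jaccard_conservation(character(0), character(0)),
               "empty")
})

test_that("Jaccard equals brute-force set arithmetic on 500 random pairs", {
  withr::local_seed(33)
  conds <- default_condition_set()$condition
  for (i in 1:500) {
    a <- sample(conds, sample.int(14, 1))
    b <- sample(conds, sample.int(14, 1))
    r <- jaccard_conservation(a, b)
    expect_equal(r$J, sum(!is.na(match(a, b))) /
                   length(unique(c(a, b))))
  }
})

test_that("categories partition the pair set and zero divergence is strong", {
  sim <- small_sim(seed = 4, n = 120,
                   substitution_rate = 0, indel_rate = 0,
                   motif_loss_prob = 0, noise_sd = 0)
  cat <- sim$truth$category
  expect_equal(sum(cat %in% c("strong", "intermediate", "none",
                              "excluded_singleton")), length(cat))
  expect_true(all(cat %in% c("strong", "excluded_singleton")))

  # J symmetric in species
  r1 <- jaccard_conservation(c("a", "b"), c("b", "c"))
  r2 <- jaccard_conservation(c("b", "c"), c("a", "b"))
  expect_equal(r1$J, r2$J)
})

test_that("complexity association reduces to textbook chi-square", {
  # hand-built 2x2: categories x (1 event vs 2+ events)
  rec <- data.frame(
    category = rep(c("strong", "none"), c(100, 100)),
    n_events_a = c(rep(1, 30), rep(2, 70), rep(1, 60), rep(2, 40)))
  out <- complexity_association(rec, max_bin = 2L)
  tab <- matrix(c(60, 40, 30, 70), 2, byrow = TRUE)
  expect_equal(out$p, stats::chisq.test(tab)$p.value)
  expect_equal(out$statistic, unname(stats::chisq.test(tab)$statistic))

  # identical distributions: p ~ 1
  rec2 <- data.frame(category = rep(c("strong", "none"), each = 100),
                     n_events_a = rep(rep(1:4, 25), 2))
  out2 <- complexity_association(rec2)
  expect_gt(out2$p, 0.99)

  # extreme separation: p < 1e-10
  rec3 <- data.frame(category = rep(c("strong", "none"), each = 200),
                     n_events_a = rep(c(5, 1), each = 200))
  out3 <- complexity_association(rec3)
  expect_lt(out3$p, 1e-10)

  # sparse table falls back to the exact test with a warning
  rec4 <- data.frame(category = rep(c("strong", "none"), c(4, 4)),
                     n_events_a = c(1, 1, 2, 3, 1, 2, 2, 5))
  expect_warning(out4 <- complexity_association(rec4), "expected cell")
  expect_equal(out4$method, "fisher")
})

test_that("activity enrichment matches the hypergeometric oracle", {
  # balanced table: OR = 1, p = 1
  rec <- data.frame(category = rep(c("strong", "none"), each = 20))
  act <- rep(c("mesoderm", "other"), 20)
  out <- activity_enrichment(rec, act, categories = c("strong", "none"))
  expect_equal(out$per_category$p, c(1, 1))
  expect_equal(out$per_category$odds_ratio, c(1, 1), tolerance = 1e-6)

  # Fisher p equals the hypergeometric tail sum on [[8,2],[1,9]]
  tab <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  # enumeration: P(X = k) for k in 0..10 with margins fixed
  ps <- vapply(0:10, function(k)
    stats::dhyper(k, 10, 10, 9), 0)
  p_oracle <- sum(ps[ps <= stats::dhyper(8, 10, 10, 9) + 1e-12])
  expect_equal(stats::fisher.test(tab)$p.value, p_oracle)

  # planted preference on strong CRMs: strong OR above none OR
  sim <- small_sim(seed = 14, n = 500)
  rec2 <- data.frame(category = sim$truth$category)
  out2 <- activity_enrichment(rec2, sim$activity$label)
  or <- setNames(out2$per_category$haldane_or, out2$per_category$category)
  expect_gt(or["strong"], or["none"])
})

test_that("conservation profile does the stated arithmetic", {
  crms <- data.frame(id = c("p1", "p2"), chrom = "c",
                     start = c(100, 500), end = c(140, 540))
  rec <- data.frame(pair_id = c("p1|x", "p2|y"), id_a = c("p1", "p2"),
                    category = "strong")
  # constant track: flat profile, SE 0
  track <- data.frame(chrom = "c", pos = 0:1000, score = 0.5)
  pr <- conservation_profile(rec, crms, track, flank = 10,
                             categories = "strong")
  expect_true(all(pr$mean == 0.5))
  expect_true(all(pr$se == 0))

  # scores 0 and 1: mean 0.5, SE = sd/sqrt(2) = 0.5
  track2 <- track
  track2$score <- ifelse(track2$pos < 300, 0, 1)
  pr2 <- conservation_profile(rec, crms, track2, flank = 5,
                              categories = "strong")
  expect_true(all(pr2$mean == 0.5))
  expect_true(all(abs(pr2$se - 0.5 / sqrt(2) * sqrt(2)) < 1e-9))
  expect_true(all(pr2$n == 2))

  # missing positions drop out of the denominator
  track3 <- track[track$pos < 130, ]
  pr3 <- conservation_profile(rec, crms, track3, flank = 5,
                              categories = "strong")
  expect_true(all(pr3$n == 1))

  # planted effect: strong curve above none curve at the center
  sim <- small_sim(seed = 6, n = 200)
  recs <- data.frame(pair_id = sim$truth$crms1$id,
                     id_a = sim$truth$crms1$id,
                     category = sim$truth$category)
  prof <- conservation_profile(recs, sim$truth$crms1,
                               sim$conservation_track, flank = 50)
  ctr <- prof[prof$offset == 0, ]
  expect_gt(ctr$mean[ctr$category == "strong"],
            ctr$mean[ctr$category == "none"])
})

test_that("signal clustering merges identical rows first and is stable", {
  withr::local_seed(5)
  base <- rnorm(28)
  x <- rbind(r1 = base, r2 = base,
             r3 = rnorm(28), r4 = rnorm(28), r5 = rnorm(28))
  a <- x[, 1:14]; b <- x[, 15:28]
  colnames(a) <- paste0("c", 1:14); colnames(b) <- paste0("c", 1:14)
  cl <- cluster_signal(a, b)
  m1 <- cl$hclust$merge[1, ]
  expect_equal(sort(rownames(x)[-m1]), c("r1", "r2"))
  expect_equal(cl$hclust$height[1], 0)

  # permuting input row order gives the same tree topology
  perm <- c(3, 1, 5, 2, 4)
  cl2 <- cluster_signal(a[perm, ], b[perm, ])
  d1 <- stats::cophenetic(cl1 <- cl$hclust)
  d2 <- stats::cophenetic(cl2$hclust)
  ids <- rownames(x)
  expect_equal(as.matrix(d1)[ids, ids], as.matrix(d2)[ids, ids])

  # three rows with clear-cut correlations merge in the expected order
  t3 <- seq(0, 2 * pi, length.out = 28)
  y <- rbind(s1 = sin(t3), s2 = sin(t3) + rnorm(28, 0, 0.01),
             s3 = cos(t3))
  cl3 <- cluster_signal(y[, 1:14], y[, 15:28])
  expect_equal(sort(cl3$hclust$merge[1, ]), c(-2, -1))

  # zero-variance rows are flagged, distance defined as 1
  z <- rbind(k1 = rep(1, 28), k2 = rnorm(28), k3 = rnorm(28))
  clz <- cluster_signal(z[, 1:14], z[, 15:28])
  expect_equal(clz$flagged, "k1")
  expect_true(grepl("k1", clz$newick))
})

test_that("binding matrix uses summit containment", {
  crms <- data.frame(id = c("c1", "c2"), chrom = "chr", start = c(0, 500),
                     end = c(100, 600))
  pk <- data.frame(chrom = "chr", summit = c(50, 100, 550),
                   condition = c("Twi_TP1", "Twi_TP1", "Tin_TP1"))
  bm <- binding_matrix(crms, pk, c("Twi_TP1", "Tin_TP1"))
  expect_equal(bm["c1", ], c(Twi_TP1 = 1L, Tin_TP1 = 0L))
  expect_equal(bm["c2", ], c(Twi_TP1 = 0L, Tin_TP1 = 1L))
  # summit 100 is outside [0,100)
  expect_equal(sum(bm), 2L)
})
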