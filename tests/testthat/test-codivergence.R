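random_binding_matrix <- function(n = 500, k = 10, density = 0.2,
                                  seed = 1) {
  crmdiverge:::with_seed(seed, {
    m <- matrix(rbinom(n * k, 1L, density), n, k,
                dimnames = list(paste0("r", 1:n), paste0("c", 1:k)))
    m
  })
}

test_that("permutation null preserves margins in every sample", {
  m <- random_binding_matrix(200, 6, 0.25, seed = 2)
  nm <- vegan::nullmodel(m, "curveball")
  sims <- stats::simulate(nm, nsim = 25, seed = 9, burnin = 2000,
                          thin = 200)
  for (i in seq_len(dim(sims)[3])) {
    expect_identical(rowSums(sims[, , i]), rowSums(m))
    expect_identical(colSums(sims[, , i]), colSums(m))
  }
})

test_that("co-association z-scores flag dependence with the right sign", {
  withr::local_seed(5)
  n <- 500
  base <- rbinom(n, 1, 0.2)
  m <- cbind(a = base, b = base,                      # identical columns
             c = rbinom(n, 1, 0.5),
             d = NA, e = rbinom(n, 1, 0.3))
  m[, "d"] <- 1L - m[, "c"]                           # mutually exclusive
  storage.mode(m) <- "integer"
  rownames(m) <- paste0("r", 1:n)
  cz <- coassociation_zscores(m, n_perm = 200, seed = 4)
  expect_gt(cz$z["a", "b"], 3)
  expect_lt(cz$z["c", "d"], -3)
  expect_true(isSymmetric(cz$z))

  # determinism
  cz2 <- coassociation_zscores(m, n_perm = 200, seed = 4)
  expect_identical(cz$z, cz2$z)

  # invariance under row shuffling of the input
  perm <- sample(n)
  cz3 <- coassociation_zscores(m[perm, ], n_perm = 200, seed = 4)
  expect_equal(cz3$obs, cz$obs)

  # degenerate columns are flagged with undefined z
  m2 <- cbind(m, f = rep(1L, n))
  czf <- coassociation_zscores(m2, n_perm = 50, seed = 4)
  expect_true("f" %in% czf$flagged)

  expect_error(coassociation_zscores(m, n_perm = 1), "n_perm")
  expect_error(coassociation_zscores(matrix(2, 3, 3)), "binary")
})

test_that("co-divergence table counts, expectation and symmetry", {
  # construct matrices realizing counts (25, 25, 25, 25)
  n <- 100
  tfa <- cbind(Twi = rep(TRUE, n), Tin = rep(TRUE, n),
               Mef2 = rep(FALSE, n))
  tfb <- cbind(Twi = rep(c(TRUE, FALSE, TRUE, FALSE), each = 25),
               Tin = rep(c(TRUE, TRUE, FALSE, FALSE), each = 25),
               Mef2 = rep(FALSE, n))
  rownames(tfa) <- rownames(tfb) <- paste0("p", 1:n)
  row <- codivergence_table(tfa, tfb, "Twi", "Tin")
  expect_equal(row$S12, 100)
  expect_equal(c(row$n_both_conserved, row$n_tf1_lost, row$n_tf2_lost,
                 row$n_both_lost), c(25, 25, 25, 25))
  expect_equal(row$P1, 0.5)
  expect_equal(row$P2, 0.5)
  expect_equal(row$expected_both_lost, 100 * 0.5 * 0.5)
  # counts sum to S12 and expectation is bounded by S12
  expect_equal(row$n_both_conserved + row$n_tf1_lost + row$n_tf2_lost +
                 row$n_both_lost, row$S12)
  expect_lte(row$expected_both_lost, row$S12)
  # independence-shaped table: observed equals expected, p large
  expect_equal(row$n_both_lost, row$expected_both_lost)
  expect_gt(row$fisher_p, 0.9)

  # dependence: both-lost doubled
  tfb2 <- tfb
  tfb2[26:50, "Twi"] <- TRUE                 # remove tf1-only losses
  tfb2[26:50, "Tin"] <- TRUE
  tfb2[1:13, c("Twi", "Tin")] <- FALSE       # add joint losses
  row2 <- codivergence_table(tfa, tfb2, "Twi", "Tin")
  expect_gt(row2$n_both_lost, row2$expected_both_lost)
  expect_lt(row2$fisher_p, 0.05)
  # Fisher p equals enumeration oracle on the same 2x2
  tab <- matrix(c(row2$n_both_conserved, row2$n_tf2_lost,
                  row2$n_tf1_lost, row2$n_both_lost), 2, byrow = TRUE)
  mm <- sum(tab[1, ]); nn <- sum(tab[2, ]); kk <- sum(tab[, 1])
  ps <- stats::dhyper(0:kk, mm, nn, kk)
  obs_p <- stats::dhyper(tab[1, 1], mm, nn, kk)
  expect_equal(row2$fisher_p, sum(ps[ps <= obs_p + 1e-12]))

  # swapping tf1/tf2 transposes counts and keeps p
  rswap <- codivergence_table(tfa, tfb2, "Tin", "Twi")
  expect_equal(rswap$n_tf1_lost, row2$n_tf2_lost)
  expect_equal(rswap$n_tf2_lost, row2$n_tf1_lost)
  expect_equal(rswap$fisher_p, row2$fisher_p)

  # degenerate: all conserved
  tfb3 <- tfa
  row3 <- codivergence_table(tfa, tfb3, "Twi", "Tin")
  expect_equal(row3$P1, 0)
  expect_equal(row3$expected_both_lost, 0)
  expect_equal(row3$fisher_p, 1)

  # empty co-bound set
  row4 <- codivergence_table(tfa, tfb, "Twi", "Mef2")
  expect_equal(row4$S12, 0L)
  expect_true(is.na(row4$fisher_p))
})

test_that("codivergence_all applies BH across populated pairs only", {
  sim <- small_sim(seed = 27, n = 250)
  out <- codivergence_all(sim$truth$tf_bound1, sim$truth$tf_bound2)
  expect_equal(nrow(out), 10L)
  ok <- !is.na(out$fisher_p)
  expect_equal(out$bh_q[ok], p.adjust(out$fisher_p[ok], "BH"))
})

test_that("independence-planted data keeps joint loss near expectation", {
  hits <- vapply(1:40, function(seed) {
    cfg <- sim_config(n_crms = 250, seed = seed,
                      cooperative_rule = list(enabled = FALSE,
                                              min_partners = 3))
    tr <- simulate_two_species(cfg)$truth
    row <- codivergence_table(tr$tf_bound1, tr$tf_bound2, "Twi", "Tin")
    p <- row$P1 * row$P2
    sdv <- sqrt(row$S12 * p * (1 - p))
    abs(row$n_both_lost - row$expected_both_lost) <= 3 * max(sdv, 1)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("occupancy loss vs motif loss association and Haldane OR", {
  withr::local_seed(8)
  n <- 300
  tfa <- cbind(Twi = rep(TRUE, n), Tin = rep(TRUE, n))
  rownames(tfa) <- paste0("p", 1:n)
  # planted rule: Twi binding requires the Tin motif
  motif_lost <- runif(n) < 0.4
  z <- ifelse(motif_lost, 2, -0.5) + rnorm(n, 0, 0.1)
  tfb <- cbind(Twi = !motif_lost | runif(n) < 0.15, Tin = rep(TRUE, n))
  rownames(tfb) <- rownames(tfa)
  out <- binding_loss_vs_motif_loss(tfa, tfb, z, "Twi", "Tin")
  expect_lt(out$fisher_p, 0.01)
  expect_gt(out$odds_ratio, 1)

  # [[10,0],[0,10]]: conditional MLE OR infinite, Haldane ~ 441
  z2 <- rep(c(2, -1), each = 10)
  tfa2 <- cbind(A = rep(TRUE, 20), B = rep(TRUE, 20))
  tfb2 <- cbind(A = rep(c(FALSE, TRUE), each = 10), B = rep(TRUE, 20))
  rownames(tfa2) <- rownames(tfb2) <- paste0("q", 1:20)
  o2 <- binding_loss_vs_motif_loss(tfa2, tfb2, z2, "A", "B")
  expect_equal(o2$odds_ratio, Inf)
  expect_equal(o2$haldane_or, (10.5 * 10.5) / (0.5 * 0.5))
  # two-sided: both extreme tables (all-lost-mlost and none) count
  expect_equal(o2$fisher_p, 2 * stats::dhyper(10, 10, 10, 10))

  # all-ordered-pairs wrapper applies BH
  zm <- cbind(A = z2, B = z2)
  allp <- binding_loss_vs_motif_loss_all(tfa2, tfb2, zm)
  expect_equal(nrow(allp), 2L)
  expect_equal(allp$bh_q, p.adjust(allp$fisher_p, "BH"))
})

test_that("loss vs motif-loss p-values are uniform under independence", {
  withr::local_seed(123)
  n <- 400
  out <- lapply(1:200, function(i) {
    tfa <- cbind(A = rep(TRUE, n), B = rep(TRUE, n))
    tfb <- cbind(A = runif(n) > 0.4, B = rep(TRUE, n))
    rownames(tfa) <- rownames(tfb) <- paste0("p", 1:n)
    z <- rnorm(n)  # motif loss independent of binding loss
    binding_loss_vs_motif_loss(tfa, tfb, z, "A", "B")
  })
  # the exact test is discrete, so its p-values are conservative by
  # construction; the mid-p correction is the calibrated quantity
  mid <- vapply(out, `[[`, 0, "mid_p")
  ks <- suppressWarnings(stats::ks.test(mid, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the raw exact p is never anti-conservative at the 5% level
  expect_lte(mean(vapply(out, `[[`, 0, "fisher_p") < 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("same-time-point co-binding counts the shared-TP subset", {
  conds <- default_condition_set()
  bm <- matrix(0L, 3, nrow(conds),
               dimnames = list(paste0("c", 1:3), conds$condition))
  # c1: Twi and Tin co-bound at the same TP1
  bm["c1", c("Twi_TP1", "Tin_TP1")] <- 1L
  # c2: Twi at TP1, Tin at TP2 only (co-bound, different TPs)
  bm["c2", c("Twi_TP1", "Tin_TP2")] <- 1L
  # c3: Twi only
  bm["c3", "Twi_TP2"] <- 1L
  out <- same_tp_cobinding(bm, conds)
  row <- out[out$tf1 == "Twi" & out$tf2 == "Tin", ]
  expect_equal(row$n_cobound, 2L)
  expect_equal(row$n_same_tp_cobound, 1L)
})
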