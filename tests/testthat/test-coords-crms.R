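test_that("summit clustering follows the gap rule and padding", {
  pk <- data.frame(chrom = "chr2L", summit = c(1000, 1300, 2000),
                   condition = "Twi_TP1")
  cl <- cluster_summits(pk, max_gap = 400, pad = 100)
  expect_equal(nrow(cl$crms), 2L)
  expect_equal(cl$crms$start, c(900, 1900))
  expect_equal(cl$crms$end, c(1400, 2100))

  one <- cluster_summits(data.frame(chrom = "chrX", summit = 500,
                                    condition = "Tin_TP1"))
  expect_equal(one$crms$start, 400)
  expect_equal(one$crms$end, 600)
  expect_equal(one$crms$end - one$crms$start, 200)
})

test_that("clustering equals the O(n^2) transitive closure on random summits", {
  withr::local_seed(42)
  n <- 1000
  pk <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                   summit = sample.int(2e5, n), condition = "x")
  pk <- pk[!duplicated(pk[c("chrom", "summit")]), ]
  cl <- cluster_summits(pk, max_gap = 400, pad = 100)

  # brute-force closure of the <=400 bp relation
  brute <- lapply(split(pk$summit, pk$chrom), function(s) {
    s <- sort(s)
    adj <- abs(outer(s, s, "-")) <= 400
    grp <- seq_along(s)
    repeat {
      new <- vapply(seq_along(s), function(i) min(grp[adj[i, ]]), 0)
      if (identical(new, grp)) break
      grp <- new
    }
    spans <- t(vapply(unique(grp), function(g)
      range(s[grp == g]), c(0, 0)))
    spans[order(spans[, 1]), , drop = FALSE]
  })
  got <- split(cl$crms, cl$crms$chrom)
  for (ch in names(brute)) {
    # per-cluster summit spans must match (before pad-merge; gap 400 with
    # pad 100 cannot merge clusters since 2*pad < gap + 2)
    expect_equal(unname(got[[ch]]$start), unname(brute[[ch]][, 1] - 100))
    expect_equal(unname(got[[ch]]$end), unname(brute[[ch]][, 2] + 100))
  }
})

test_that("clustering is idempotent and validates summits", {
  withr::local_seed(7)
  pk <- data.frame(chrom = "c1", summit = sort(sample.int(5e4, 200)),
                   condition = "x")
  cl1 <- cluster_summits(pk)
  again <- data.frame(chrom = "c1", summit = cl1$members$summit,
                      condition = "x")
  cl2 <- cluster_summits(again)
  expect_equal(cl1$crms[c("start", "end")], cl2$crms[c("start", "end")])

  expect_error(
    cluster_summits(data.frame(chrom = "c1", summit = 100, condition = "x"),
                    chrom_sizes = c(c1 = 50)),
    "outside chromosome")
})

test_that("interval translation matches a per-base brute-force oracle", {
  map <- data.frame(
    src_chrom = "s", src_start = c(0, 150, 400), src_end = c(100, 350, 500),
    tgt_chrom = "t", tgt_start = c(1000, 1150, 2000),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)

  # fully inside one + block: shift by offset
  tr <- translate_interval("s", 10, 60, map)
  expect_equal(tr$mapped_fraction, 1.0)
  expect_equal(tr$intervals$start, 1010)
  expect_equal(tr$intervals$end, 1060)

  # spanning the unaligned gap 100-150 (50 bp deleted in target)
  tr2 <- translate_interval("s", 50, 250, map)
  expect_equal(tr2$mapped_fraction, (200 - 50) / 200)
  expect_equal(nrow(tr2$intervals), 2L)

  # unaligned gap only
  tr3 <- translate_interval("s", 110, 140, map)
  expect_equal(tr3$mapped_fraction, 0)
  expect_equal(nrow(tr3$intervals), 0L)

  # brute-force per-base oracle incl. minus strand
  base_map <- function(p) {
    for (i in seq_len(nrow(map))) {
      if (p >= map$src_start[i] && p < map$src_end[i]) {
        return(if (map$strand[i] == "-")
          map$tgt_start[i] + (map$src_end[i] - 1 - p)
          else map$tgt_start[i] + (p - map$src_start[i]))
      }
    }
    NA_real_
  }
  for (iv in list(c(80, 180), c(390, 460), c(0, 500), c(340, 410))) {
    tr <- translate_interval("s", iv[1], iv[2], map)
    img <- sort(stats::na.omit(vapply(iv[1]:(iv[2] - 1), base_map, 0)))
    got <- sort(unlist(mapply(function(s, e) s:(e - 1),
                              tr$intervals$start, tr$intervals$end)))
    expect_equal(unname(got), unname(img))
    expect_equal(tr$mapped_fraction, length(img) / (iv[2] - iv[1]))
  }
})

test_that("translation is injective on bases and rejects malformed blocks", {
  withr::local_seed(3)
  sim <- small_sim(n = 60)
  map <- sim$block_map
  # no two source bases map to one target base: image sizes add up
  crms <- sim$truth$crms2[1:30, ]
  for (i in seq_len(nrow(crms))) {
    tr <- translate_interval(crms$chrom[i], crms$start[i], crms$end[i], map)
    w <- sum(tr$intervals$end - tr$intervals$start)
    expect_true(w <= crms$end[i] - crms$start[i])
  }
  bad <- map[1:3, ]
  bad$tgt_end <- bad$tgt_start + (bad$src_end - bad$src_start) + 5
  expect_error(validate_block_map(bad), "malformed block")
})

test_that("ortholog pairing keeps only one-to-one components", {
  crms_a <- data.frame(id = c("a1", "a2", "a3"), chrom = "t",
                       start = c(0, 1000, 5000), end = c(300, 1300, 5200))
  # b1 overlaps a1; b2 and b3 both overlap a2 (multi); b4 overlaps nothing
  trans_b <- data.frame(id = c("b1", "b2", "b3", "b4"), tgt_chrom = "t",
                        start = c(100, 900, 1200, 9000),
                        end = c(400, 1100, 1400, 9100),
                        mapped_fraction = 1, unique = TRUE)
  po <- pair_orthologs(crms_a, trans_b)
  expect_equal(po$pairs$id_a, "a1")
  expect_equal(po$pairs$id_b, "b1")
  expect_true(all(c("a2", "b2", "b3") %in% po$multi_clusters$id))
  expect_equal(po$summary$n_pairs, 1L)

  # disjoint CRMs: zero pairs
  po0 <- pair_orthologs(crms_a[3, ], trans_b[4, , drop = FALSE])
  expect_equal(nrow(po0$pairs), 0L)
})

test_that("pairing recovers the synthetic ground-truth one-to-one map", {
  sim <- small_sim(seed = 5, n = 120)
  crms1 <- sim$truth$crms1
  trans <- translate_crms(sim$truth$crms2, sim$block_map)
  po <- pair_orthologs(crms1, trans)
  expect_equal(nrow(po$pairs), nrow(crms1))
  expect_equal(po$pairs$id_a, po$pairs$id_b)  # same generator ids
})

test_that("pairing is symmetric in the species labels", {
  sim <- small_sim(seed = 9, n = 80)
  crms1 <- sim$truth$crms1
  trans <- translate_crms(sim$truth$crms2, sim$block_map)
  po <- pair_orthologs(crms1, trans)
  # swap roles: treat translated species-2 loci as the reference
  crms_b <- data.frame(id = trans$id, chrom = trans$tgt_chrom,
                       start = trans$start, end = trans$end)
  trans_a <- data.frame(id = crms1$id, tgt_chrom = crms1$chrom,
                        start = crms1$start, end = crms1$end,
                        mapped_fraction = 1, unique = TRUE)
  po2 <- pair_orthologs(crms_b, trans_a)
  k1 <- sort(paste(po$pairs$id_a, po$pairs$id_b))
  k2 <- sort(paste(po2$pairs$id_b, po2$pairs$id_a))
  expect_equal(k1, k2)
})

test_that("common-size extension has the stated arithmetic and property", {
  p <- data.frame(id_a = "a", id_b = "b", chrom = "c",
                  start_a = 1000, end_a = 1200, start_b = 5000,
                  end_b = 5300, len_a = 200, len_b = 300,
                  overlap_bp = 10, overlap_frac = 0.05)
  e <- extend_to_common_size(p)
  expect_equal(e$ext_end_a - e$ext_start_a, 500)
  expect_equal(e$ext_end_b - e$ext_start_b, 500)
  expect_equal(e$extended_len_S, 500)
  # centers preserved
  expect_equal((e$ext_start_a + e$ext_end_a) %/% 2, (1000 + 1200) %/% 2)

  # equal inputs of length L become 2L
  p2 <- within(p, { end_b <- 5200; len_b <- 200 })
  e2 <- extend_to_common_size(p2)
  expect_equal(e2$ext_end_a - e2$ext_start_a, 400)

  # property: output lengths always equal S (random pairs, unclipped)
  withr::local_seed(21)
  n <- 1000
  la <- sample(50:400, n, TRUE); lb <- sample(50:400, n, TRUE)
  sa <- sample(2000:9000, n, TRUE); sb <- sample(2000:9000, n, TRUE)
  pr <- data.frame(id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
                   chrom = "c", start_a = sa, end_a = sa + la,
                   start_b = sb, end_b = sb + lb, len_a = la, len_b = lb,
                   overlap_bp = 1, overlap_frac = 0.1)
  er <- extend_to_common_size(pr)
  expect_true(all(er$ext_end_a - er$ext_start_a == la + lb))
  expect_true(all(er$ext_end_b - er$ext_start_b == la + lb))
  # clipping at the chromosome start is flagged
  pc <- within(p, { start_a <- 10; end_a <- 210 })
  ec <- extend_to_common_size(pc)
  expect_true(ec$clipped)
  expect_gte(ec$ext_start_a, 0)
})
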