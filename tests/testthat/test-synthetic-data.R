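test_that("config validation rejects bad inputs", {
  expect_error(sim_config(substitution_rate = 1.5), "outside \\[0,1\\]")
  expect_error(sim_config(n_crms = 0), "n_crms")
  expect_error(sim_config(crm_len_mean = 20), "unplantable")
  expect_error(sim_config(condition_set = default_condition_set()[0, ]),
               "non-empty")
  cfg <- sim_config(n_crms = 5)
  expect_error(plant_cooccurrence(cfg, c("Twi", "NoSuch"), 0.5),
               "tf_set")
  expect_error(plant_cooccurrence(cfg, c("Twi", "Tin"), 1.2),
               "outside \\[0,1\\]")
})

test_that("zero-divergence limit gives identical sequences and strong truth", {
  sim <- small_sim(seed = 3, n = 80, substitution_rate = 0,
                   indel_rate = 0, motif_loss_prob = 0, noise_sd = 0)
  expect_identical(sim$sequences$species1[[1]], sim$sequences$species2[[1]])
  nonsing <- sim$truth$category != "excluded_singleton"
  expect_true(all(sim$truth$category[nonsing] == "strong"))
  # and with J = 1: species-2 binding identical to species-1
  expect_identical(sim$truth$binding1, sim$truth$binding2)
})

test_that("forced loss removes species-2 peaks from the truth", {
  # motif_loss_prob = 1 with rescue off: every binding lost in species 2
  cfg1 <- sim_config(n_crms = 80, seed = 5, motif_loss_prob = 1,
                     cooperative_rule = list(enabled = FALSE,
                                             min_partners = 3))
  sim1 <- simulate_two_species(cfg1)
  expect_false(any(sim1$truth$tf_bound2))
  pk2 <- sim1$peaks[sim1$peaks$species == "species2", ]
  expect_true(is.null(pk2) || nrow(pk2) == 0L)
  # species 1 unaffected
  expect_true(any(sim1$truth$tf_bound1))
})

test_that("identical seeds give byte-identical artifacts", {
  cfg <- sim_config(n_crms = 40, seed = 7)
  s1 <- simulate_two_species(cfg)
  s2 <- simulate_two_species(cfg)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  write_fasta(s1$sequences$species2, file.path(d1, "g.fa"))
  write_fasta(s2$sequences$species2, file.path(d2, "g.fa"))
  write_matrix_tsv(s1$signal$species1, file.path(d1, "sig.tsv"))
  write_matrix_tsv(s2$signal$species1, file.path(d2, "sig.tsv"))
  expect_identical(tools::md5sum(file.path(d1, "g.fa"))[[1]],
                   tools::md5sum(file.path(d2, "g.fa"))[[1]])
  expect_identical(tools::md5sum(file.path(d1, "sig.tsv"))[[1]],
                   tools::md5sum(file.path(d2, "sig.tsv"))[[1]])
  # and a different seed changes them
  s3 <- simulate_two_species(sim_config(n_crms = 40, seed = 8))
  expect_false(identical(s1$sequences$species1, s3$sequences$species1))
})

test_that("substitution count is within 3 binomial SDs of the rate", {
  rate <- 0.2
  sim <- small_sim(seed = 9, n = 100, substitution_rate = rate,
                   indel_rate = 0)
  s1 <- crmdiverge:::seq_to_codes(sim$sequences$species1[[1]])
  s2 <- crmdiverge:::seq_to_codes(sim$sequences$species2[[1]])
  expect_equal(length(s1), length(s2))  # no indels
  # protected (conserved) sites never mutate and lost sites get extra
  # targeted degradation, so the rate applies to non-site bases only
  site_idx <- unlist(mapply(function(s, e) (s + 1L):e,
                            sim$truth$sites$start, sim$truth$sites$end))
  neutral <- setdiff(seq_along(s1), site_idx)
  n_sub <- sum(s1[neutral] != s2[neutral])
  expected <- rate * length(neutral)
  sd3 <- 3 * sqrt(length(neutral) * rate * (1 - rate))
  expect_lt(abs(n_sub - expected), sd3)
})

test_that("the binding caller recovers truth exactly on noiseless signal", {
  sim <- small_sim(seed = 13, n = 100, noise_sd = 0)
  called1 <- call_binding(sim$signal$species1, sim$config)
  called2 <- call_binding(sim$signal$species2, sim$config)
  expect_equal(unname(called1), unname(sim$truth$binding1))
  expect_equal(unname(called2), unname(sim$truth$binding2))
})

test_that("alignment block map exactly records the indel structure", {
  sim <- small_sim(seed = 17, n = 60)
  map <- sim$block_map
  expect_silent(validate_block_map(map))
  # blocks strictly ordered and non-overlapping in both species
  expect_true(all(diff(map$src_start) > 0))
  expect_true(all(map$src_start[-1] >= map$src_end[-nrow(map)]))
  expect_true(all(diff(map$tgt_start) > 0))
  # ungapped: translating any block start recovers the paired coordinate
  s2 <- crmdiverge:::seq_to_codes(sim$sequences$species2[[1]])
  s1 <- crmdiverge:::seq_to_codes(sim$sequences$species1[[1]])
  # block-aligned bases agree up to the substitution process: sample some
  # blocks and check lengths stay inside both sequences
  expect_true(all(map$src_end <= length(s2)))
  expect_true(all(map$tgt_start + (map$src_end - map$src_start) <=
                    length(s1)))
})

test_that("co-loss planting: independence at 0 and excess at 0.5", {
  # with the cooperative rule off and co_loss 0, joint losses match the
  # independence expectation S12 * P1 * P2 on average over seeds
  devs <- vapply(1:50, function(seed) {
    cfg <- sim_config(n_crms = 250, seed = seed,
                      cooperative_rule = list(enabled = FALSE,
                                              min_partners = 3))
    cfg <- plant_cooccurrence(cfg, c("Twi", "Tin"), 0)
    tr <- simulate_two_species(cfg)$truth
    co <- tr$tf_bound1[, "Twi"] & tr$tf_bound1[, "Tin"]
    s12 <- sum(co)
    l1 <- !tr$tf_bound2[co, "Twi"]; l2 <- !tr$tf_bound2[co, "Tin"]
    p1 <- mean(l1); p2 <- mean(l2)
    obs <- sum(l1 & l2); exp_ <- s12 * p1 * p2
    sdv <- sqrt(max(s12 * p1 * p2 * (1 - p1 * p2), 1e-9))
    c(dev = (obs - exp_) / sdv, obs = obs, exp = exp_)
  }, c(0, 0, 0))
  # standardized deviations center on 0 (mean over 50 seeds within 3 SEM)
  expect_lt(abs(mean(devs["dev", ])), 3 / sqrt(50))

  # planted co-loss at 0.5 produces strong detectable dependence
  cfg <- plant_cooccurrence(sim_config(n_crms = 400, seed = 2,
                                       cooperative_rule = list(
                                         enabled = FALSE,
                                         min_partners = 3)),
                            c("Twi", "Tin"), 0.5)
  tr <- simulate_two_species(cfg)$truth
  row <- codivergence_table(tr$tf_bound1, tr$tf_bound2, "Twi", "Tin")
  expect_gt(row$n_both_lost, row$expected_both_lost)
  expect_lt(row$fisher_p, 1e-4)
})

test_that("every true binding event has an intact motif or a rescue", {
  sim <- small_sim(seed = 19, n = 150)
  tr <- sim$truth
  tfs <- colnames(tr$tf_bound2)
  for (j in seq_along(tfs)) {
    b2 <- which(tr$tf_bound2[, j])
    intact <- !tr$lost[b2, j]
    resc <- tr$rescued[b2, j]
    expect_true(all(intact | resc))
  }
})
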