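PIPELINE_STAGES <- c("simulate", "crms", "pair", "conserve", "motifs",
                     "stap", "codiv")

#' Pipeline configuration
#'
#' Bundles the synthetic-benchmark configuration with every stage
#' parameter. One global seed derives per-stage seeds deterministically
#' (see [stage_seed()]), so toggling unrelated stages does not shift a
#' stage's randomness.
#'
#' @param sim a [sim_config()]; its seed is overridden by the derived
#'   per-stage seed.
#' @param seed global integer seed.
#' @param stages stages to run, in dependency order.
#' @param max_gap,pad summit-clustering parameters (bp).
#' @param min_overlap minimum pairing overlap (bp).
#' @param merge_dist unique-translation merge distance (bp).
#' @param n_perm co-association permutations.
#' @param match_pvalue,enrich_p differential-enrichment thresholds.
#' @param motif_loss_cutoff z(dStap) cutoff calling a motif lost.
#' @param tpr_lo,tpr_hi,fpr_max ROC threshold-selection rule bounds.
#' @param top_peaks occupancy-model training peaks per condition.
#' @param dchip_mode "max" (condition with maximal species-1 signal per
#'   CRM) or "mean" across the TF's conditions.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1,
                            stages = PIPELINE_STAGES,
                            max_gap = 400, pad = 100, min_overlap = 1,
                            merge_dist = 1000, n_perm = 500,
                            match_pvalue = 1e-4, enrich_p = 0.05,
                            motif_loss_cutoff = 1.0,
                            tpr_lo = 0.70, tpr_hi = 0.80, fpr_max = 0.40,
                            top_peaks = 1000, dchip_mode = c("max", "mean")) {
  dchip_mode <- match.arg(dchip_mode)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a pipeline_config to validate.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  unknown <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))
  deps <- list(crms = "simulate", pair = "crms", conserve = "pair",
               motifs = "conserve", stap = "motifs", codiv = "stap")
  for (s in config$stages) {
    d <- deps[[s]]
    if (!is.null(d) && !d %in% config$stages)
      stop("stage '", s, "' requires stage '", d, "' to be enabled")
  }
  if (!inherits(config$sim, "sim_config")) stop("sim must be a sim_config")
  invisible(config)
}

match_to_truth <- function(crms, truth_crms) {
  # maximal-overlap assignment of constructed CRMs to generator CRMs
  gr_c <- GenomicRanges::GRanges(crms$chrom,
                                 IRanges::IRanges(crms$start + 1L,
                                                  crms$end))
  gr_t <- GenomicRanges::GRanges(truth_crms$chrom,
                                 IRanges::IRanges(truth_crms$start + 1L,
                                                  truth_crms$end))
  hits <- GenomicRanges::findOverlaps(gr_c, gr_t)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_c)[q],
                                           IRanges::ranges(gr_t)[s]))
  best <- tapply(seq_along(q), q, function(i) s[i][which.max(ov[i])])
  out <- rep(NA_character_, nrow(crms))
  out[as.integer(names(best))] <- truth_crms$id[unlist(best)]
  out
}

write_manifest <- function(outdir, stage, params, seed, inputs, outputs,
                           t0) {
  man <- list(
    stage = stage, params = params, seed = seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = outputs,
    runtime_sec = round(as.numeric(Sys.time()) - t0, 3),
    schema_version = "1.0"
  )
  write_json_report(man, file.path(outdir, paste0("manifest_", stage,
                                                  ".json")))
}

#' Run the full cross-species occupancy-divergence pipeline
#'
#' Executes the enabled stages in dependency order on the synthetic
#' benchmark, writing each stage's TSV/JSON artifacts plus a manifest
#' (parameters, seed, input hashes, runtime) under `outdir`, and returns
#' all in-memory results. Reruns with the same config and seed produce
#' byte-identical numeric artifacts.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return list of stage results (invisible components documented per
#'   stage function).
#' @export
run_pipeline <- function(config, outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  on <- function(s) s %in% config$stages

  ## ---- simulate ------------------------------------------------------
  if (on("simulate")) {
    t0 <- as.numeric(Sys.time())
    scfg <- config$sim
    scfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_two_species(scfg)
    res$sim <- sim
    f <- function(...) file.path(outdir, ...)
    write_fasta(sim$sequences$species1, f("species1.fa"))
    write_fasta(sim$sequences$species2, f("species2.fa"))
    write_narrowpeak(sim$peaks[sim$peaks$species == "species1", ],
                     f("peaks_species1.narrowPeak"))
    write_narrowpeak(sim$peaks[sim$peaks$species == "species2", ],
                     f("peaks_species2.narrowPeak"))
    write_matrix_tsv(sim$signal$species1, f("signal_species1.tsv"))
    write_matrix_tsv(sim$signal$species2, f("signal_species2.tsv"))
    write_block_map(sim$block_map, f("block_map.tsv"))
    utils::write.table(sim$activity, f("activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_json_report(list(
      n_crms = nrow(sim$truth$crms1),
      conditions = sim$config$condition_set$condition,
      category_counts = as.list(table(sim$truth$category)),
      codiv_pair = sim$truth$codiv_pair,
      n_peaks = as.list(table(sim$peaks$species))
    ), f("truth_summary.json"))
    write_manifest(outdir, "simulate",
                   list(n_crms = scfg$n_crms,
                        substitution_rate = scfg$substitution_rate,
                        indel_rate = scfg$indel_rate,
                        motif_loss_prob = scfg$motif_loss_prob),
                   scfg$seed, character(0),
                   c("species1.fa", "species2.fa"), t0)
  }

  ## ---- crms ----------------------------------------------------------
  if (on("crms")) {
    t0 <- as.numeric(Sys.time())
    pk1 <- res$sim$peaks[res$sim$peaks$species == "species1", ]
    pk2 <- res$sim$peaks[res$sim$peaks$species == "species2", ]
    res$crms1 <- cluster_summits(pk1, config$max_gap, config$pad,
                                 id_prefix = "sp1crm")
    res$crms2 <- cluster_summits(pk2, config$max_gap, config$pad,
                                 id_prefix = "sp2crm")
    utils::write.table(res$crms1$crms, file.path(outdir, "crms_species1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$crms2$crms, file.path(outdir, "crms_species2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(outdir, "crms",
                   list(max_gap = config$max_gap, pad = config$pad),
                   NA, file.path(outdir, c("peaks_species1.narrowPeak",
                                           "peaks_species2.narrowPeak")),
                   c("crms_species1.tsv", "crms_species2.tsv"), t0)
  }

  ## ---- pair ----------------------------------------------------------
  if (on("pair")) {
    t0 <- as.numeric(Sys.time())
    trans <- translate_crms(res$crms2$crms, res$sim$block_map,
                            merge_dist = config$merge_dist)
    po <- pair_orthologs(res$crms1$crms, trans,
                         min_overlap = config$min_overlap)
    po$pairs <- extend_to_common_size(po$pairs)
    res$translated <- trans
    res$pairs <- po$pairs
    res$pair_summary <- c(po$summary, list(
      n_crms_b = nrow(res$crms2$crms),
      pct_translated = summarize_fractions(
        length(unique(trans$id)), nrow(res$crms2$crms)),
      pct_uniquely_mapped = summarize_fractions(
        sum(trans$unique[!duplicated(trans$id)]), nrow(res$crms2$crms))
    ))
    res$multi_clusters <- po$multi_clusters
    utils::write.table(res$pairs, file.path(outdir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_report(res$pair_summary, file.path(outdir,
                                                  "pair_summary.json"))
    write_manifest(outdir, "pair",
                   list(min_overlap = config$min_overlap,
                        merge_dist = config$merge_dist),
                   NA, file.path(outdir, c("crms_species1.tsv",
                                           "crms_species2.tsv",
                                           "block_map.tsv")),
                   c("pairs.tsv", "pair_summary.json"), t0)
  }

  ## ---- conserve ------------------------------------------------------
  if (on("conserve")) {
    t0 <- as.numeric(Sys.time())
    conds <- config$sim$condition_set$condition
    pk1 <- res$sim$peaks[res$sim$peaks$species == "species1", ]
    pk2 <- res$sim$peaks[res$sim$peaks$species == "species2", ]
    res$bm1 <- binding_matrix(res$crms1$crms, pk1, conds)
    res$bm2 <- binding_matrix(res$crms2$crms, pk2, conds)
    res$records <- conservation_records(res$pairs, res$bm1, res$bm2)
    # align pairs with records (pairs whose union is empty are dropped)
    res$pairs <- res$pairs[match(res$records$id_a, res$pairs$id_a), ]
    # join constructed CRMs to generator CRMs for signal and activity
    m1 <- match_to_truth(res$crms1$crms, res$sim$truth$crms1)
    names(m1) <- res$crms1$crms$id
    res$truth_of_a <- m1
    tid <- m1[res$records$id_a]
    sig1 <- res$sim$signal$species1[tid, , drop = FALSE]
    sig2 <- res$sim$signal$species2[tid, , drop = FALSE]
    rownames(sig1) <- rownames(sig2) <- res$records$id_a
    res$sig1 <- sig1; res$sig2 <- sig2
    act <- res$sim$activity$label[match(tid, res$sim$activity$id)]
    res$activity <- act
    res$complexity <- complexity_association(res$records)
    res$activity_enrichment <- activity_enrichment(res$records, act)
    res$profile <- conservation_profile(
      res$records, res$crms1$crms,
      res$sim$conservation_track, flank = 300)
    nonsing <- res$records$pair_id[res$records$category !=
                                     "excluded_singleton"]
    res$clustering <- cluster_signal(sig1, sig2,
                                     ids = res$records$id_a[
                                       res$records$pair_id %in% nonsing])
    utils::write.table(res$records, file.path(outdir,
                                              "conservation_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$profile, file.path(outdir,
                                              "conservation_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$clustering$newick, file.path(outdir,
                                                "signal_dendrogram.nwk"))
    write_json_report(list(
      category_counts = as.list(table(res$records$category)),
      pct_singletons = summarize_fractions(
        sum(res$records$category == "excluded_singleton"),
        nrow(res$records)),
      overall_activity_p = res$activity_enrichment$overall_p
    ), file.path(outdir, "conservation_summary.json"))
    write_manifest(outdir, "conserve", list(),
                   NA, file.path(outdir, "pairs.tsv"),
                   c("conservation_records.tsv"), t0)
  }

  ## ---- motifs --------------------------------------------------------
  if (on("motifs")) {
    t0 <- as.numeric(Sys.time())
    seedm <- stage_seed(config$seed, "motifs")
    motifs <- config$sim$motifs[config$sim$tf_set]
    tfs <- config$sim$tf_set
    conds_df <- config$sim$condition_set
    res$thresholds <- list()
    res$density <- list()
    crm_seq1 <- crm_sequences(res$sim$sequences$species1, res$crms1$crms)
    crm_seq2 <- crm_sequences(res$sim$sequences$species2, res$crms2$crms)
    tfb1 <- tf_level_binding(res$bm1, conds_df)
    tfb2 <- tf_level_binding(res$bm2, conds_df)
    for (tf in tfs) {
      cal <- with_seed(stage_seed(seedm, paste0("roc_", tf)), {
        roc_for <- function(crms, members, seqs_chr, bound, conds) {
          b <- crms$id[bound]
          u <- crms$id[!bound]
          sm <- members[members$crm_id %in% b &
                          sub("_TP[0-9]+$", "", members$condition) == tf, ]
          pos <- summit_windows(seqs_chr,
                                crms$chrom[match(sm$crm_id, crms$id)],
                                sm$summit)
          uc <- crms[match(u, crms$id), ]
          rp <- uc$start + vapply(pmax(uc$end - uc$start, 1L),
                                  function(L) sample.int(L, 1L) - 1L, 0L)
          neg <- summit_windows(seqs_chr, uc$chrom, rp)
          calibrate_threshold(motifs[[tf]], pos, neg)
        }
        r1 <- roc_for(res$crms1$crms, res$crms1$members,
                      res$sim$sequences$species1, tfb1[, tf], conds_df)
        r2 <- roc_for(res$crms2$crms, res$crms2$members,
                      res$sim$sequences$species2, tfb2[, tf], conds_df)
        c(list(roc1 = r1, roc2 = r2),
          choose_thresholds(r1, r2, config$tpr_lo, config$tpr_hi,
                            config$fpr_max))
      })
      res$thresholds[[tf]] <- cal
      # species-2 TFBS density by species-1 binding conservation
      hits2 <- scan_pwm(res$sim$sequences$species2[[1L]], motifs[[tf]],
                        min_score = cal$threshold_b,
                        compute_pvalues = FALSE)
      hits2$chrom <- names(res$sim$sequences$species2)[1L]
      # density measured on the species-2 side of each pair
      pair_b <- res$crms2$crms[match(res$records$id_b,
                                     res$crms2$crms$id), ]
      sm2 <- res$crms2$members[
        sub("_TP[0-9]+$", "", res$crms2$members$condition) == tf, ]
      names(sm2)[names(sm2) == "crm_id"] <- "id"
      bound_b <- tfb2[res$records$id_b, tf]
      dens <- tfbs_density(pair_b, hits2, sm2, bound_b,
                           seed = stage_seed(seedm, paste0("dens_", tf)))
      dens$conserved <- tfb1[res$records$id_a, tf] & bound_b
      dens$lost <- tfb1[res$records$id_a, tf] & !bound_b
      dens$class <- as.character(
        complexity_class(rowSums(tfb1[res$records$id_a, , drop = FALSE])))
      res$density[[tf]] <- dens
      res$background_density[[tf]] <- genome_background_density(
        hits2, nchar(res$sim$sequences$species2[[1L]]))
    }
    # temporal classes + differential enrichment on the first TF with >= 2
    # time points (Twi in the default design)
    ttf <- tfs[vapply(tfs, function(tf)
      sum(conds_df$tf == tf) >= 2L, TRUE)][1L]
    sig1_all <- res$sim$signal$species1[
      match_to_truth(res$crms1$crms, res$sim$truth$crms1), , drop = FALSE]
    rownames(sig1_all) <- res$crms1$crms$id
    tc1 <- temporal_classes(res$bm1, sig1_all, ttf, conds_df)
    res$temporal <- tc1
    lib <- config$sim$motifs
    if (length(tc1$early) >= 2L && length(tc1$late) >= 2L) {
      res$enrichment <- differential_enrichment(
        crm_seq1[tc1$early], crm_seq1[tc1$late], lib,
        match_pvalue = config$match_pvalue, enrich_p = config$enrich_p)
      utils::write.table(res$enrichment$table,
                         file.path(outdir, "motif_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    dens_all <- do.call(rbind, lapply(names(res$density), function(tf)
      cbind(tf = tf, res$density[[tf]])))
    utils::write.table(dens_all, file.path(outdir, "tfbs_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_report(lapply(res$thresholds, function(x)
      list(threshold_sp1 = x$threshold_a, threshold_sp2 = x$threshold_b,
           auc_sp1 = x$roc1$auc, auc_sp2 = x$roc2$auc,
           tpr = x$tpr_at_choice, feasible = x$feasible)),
      file.path(outdir, "roc_thresholds.json"))
    write_manifest(outdir, "motifs",
                   list(tpr_lo = config$tpr_lo, tpr_hi = config$tpr_hi,
                        fpr_max = config$fpr_max,
                        match_pvalue = config$match_pvalue),
                   seedm, file.path(outdir, "conservation_records.tsv"),
                   c("tfbs_density.tsv", "roc_thresholds.json"), t0)
  }

  ## ---- stap ----------------------------------------------------------
  if (on("stap")) {
    t0 <- as.numeric(Sys.time())
    seeds <- stage_seed(config$seed, "stap")
    res$stap <- run_stap_stage(config, res, seeds)
    utils::write.table(res$stap$deltas, file.path(outdir,
                                                  "delta_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_report(res$stap$report, file.path(outdir,
                                                 "stap_report.json"))
    write_manifest(outdir, "stap",
                   list(top_peaks = config$top_peaks,
                        dchip_mode = config$dchip_mode),
                   seeds, file.path(outdir, "pairs.tsv"),
                   c("delta_records.tsv", "stap_report.json"), t0)
  }

  ## ---- codiv ---------------------------------------------------------
  if (on("codiv")) {
    t0 <- as.numeric(Sys.time())
    seedc <- stage_seed(config$seed, "codiv")
    conds_df <- config$sim$condition_set
    bmp1 <- res$bm1[res$records$id_a, , drop = FALSE]
    bmp2 <- res$bm2[res$records$id_b, , drop = FALSE]
    res$coassoc1 <- coassociation_zscores(bmp1, config$n_perm,
                                          seed = stage_seed(seedc, "sp1"))
    res$coassoc2 <- coassociation_zscores(bmp2, config$n_perm,
                                          seed = stage_seed(seedc, "sp2"))
    tfb1 <- tf_level_binding(bmp1, conds_df)
    tfb2 <- tf_level_binding(bmp2, conds_df)
    res$codiv <- codivergence_all(tfb1, tfb2)
    stp <- same_tp_cobinding(bmp1, conds_df)
    res$codiv$n_same_tp_cobound <- stp$n_same_tp_cobound[
      match(paste(res$codiv$tf1, res$codiv$tf2),
            paste(stp$tf1, stp$tf2))]
    zs <- res$stap$z_dstap
    res$loss_vs_motif <- binding_loss_vs_motif_loss_all(
      tfb1, tfb2, zs, motif_loss_cutoff = config$motif_loss_cutoff)
    write_matrix_tsv(res$coassoc1$z, file.path(outdir,
                                               "coassociation_z_sp1.tsv"))
    write_matrix_tsv(res$coassoc2$z, file.path(outdir,
                                               "coassociation_z_sp2.tsv"))
    utils::write.table(res$codiv, file.path(outdir, "codivergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$loss_vs_motif,
                       file.path(outdir, "loss_vs_motif.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(outdir, "codiv",
                   list(n_perm = config$n_perm,
                        motif_loss_cutoff = config$motif_loss_cutoff),
                   seedc, file.path(outdir, "delta_records.tsv"),
                   c("codivergence.tsv", "loss_vs_motif.tsv"), t0)
  }

  ## ---- final report ----------------------------------------------------
  report <- list(
    pair_summary = res$pair_summary,
    category_counts = if (!is.null(res$records))
      as.list(table(res$records$category)),
    stap_cv_pcc = res$stap$report$cv_pcc_mean %||% NULL,
    codivergence = if (!is.null(res$codiv))
      res$codiv[, c("tf1", "tf2", "S12", "n_both_lost",
                    "expected_both_lost", "fisher_p", "bh_q")]
  )
  write_json_report(report, file.path(outdir, "report.json"))
  invisible(res)
}

run_stap_stage <- function(config, res, seed) {
  tfs <- config$sim$tf_set
  conds_df <- config$sim$condition_set
  motifs <- config$sim$motifs[tfs]
  genome <- list(sp1 = res$sim$sequences$species1,
                 sp2 = res$sim$sequences$species2)
  crms <- list(sp1 = res$crms1, sp2 = res$crms2)
  peaks <- list(
    sp1 = res$sim$peaks[res$sim$peaks$species == "species1", ],
    sp2 = res$sim$peaks[res$sim$peaks$species == "species2", ])
  sigs <- list(sp1 = res$sig1, sp2 = res$sig2)
  ids <- list(sp1 = res$records$id_a, sp2 = res$records$id_b)
  # the model scores each CRM sequence itself (size-extended windows are
  # only used for TFBS density)
  eseq <- list(
    sp1 = crm_sequences(genome$sp1,
                        crms$sp1$crms[match(ids$sp1, crms$sp1$crms$id), ]),
    sp2 = crm_sequences(genome$sp2,
                        crms$sp2$crms[match(ids$sp2, crms$sp2$crms$id), ]))

  models <- list(); cv_pcc <- c(); chip_norm <- list(); stap_norm <- list()
  for (sp in c("sp1", "sp2")) {
    gseq <- genome[[sp]][[1L]]
    L <- nchar(gseq)
    for (tf in tfs) {
      cond_tf <- conds_df$condition[conds_df$tf == tf]
      pk <- peaks[[sp]][peaks[[sp]]$condition %in% cond_tf, ]
      # training: top peaks by score for the TF (best condition per CRM)
      pk <- pk[order(-pk$score), ]
      pk <- pk[!duplicated(pk$summit), ]
      pk <- utils::head(pk, config$top_peaks)
      if (nrow(pk) < 10L) next
      wlen <- as.integer(round(mean(pk$end - pk$start)))
      sseed <- stage_seed(seed, paste(sp, tf, sep = "_"))
      train <- with_seed(sseed, {
        rnd_start <- sample.int(L - wlen, nrow(pk))
        rnd_chip <- config$sim$signal_baseline +
          stats::rnorm(nrow(pk), 0, config$sim$noise_sd)
        list(rnd_start = rnd_start, rnd_chip = rnd_chip)
      })
      seqs <- c(substring(gseq, pk$start + 1L, pk$end),
                substring(gseq, train$rnd_start + 1L,
                          train$rnd_start + wlen))
      chip <- c(pk$score, train$rnd_chip)
      key <- paste(sp, tf, sep = "_")
      models[[key]] <- train_stap(seqs, chip, motifs[[tf]])
      cv <- crossvalidate_stap(seqs, chip, motifs[[tf]],
                               seed = stage_seed(sseed, "cv"))
      cv_pcc[key] <- cv$pooled_pcc
    }
  }

  # per-pair normalized ChIP and model scores per TF per species
  n_pairs <- nrow(res$records)
  z_dstap <- matrix(NA_real_, n_pairs, length(tfs),
                    dimnames = list(res$records$pair_id, tfs))
  deltas <- list(); delta_tests <- list()
  tfb1 <- tf_level_binding(res$bm1[ids$sp1, , drop = FALSE], conds_df)
  classv <- complexity_class(rowSums(tfb1))
  for (tf in tfs) {
    k1 <- paste("sp1", tf, sep = "_"); k2 <- paste("sp2", tf, sep = "_")
    if (is.null(models[[k1]]) || is.null(models[[k2]])) next
    cond_tf <- conds_df$condition[conds_df$tf == tf]
    nsig1 <- apply(sigs$sp1[, cond_tf, drop = FALSE], 2L,
                   function(x) normalize_scores(x)$scores)
    nsig2 <- apply(sigs$sp2[, cond_tf, drop = FALSE], 2L,
                   function(x) normalize_scores(x)$scores)
    if (config$dchip_mode == "max") {
      jmax <- max.col(sigs$sp1[, cond_tf, drop = FALSE],
                      ties.method = "first")
      chip1 <- nsig1[cbind(seq_len(n_pairs), jmax)]
      chip2 <- nsig2[cbind(seq_len(n_pairs), jmax)]
    } else {
      chip1 <- rowMeans(nsig1); chip2 <- rowMeans(nsig2)
    }
    st1 <- stap_scores(models[[k1]], eseq$sp1)
    st2 <- stap_scores(models[[k2]], eseq$sp2)
    da <- delta_analysis(chip1, chip2, st1, st2, classv,
                         ids = res$records$pair_id)
    z_dstap[, tf] <- da$records$z_dstap
    deltas[[tf]] <- cbind(tf = tf, da$records)
    delta_tests[[tf]] <- list(
      spearman = as.list(da$spearman), n = as.list(da$n),
      fisher_z_p = da$fisher_z_p,
      quadrant_fisher_p = da$quadrant_fisher_p,
      quadrant_fisher_p_green = da$quadrant_fisher_p_green,
      quadrant_counts = as.list(as.data.frame(da$quadrant_counts)))
  }
  deltas <- do.call(rbind, deltas)
  rownames(deltas) <- NULL
  list(models = models, cv_pcc = cv_pcc, deltas = deltas,
       z_dstap = z_dstap,
       report = list(cv_pcc = as.list(cv_pcc),
                     cv_pcc_mean = mean(cv_pcc),
                     delta_tests = delta_tests))
}

#' Interspecies occupancy-vs-motif divergence over the known CRM universe
#'
#' Convenience wrapper for benchmark runs: takes a [simulate_two_species()]
#' result, trains the occupancy model for one TF in each species (top
#' peaks plus length-matched random windows), scores the size-extended
#' orthologous CRM sequences, and runs [delta_analysis()] with ChIP
#' scores normalized per condition. The orthologous universe is the
#' generator's CRM set (known from the alignment), so pairs persist even
#' when all species-2 binding is lost.
#'
#' @param sim result of [simulate_two_species()].
#' @param tf TF name.
#' @param top_peaks training peaks per species.
#' @param seed RNG seed (random windows).
#' @param dchip_mode "max" or "mean" collapse over the TF's conditions.
#' @return [delta_analysis()] result plus `models` and `cv_pcc`.
#' @export
stap_delta_truth <- function(sim, tf, top_peaks = 1000, seed = 1,
                             dchip_mode = c("max", "mean")) {
  dchip_mode <- match.arg(dchip_mode)
  cfg <- sim$config
  conds_df <- cfg$condition_set
  cond_tf <- conds_df$condition[conds_df$tf == tf]
  tr <- sim$truth
  # the analysis set is the orthologous pairs bound by the TF in species 1;
  # the model scores each CRM sequence itself (size extension is only used
  # for TFBS density counting)
  sel <- which(tr$tf_bound1[, tf])
  n <- length(sel)
  seq_a <- crm_sequences(sim$sequences$species1, tr$crms1[sel, ])
  seq_b <- crm_sequences(sim$sequences$species2, tr$crms2[sel, ])

  models <- list(); cv_pcc <- c()
  scores <- list()
  for (sp in c("species1", "species2")) {
    gseq <- sim$sequences[[sp]][[1L]]
    pk <- sim$peaks[sim$peaks$species == sp &
                      sim$peaks$condition %in% cond_tf, ]
    pk <- pk[order(-pk$score), ]
    pk <- pk[!duplicated(pk$summit), ]
    pk <- utils::head(pk, top_peaks)
    wlen <- as.integer(round(mean(pk$end - pk$start)))
    tr_rnd <- with_seed(stage_seed(seed, sp), {
      list(start = sample.int(nchar(gseq) - wlen, nrow(pk)),
           chip = cfg$signal_baseline +
             stats::rnorm(nrow(pk), 0, cfg$noise_sd))
    })
    seqs <- c(substring(gseq, pk$start + 1L, pk$end),
              substring(gseq, tr_rnd$start + 1L, tr_rnd$start + wlen))
    chip <- c(pk$score, tr_rnd$chip)
    models[[sp]] <- train_stap(seqs, chip, cfg$motifs[[tf]])
    cv <- crossvalidate_stap(seqs, chip, cfg$motifs[[tf]],
                             seed = stage_seed(seed, paste0(sp, "cv")))
    cv_pcc[sp] <- cv$pooled_pcc
    scores[[sp]] <- stap_scores(models[[sp]],
                                if (sp == "species1") seq_a else seq_b)
  }

  s1 <- sim$signal$species1[sel, cond_tf, drop = FALSE]
  s2 <- sim$signal$species2[sel, cond_tf, drop = FALSE]
  nsig1 <- apply(s1, 2L, function(x) normalize_scores(x)$scores)
  nsig2 <- apply(s2, 2L, function(x) normalize_scores(x)$scores)
  if (dchip_mode == "max") {
    jmax <- max.col(s1, ties.method = "first")
    chip1 <- nsig1[cbind(seq_len(n), jmax)]
    chip2 <- nsig2[cbind(seq_len(n), jmax)]
  } else {
    chip1 <- rowMeans(nsig1); chip2 <- rowMeans(nsig2)
  }
  cls <- complexity_class(rowSums(tr$tf_bound1))[sel]
  da <- delta_analysis(chip1, chip2, scores$species1, scores$species2,
                       cls, ids = tr$crms1$id[sel])
  c(da, list(models = models, cv_pcc = cv_pcc))
}

#' Build a pipeline configuration from a YAML file
#'
#' The file may contain a `sim:` block (arguments to [sim_config()]) and
#' top-level pipeline arguments (arguments to [pipeline_config()]).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$cooperative_rule))
    sim_args$cooperative_rule <- as.list(sim_args$cooperative_rule)
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}
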