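#' Default (TF, time point) condition design
#'
#' Five mesodermal TFs assayed over five embryonic time points, 14
#' conditions in total: Twi and Tin at TP1-TP3, Mef2 at TP1-TP5, Bap at
#' TP2 and Bin at TP3-TP4. For non-standard TF sets each TF gets TP1-TP3.
#'
#' @param tf_set character vector of TF names.
#' @return data.frame with columns tf, tp, condition.
#' @export
default_condition_set <- function(tf_set = c("Twi", "Tin", "Mef2", "Bap",
                                             "Bin")) {
  std <- list(Twi = 1:3, Tin = 1:3, Mef2 = 1:5, Bap = 2, Bin = 3:4)
  tps <- lapply(tf_set, function(tf) std[[tf]] %||% 1:3)
  df <- data.frame(
    tf = rep(tf_set, lengths(tps)),
    tp = paste0("TP", unlist(tps)),
    stringsAsFactors = FALSE
  )
  df$condition <- paste(df$tf, df$tp, sep = "_")
  df
}

#' Configuration for the synthetic two-species benchmark
#'
#' Defines every tunable of the generator: genome layout, divergence
#' rates, the motif-loss and cooperative-rescue (TF collective) rules and
#' the signal model `log2 signal = gain * occupancy + baseline + N(0,
#' noise_sd)` where occupancy is the number of intact planted sites.
#'
#' @param n_crms number of CRM loci (>= 1).
#' @param crm_len_mean,crm_len_sd CRM length distribution (bp); the mean
#'   must be at least 3x the longest motif.
#' @param spacer_mean,spacer_min inter-CRM spacer (bp); the minimum keeps
#'   neighbouring CRMs beyond the summit-clustering gap.
#' @param substitution_rate per-base substitution probability between the
#'   species (neutral positions only; conserved motif instances are
#'   protected).
#' @param indel_rate per-base indel event probability.
#' @param indel_len_geom_p geometric length parameter; lengths are
#'   `rgeom(p) + 1`.
#' @param tf_set TF names; PWMs of the same names must exist in `motifs`.
#' @param condition_set data.frame(tf, tp, condition).
#' @param motif_loss_prob per-(CRM, TF) probability that the planted
#'   motifs are destroyed in species 2.
#' @param cooperative_rule list(enabled, min_partners): a TF whose motifs
#'   are lost keeps its species-2 binding when at least `min_partners`
#'   other TFs retain their motifs on the CRM (TF collective rescue).
#' @param noise_sd Gaussian noise SD on the log2 signal.
#' @param signal_gain,signal_baseline linear link from occupancy to log2
#'   signal.
#' @param background species-1 base composition (A/T-rich fly-like).
#' @param n_tfs_probs distribution of the number of distinct TFs bound
#'   per CRM (1..5).
#' @param temporal_probs named probabilities of the continuous/early/late
#'   temporal occupancy classes per (CRM, TF).
#' @param track_flank bp of conservation-score track emitted around each
#'   CRM.
#' @param codiv_pair,co_loss_prob planted co-divergent TF pair, see
#'   [plant_cooccurrence()].
#' @param motifs list of PWMs; defaults to the packaged synthetic library.
#' @param seed integer; identical seeds give bit-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_crms = 2000, crm_len_mean = 300, crm_len_sd = 50,
                       spacer_mean = 900, spacer_min = 600,
                       substitution_rate = 0.5, indel_rate = 0.02,
                       indel_len_geom_p = 0.4,
                       tf_set = c("Twi", "Tin", "Mef2", "Bap", "Bin"),
                       condition_set = default_condition_set(tf_set),
                       motif_loss_prob = 0.3,
                       cooperative_rule = list(enabled = TRUE,
                                               min_partners = 3),
                       noise_sd = 0.5, signal_gain = 1.5,
                       signal_baseline = 0.5,
                       background = c(A = 0.28, C = 0.22, G = 0.22,
                                      T = 0.28),
                       n_tfs_probs = c(0.53, 0.20, 0.17, 0.06, 0.04),
                       temporal_probs = c(continuous = 0.5, early = 0.25,
                                          late = 0.25),
                       track_flank = 500,
                       codiv_pair = NULL, co_loss_prob = 0,
                       motifs = NULL, seed = 1) {
  if (is.null(motifs)) {
    motifs <- read_meme(system.file("extdata", "motifs_synthetic.meme",
                                    package = "crmdiverge"))
  }
  missing_tf <- setdiff(tf_set, names(motifs))
  if (length(missing_tf))
    stop("no PWM for TF(s): ", paste(missing_tf, collapse = ", "))
  probs <- c(substitution_rate = substitution_rate,
             indel_rate = indel_rate, indel_len_geom_p = indel_len_geom_p,
             motif_loss_prob = motif_loss_prob, co_loss_prob = co_loss_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (n_crms < 1) stop("n_crms must be >= 1")
  if (nrow(condition_set) == 0) stop("condition_set must be non-empty")
  maxw <- max(vapply(motifs[tf_set], function(p) nrow(p$mat), 0L))
  if (crm_len_mean < 3 * maxw)
    stop("crm_len_mean < 3x longest motif width (", maxw, " bp): ",
         "motifs unplantable")
  if (!is.null(codiv_pair)) {
    if (length(codiv_pair) != 2L || !all(codiv_pair %in% tf_set))
      stop("codiv_pair must name two TFs from tf_set")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Plant a co-divergent TF pair
#'
#' Among CRMs co-bound by the pair in species 1, a fraction
#' `co_loss_prob` lose the binding (and motifs) of BOTH factors in
#' species 2, in excess of independent loss; those forced joint losses
#' are not eligible for cooperative rescue (the emulated mechanism is
#' partner-dependent binding).
#'
#' @param config a [sim_config()].
#' @param pair character vector of two TF names from `config$tf_set`.
#' @param co_loss_prob probability in `[0, 1]`.
#' @return the amended config, to be passed to [simulate_two_species()].
#' @export
plant_cooccurrence <- function(config, pair, co_loss_prob) {
  stopifnot(inherits(config, "sim_config"))
  if (length(pair) != 2L || !all(pair %in% config$tf_set))
    stop("pair must name two TFs from tf_set")
  if (co_loss_prob < 0 || co_loss_prob > 1)
    stop("co_loss_prob outside [0,1]")
  config$codiv_pair <- pair
  config$co_loss_prob <- co_loss_prob
  config
}

sample_motif_instance <- function(pwm) {
  w <- nrow(pwm$mat)
  vapply(seq_len(w), function(j)
    sample.int(4L, 1L, prob = pwm$mat[j, ]), 0L)
}

comp_codes <- function(codes) 5L - codes

evolve_sequence <- function(codes1, protected, cfg) {
  L <- length(codes1)
  codes2 <- codes1
  sub <- stats::runif(L) < cfg$substitution_rate & !protected
  if (any(sub))
    codes2[sub] <- ((codes1[sub] - 1L +
                       sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L
  # indel events; none may start on (or insert into) a protected run
  cand <- stats::runif(L) < cfg$indel_rate
  cand[protected] <- FALSE
  cand[c(FALSE, protected[-L])] <- FALSE
  cand[1L] <- FALSE
  pos <- which(cand)
  n <- length(pos)
  if (n) {
    is_del <- stats::runif(n) < 0.5
    len <- stats::rgeom(n, cfg$indel_len_geom_p) + 1L
    prot_pos <- which(protected)
    if (length(prot_pos)) {
      k <- findInterval(pos, prot_pos) + 1L
      nxt <- ifelse(k <= length(prot_pos), prot_pos[k], L + 1L)
    } else nxt <- rep(L + 1L, n)
    len <- ifelse(is_del, pmin(len, nxt - pos, L - pos + 1L), len)
    ok <- len >= 1L
    pos <- pos[ok]; is_del <- is_del[ok]; len <- len[ok]
    # drop events overlapping an earlier deletion
    keep <- logical(length(pos)); last_end <- 0L
    for (i in seq_along(pos)) {
      if (pos[i] > last_end) {
        keep[i] <- TRUE
        last_end <- pos[i] + if (is_del[i]) len[i] - 1L else 0L
      }
    }
    pos <- pos[keep]; is_del <- is_del[keep]; len <- len[keep]
  }
  if (!length(pos)) {
    blocks <- data.frame(src_start = 0L, src_end = L, tgt_start = 0L)
    return(list(codes2 = codes2, blocks = blocks))
  }
  del_len <- ifelse(is_del, len, 0L)
  ins_len <- ifelse(is_del, 0L, len)
  m <- length(pos)
  pre_shift <- c(0L, cumsum(ins_len - del_len))  # length m + 1
  src_starts <- c(1L, pos + del_len)
  src_ends <- c(pos - 1L, L)
  tgt_starts <- src_starts + pre_shift
  seg_len <- src_ends - src_starts + 1L
  keep_seg <- seg_len > 0L
  L2 <- L + sum(ins_len) - sum(del_len)
  out <- integer(L2)
  seg_src <- sequence(seg_len[keep_seg], from = src_starts[keep_seg])
  seg_tgt <- sequence(seg_len[keep_seg], from = tgt_starts[keep_seg])
  out[seg_tgt] <- codes2[seg_src]
  ins_i <- which(ins_len > 0L)
  if (length(ins_i)) {
    ins_tgt <- sequence(ins_len[ins_i],
                        from = pos[ins_i] + pre_shift[ins_i])
    out[ins_tgt] <- sample.int(4L, length(ins_tgt), replace = TRUE,
                               prob = cfg$background)
  }
  blocks <- data.frame(
    src_start = src_starts[keep_seg] - 1L,
    src_end = src_ends[keep_seg],
    tgt_start = tgt_starts[keep_seg] - 1L
  )
  list(codes2 = out, blocks = blocks)
}

map_positions <- function(p0, blocks) {
  # p0 0-based positions on src; returns 0-based target or NA (deleted)
  i <- findInterval(p0, blocks$src_start)
  ok <- i >= 1L & p0 < blocks$src_end[pmax(i, 1L)]
  out <- rep(NA_integer_, length(p0))
  out[ok] <- blocks$tgt_start[i[ok]] + (p0[ok] - blocks$src_start[i[ok]])
  out
}

codes_to_seq <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes])
}

#' Simulate a two-species regulatory benchmark with known ground truth
#'
#' Species 1 carries `n_crms` CRM loci on one chromosome, each bound by
#' 1-5 TFs at temporal subsets of their conditions, with binding realized
#' as planted PWM-sampled motif instances. Species 2 is the species-1
#' sequence evolved by substitutions and indels; motif instances of
#' conserved binding events are protected, lost events are degraded.
#' A TF whose motifs are lost keeps binding when enough partners remain
#' (TF collective rescue). The emitted alignment block map records the
#' indel structure exactly.
#'
#' @param config a [sim_config()].
#' @return list with elements `sequences` (named character per species),
#'   `peaks` (data.frame, both species), `signal` (per-species CRM x
#'   condition log2 matrices), `block_map` (species2 -> species1),
#'   `activity` (per-CRM label), `conservation_track` (data.frame chrom,
#'   pos, score around species-1 CRMs), `truth` (ground truth list) and
#'   `config`.
#' @export
simulate_two_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_two_species_impl(config))
}

simulate_two_species_impl <- function(cfg) {
  n <- cfg$n_crms
  tfs <- cfg$tf_set
  conds <- cfg$condition_set
  motifs <- cfg$motifs[tfs]
  chrom <- "chr2L"

  crm_len <- pmax(round(stats::rnorm(n, cfg$crm_len_mean, cfg$crm_len_sd)),
                  3L * max(vapply(motifs, function(p) nrow(p$mat), 0L)))
  spacer <- pmax(round(stats::rnorm(n + 1L, cfg$spacer_mean,
                                    cfg$spacer_mean / 6)),
                 cfg$spacer_min)
  starts <- cumsum(spacer)[seq_len(n)] + c(0L, cumsum(crm_len))[seq_len(n)]
  ends <- starts + crm_len
  L1 <- ends[n] + spacer[n + 1L]
  codes1 <- sample.int(4L, L1, replace = TRUE, prob = cfg$background)

  # --- binding design -------------------------------------------------
  ntf_probs <- cfg$n_tfs_probs[seq_len(min(length(tfs),
                                           length(cfg$n_tfs_probs)))]
  n_tfs <- sample.int(length(ntf_probs), n, replace = TRUE,
                      prob = ntf_probs)
  tf_bound1 <- matrix(FALSE, n, length(tfs), dimnames = list(NULL, tfs))
  for (i in seq_len(n))
    tf_bound1[i, sample(tfs, n_tfs[i])] <- TRUE

  tclass <- matrix(NA_character_, n, length(tfs),
                   dimnames = list(NULL, tfs))
  idx <- which(tf_bound1)
  tclass[idx] <- sample(names(cfg$temporal_probs), length(idx),
                        replace = TRUE, prob = cfg$temporal_probs)

  # planted sites (accumulated as flat vectors for speed)
  acc <- list(crm = integer(0), tf = character(0), start = integer(0),
              end = integer(0), strand = character(0), score = numeric(0))
  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- integer(0)  # occupied offsets within CRM
    v_tf <- character(0); v_off <- integer(0); v_strand <- character(0)
    v_score <- numeric(0); v_w <- integer(0)
    for (tf in tfs[tf_bound1[i, ]]) {
      w <- nrow(motifs[[tf]]$mat)
      k <- 1L + stats::rbinom(1L, 2L, 0.4)
      for (s in seq_len(k)) {
        for (try in 1:12) {
          off <- sample.int(crm_len[i] - w - 3L, 1L) + 1L
          if (!any(abs(placed - off) < w + 2L)) break
          off <- NA_integer_
        }
        if (is.na(off)) next
        placed <- c(placed, off)
        inst <- sample_motif_instance(motifs[[tf]])
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "+") inst else rev(comp_codes(inst))
        p0 <- starts[i] + off  # 0-based genome start
        codes1[(p0 + 1L):(p0 + w)] <- planted
        v_tf <- c(v_tf, tf); v_off <- c(v_off, p0)
        v_strand <- c(v_strand, strand); v_w <- c(v_w, w)
        v_score <- c(v_score,
                     sum(motifs[[tf]]$score_mat[cbind(seq_len(w), inst)]))
      }
    }
    if (length(v_tf))
      chunks[[i]] <- list(crm = rep.int(i, length(v_tf)), tf = v_tf,
                          start = v_off, end = v_off + v_w,
                          strand = v_strand, score = v_score)
  }
  chunks <- chunks[!vapply(chunks, is.null, TRUE)]
  sites <- if (length(chunks)) data.frame(
    crm = unlist(lapply(chunks, `[[`, "crm")),
    tf = unlist(lapply(chunks, `[[`, "tf")),
    start = unlist(lapply(chunks, `[[`, "start")),
    end = unlist(lapply(chunks, `[[`, "end")),
    strand = unlist(lapply(chunks, `[[`, "strand")),
    score = unlist(lapply(chunks, `[[`, "score")),
    stringsAsFactors = FALSE) else NULL

  # --- species-2 loss / rescue ---------------------------------------
  lost <- matrix(FALSE, n, length(tfs), dimnames = list(NULL, tfs))
  lost[idx] <- stats::runif(length(idx)) < cfg$motif_loss_prob
  lost[!tf_bound1] <- FALSE
  forced <- matrix(FALSE, n, length(tfs), dimnames = list(NULL, tfs))
  if (!is.null(cfg$codiv_pair) && cfg$co_loss_prob > 0) {
    p1 <- cfg$codiv_pair[1L]; p2 <- cfg$codiv_pair[2L]
    cob <- which(tf_bound1[, p1] & tf_bound1[, p2])
    hit <- cob[stats::runif(length(cob)) < cfg$co_loss_prob]
    lost[hit, p1] <- TRUE; lost[hit, p2] <- TRUE
    forced[hit, p1] <- TRUE; forced[hit, p2] <- TRUE
  }
  rescued <- matrix(FALSE, n, length(tfs), dimnames = list(NULL, tfs))
  if (isTRUE(cfg$cooperative_rule$enabled)) {
    partners <- rowSums(tf_bound1 & !lost)  # TFs with intact motifs
    for (j in seq_along(tfs)) {
      cand <- tf_bound1[, j] & lost[, j] & !forced[, j]
      rescued[cand, j] <- partners[cand] >= cfg$cooperative_rule$min_partners
    }
  }
  tf_bound2 <- tf_bound1 & (!lost | rescued)

  # --- evolve sequence ------------------------------------------------
  protected <- logical(L1)
  if (!is.null(sites)) {
    cons <- !lost[cbind(sites$crm, match(sites$tf, tfs))]
    if (any(cons)) {
      ks <- which(cons)
      protected[sequence(sites$end[ks] - sites$start[ks],
                         from = sites$start[ks] + 1L)] <- TRUE
    }
  }
  ev <- evolve_sequence(codes1, protected, cfg)
  codes2 <- ev$codes2
  # degrade lost motif instances beyond the background substitution rate
  if (!is.null(sites)) {
    lost_sites <- which(lost[cbind(sites$crm, match(sites$tf, tfs))])
    for (k in lost_sites) {
      p2 <- map_positions(sites$start[k]:(sites$end[k] - 1L), ev$blocks)
      p2 <- p2[!is.na(p2)]
      if (!length(p2)) next
      mut <- stats::runif(length(p2)) < 0.6
      if (sum(mut) < min(2L, length(p2))) mut[seq_len(min(2L, length(p2)))] <- TRUE
      tp <- p2[mut] + 1L
      codes2[tp] <- ((codes2[tp] - 1L +
                        sample.int(3L, length(tp), replace = TRUE)) %% 4L) + 1L
    }
  }
  L2 <- length(codes2)

  # --- species-2 CRM coordinates (truth) -----------------------------
  crms2_start <- integer(n); crms2_end <- integer(n)
  for (i in seq_len(n)) {
    p <- map_positions(c(starts[i], ends[i] - 1L), ev$blocks)
    if (is.na(p[1L])) {
      bi <- min(findInterval(starts[i], ev$blocks$src_start) + 1L,
                nrow(ev$blocks))
      p[1L] <- ev$blocks$tgt_start[bi]
    }
    if (is.na(p[2L])) {
      bi <- max(findInterval(ends[i] - 1L, ev$blocks$src_start), 1L)
      p[2L] <- ev$blocks$tgt_start[bi] +
        (ev$blocks$src_end[bi] - 1L - ev$blocks$src_start[bi])
    }
    crms2_start[i] <- p[1L]; crms2_end[i] <- p[2L] + 1L
  }

  # --- condition-level truth ------------------------------------------
  cond_ids <- conds$condition
  tp_subset <- function(tf, cls) {
    ctp <- conds$tp[conds$tf == tf]
    k <- length(ctp)
    switch(cls,
           continuous = ctp,
           early = ctp[seq_len(ceiling(k / 2))],
           late = ctp[(k - ceiling(k / 2) + 1L):k])
  }
  binding1 <- matrix(FALSE, n, length(cond_ids),
                     dimnames = list(NULL, cond_ids))
  for (j in seq_along(tfs)) {
    tf <- tfs[j]
    bi <- which(tf_bound1[, j])
    for (i in bi) {
      tps <- tp_subset(tf, tclass[i, j])
      binding1[i, paste(tf, tps, sep = "_")] <- TRUE
    }
  }
  binding2 <- binding1
  for (j in seq_along(tfs))
    binding2[!tf_bound2[, j], conds$tf == tfs[j]] <- FALSE

  # --- signal ----------------------------------------------------------
  nsite <- matrix(0L, n, length(tfs), dimnames = list(NULL, tfs))
  if (!is.null(sites)) {
    tb <- table(factor(sites$crm, levels = seq_len(n)),
                factor(sites$tf, levels = tfs))
    nsite[] <- as.integer(tb)
  }
  occ_for <- function(bound_tf) {
    occ <- matrix(0, n, length(cond_ids), dimnames = list(NULL, cond_ids))
    for (j in seq_along(tfs)) {
      cj <- which(conds$tf == tfs[j])
      occ[, cj] <- outer(nsite[, j] * bound_tf[, j], rep(1L, length(cj)))
    }
    occ * binding1  # condition pattern shared across species at TF level
  }
  crm_ids <- sprintf("crm_%05d", seq_len(n))
  mk_signal <- function(occ) {
    m <- cfg$signal_gain * occ + cfg$signal_baseline +
      stats::rnorm(length(occ), 0, cfg$noise_sd)
    dimnames(m) <- list(crm_ids, cond_ids)
    m
  }
  signal1 <- mk_signal(occ_for(tf_bound1))
  signal2 <- mk_signal(occ_for(tf_bound2))

  # --- peaks ------------------------------------------------------------
  # summit at the strongest planted site of the TF (mapped for species 2);
  # rescued binding without an intact motif peaks at the CRM center.
  best_site <- matrix(NA_integer_, n, length(tfs),
                      dimnames = list(NULL, tfs))
  if (!is.null(sites)) {
    o <- order(sites$crm, sites$tf, -sites$score)
    so <- sites[o, ]
    first <- !duplicated(paste(so$crm, so$tf))
    sel <- so[first, ]
    best_site[cbind(sel$crm, match(sel$tf, tfs))] <-
      sel$start + (sel$end - sel$start) %/% 2L
  }
  centers1 <- (starts + ends) %/% 2L
  peak_rows <- function(species, bindmat, sigmat, summit_fun, chlen) {
    out <- list()
    for (cid in cond_ids) {
      tf <- conds$tf[conds$condition == cid]
      b <- which(bindmat[, cid])
      if (!length(b)) next
      sm <- summit_fun(b, tf)
      out[[cid]] <- data.frame(
        chrom = chrom, start = pmax(0L, sm - 150L),
        end = pmin(chlen, sm + 150L), summit = sm,
        score = sigmat[b, cid],
        tf = tf, tp = sub("^.*_", "", cid), condition = cid,
        species = species, crm_truth = crm_ids[b],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  summit1 <- function(b, tf) {
    s <- best_site[b, tf]
    ifelse(is.na(s), centers1[b], s)
  }
  summit2 <- function(b, tf) {
    s1 <- summit1(b, tf)
    # rescued-without-motif binding peaks at the (mapped) CRM center
    resc <- rescued[b, tf]
    s1[resc] <- centers1[b][resc]
    s2 <- map_positions(s1, ev$blocks)
    miss <- is.na(s2)
    if (any(miss)) {
      bi <- findInterval(s1[miss], ev$blocks$src_start)
      s2[miss] <- ev$blocks$tgt_start[pmax(bi, 1L)]
    }
    s2
  }
  peaks <- rbind(
    peak_rows("species1", binding1, signal1, summit1, L1),
    peak_rows("species2", binding2, signal2, summit2, L2)
  )
  rownames(peaks) <- NULL

  # --- true conservation categories ------------------------------------
  category <- character(n)
  for (i in seq_len(n)) {
    a <- cond_ids[binding1[i, ]]; b <- cond_ids[binding2[i, ]]
    rec <- jaccard_conservation(a, b)
    category[i] <- rec$category
  }

  # --- activity labels --------------------------------------------------
  activity <- vapply(seq_len(n), function(i) {
    p <- if (category[i] == "strong") c(0.35, 0.25, 0.40)
         else c(0.15, 0.35, 0.50)
    sample(c("mesoderm", "other", "none"), 1L, prob = p)
  }, "")

  # --- conservation-score track (species 1, whole chromosome) ----------
  base_level <- 0.15
  jnum <- ifelse(category == "strong", 0.55,
                 ifelse(category == "intermediate", 0.30, 0.05))
  sc <- rep(base_level, L1)
  in_crm <- sequence(ends - starts, from = starts + 1L)  # 1-based index
  sc[in_crm] <- base_level + rep(jnum, ends - starts)
  sc <- pmin(1, pmax(0, sc + stats::rnorm(L1, 0, 0.02)))
  track <- data.frame(chrom = chrom, pos = 0:(L1 - 1L), score = sc)

  # --- block map: species2 -> species1 (inverted; blocks are ungapped) --
  block_map <- data.frame(
    src_chrom = chrom,
    src_start = ev$blocks$tgt_start,
    src_end = ev$blocks$tgt_start + (ev$blocks$src_end -
                                       ev$blocks$src_start),
    tgt_chrom = chrom,
    tgt_start = ev$blocks$src_start,
    strand = "+",
    stringsAsFactors = FALSE
  )

  truth <- list(
    crms1 = data.frame(id = crm_ids, chrom = chrom, start = starts,
                       end = ends, stringsAsFactors = FALSE),
    crms2 = data.frame(id = crm_ids, chrom = chrom, start = crms2_start,
                       end = crms2_end, stringsAsFactors = FALSE),
    sites = sites,
    tf_bound1 = tf_bound1, tf_bound2 = tf_bound2,
    lost = lost, rescued = rescued, forced_co_loss = forced,
    binding1 = binding1, binding2 = binding2,
    nsite = nsite,
    category = category,
    codiv_pair = cfg$codiv_pair,
    blocks_sp1_to_sp2 = ev$blocks
  )

  list(
    sequences = list(species1 = stats::setNames(codes_to_seq(codes1), chrom),
                     species2 = stats::setNames(codes_to_seq(codes2), chrom)),
    peaks = peaks,
    signal = list(species1 = signal1, species2 = signal2),
    block_map = block_map,
    activity = data.frame(id = crm_ids, label = activity,
                          stringsAsFactors = FALSE),
    conservation_track = track,
    truth = truth,
    config = cfg
  )
}

#' Call binding from a quantitative signal matrix
#'
#' The generator's own caller: a cell is bound when its log2 signal
#' exceeds the midpoint between the unbound baseline and the one-site
#' level. On noiseless signal this recovers the ground truth exactly.
#'
#' @param signal CRM x condition log2 signal matrix.
#' @param config the [sim_config()] used to generate it.
#' @return logical matrix of the same shape.
#' @export
call_binding <- function(signal, config) {
  signal > config$signal_baseline + config$signal_gain / 2
}
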