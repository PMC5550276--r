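#' Pairwise condition co-association z-scores
#'
#' The observed co-association for conditions (j, k) is the number of
#' CRMs bound in both. The null preserves all row and column sums of the
#' binary matrix (degree-preserving randomization, curveball trades with
#' burn-in and thinning); z = (obs - null mean) / null SD. Columns that
#' are constant (all 0 or all 1) get undefined z for their pairs and are
#' flagged.
#'
#' @param mat binary CRM x condition matrix.
#' @param n_perm number of null samples (>= 2; default 500).
#' @param seed RNG seed.
#' @param burnin,thin Markov-chain controls; defaults scale with the
#'   matrix (10x and 1x the number of rows).
#' @return list with obs, null_mean, null_sd, z (condition x condition
#'   matrices), `flagged` (degenerate columns) and `n_perm`.
#' @export
coassociation_zscores <- function(mat, n_perm = 500, seed = 1,
                                  burnin = NULL, thin = NULL) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (!all(mat %in% c(0, 1))) stop("matrix must be binary")
  storage.mode(mat) <- "integer"
  flagged <- colnames(mat)[colSums(mat) %in% c(0L, nrow(mat))]
  burnin <- burnin %||% (10L * nrow(mat))
  thin <- thin %||% nrow(mat)
  obs <- crossprod(mat)
  nm <- vegan::nullmodel(mat, "curveball")
  sims <- stats::simulate(nm, nsim = n_perm, seed = seed,
                          burnin = burnin, thin = thin)
  k <- ncol(mat)
  s1 <- matrix(0, k, k); s2 <- matrix(0, k, k)
  for (i in seq_len(n_perm)) {
    cp <- crossprod(sims[, , i])
    s1 <- s1 + cp
    s2 <- s2 + cp^2
  }
  mu <- s1 / n_perm
  sdv <- sqrt(pmax(s2 / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA
  dimnames(mu) <- dimnames(sdv) <- dimnames(z) <- dimnames(obs)
  list(obs = obs, null_mean = mu, null_sd = sdv, z = z,
       flagged = flagged, n_perm = n_perm)
}

#' TF-level binding from a condition-level binding matrix
#'
#' A TF is bound when at least one of its conditions is bound.
#'
#' @param binding binary CRM x condition matrix.
#' @param conditions data.frame(tf, condition).
#' @return logical CRM x TF matrix.
#' @export
tf_level_binding <- function(binding, conditions) {
  tfs <- unique(conditions$tf)
  out <- vapply(tfs, function(tf) {
    cols <- conditions$condition[conditions$tf == tf]
    rowSums(binding[, cols, drop = FALSE]) > 0
  }, logical(nrow(binding)))
  dimnames(out) <- list(rownames(binding), tfs)
  out
}

#' Co-divergence contingency table for one TF pair
#'
#' Over orthologous CRMs co-bound by tf1 and tf2 in species 1, counts the
#' four species-2 outcomes (both conserved, tf1 lost, tf2 lost, both
#' lost), the per-TF loss probabilities `P1`, `P2`, the independence
#' expectation `Expected = S12 * P1 * P2` for joint loss, and the
#' two-sided Fisher exact p of binding dependence on the 2x2 table
#' `[[both_conserved, tf2_lost], [tf1_lost, both_lost]]`.
#'
#' @param tf_bound_a,tf_bound_b logical CRM x TF matrices (pair-aligned
#'   rows) for species 1 and 2.
#' @param tf1,tf2 TF names.
#' @return one-row data.frame (S12 = 0 yields an empty-count row with NA
#'   p, excluded from BH).
#' @export
codivergence_table <- function(tf_bound_a, tf_bound_b, tf1, tf2) {
  co <- tf_bound_a[, tf1] & tf_bound_a[, tf2]
  s12 <- sum(co)
  if (s12 == 0L) {
    return(data.frame(tf1 = tf1, tf2 = tf2, n_both_conserved = 0L,
                      n_tf1_lost = 0L, n_tf2_lost = 0L, n_both_lost = 0L,
                      S12 = 0L, P1 = NA_real_, P2 = NA_real_,
                      expected_both_lost = NA_real_, fisher_p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  b1 <- tf_bound_b[co, tf1]; b2 <- tf_bound_b[co, tf2]
  cc <- sum(b1 & b2); l1 <- sum(!b1 & b2); l2 <- sum(b1 & !b2)
  ll <- sum(!b1 & !b2)
  p1 <- (l1 + ll) / s12; p2 <- (l2 + ll) / s12
  expected <- s12 * p1 * p2
  p <- if (p1 == 0 || p2 == 0) 1 else
    stats::fisher.test(matrix(c(cc, l2, l1, ll), 2L, byrow = TRUE))$p.value
  data.frame(tf1 = tf1, tf2 = tf2, n_both_conserved = cc,
             n_tf1_lost = l1, n_tf2_lost = l2, n_both_lost = ll,
             S12 = s12, P1 = p1, P2 = p2,
             expected_both_lost = expected, fisher_p = p,
             stringsAsFactors = FALSE)
}

#' Co-divergence tables for all TF pairs, with BH correction
#'
#' @param tf_bound_a,tf_bound_b as in [codivergence_table()].
#' @param tfs TF names (default: matrix columns).
#' @return data.frame with one row per unordered pair and a `bh_q`
#'   column (rows with S12 = 0 excluded from the BH family).
#' @export
codivergence_all <- function(tf_bound_a, tf_bound_b,
                             tfs = colnames(tf_bound_a)) {
  combs <- utils::combn(tfs, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(k)
    codivergence_table(tf_bound_a, tf_bound_b, combs[1L, k], combs[2L, k]))
  out <- do.call(rbind, rows)
  out$bh_q <- NA_real_
  ok <- !is.na(out$fisher_p)
  out$bh_q[ok] <- stats::p.adjust(out$fisher_p[ok], "BH")
  out
}

#' Association between loss of TF1 occupancy and loss of TF2 motifs
#'
#' Over CRMs co-bound by tf1 and tf2 in species 1: rows = tf1 binding
#' lost vs conserved in species 2; columns = tf2 motif lost (z_dStap for
#' tf2 above `motif_loss_cutoff`) vs retained. Two-sided Fisher exact
#' test; the odds ratio is Haldane-corrected when a margin is empty.
#'
#' @param tf_bound_a,tf_bound_b logical CRM x TF matrices.
#' @param z_dstap_tf2 z-standardized dStap values for tf2, aligned with
#'   the matrix rows.
#' @param tf1,tf2 TF names (ordered: occupancy of tf1, motifs of tf2).
#' @param motif_loss_cutoff z threshold calling a motif lost (default 1).
#' @return one-row data.frame with the 2x2 counts, odds_ratio (exact
#'   conditional MLE), haldane_or, fisher_p, and mid_p (the Lancaster
#'   mid-p: `fisher_p - P(observed table)/2`, uniform under the null for
#'   this discrete test and therefore the quantity to use in calibration
#'   checks).
#' @export
binding_loss_vs_motif_loss <- function(tf_bound_a, tf_bound_b,
                                       z_dstap_tf2, tf1, tf2,
                                       motif_loss_cutoff = 1.0) {
  co <- tf_bound_a[, tf1] & tf_bound_a[, tf2] & !is.na(z_dstap_tf2)
  lost1 <- !tf_bound_b[co, tf1]
  mlost2 <- z_dstap_tf2[co] > motif_loss_cutoff
  tab <- matrix(c(sum(lost1 & mlost2), sum(lost1 & !mlost2),
                  sum(!lost1 & mlost2), sum(!lost1 & !mlost2)),
                2L, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  hor <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
    ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  obs_p <- stats::dhyper(tab[1, 1], sum(tab[1, ]), sum(tab[2, ]),
                         sum(tab[, 1]))
  data.frame(tf1 = tf1, tf2 = tf2,
             n_lost_mlost = tab[1, 1], n_lost_mkept = tab[1, 2],
             n_cons_mlost = tab[2, 1], n_cons_mkept = tab[2, 2],
             odds_ratio = unname(ft$estimate), haldane_or = hor,
             fisher_p = ft$p.value,
             mid_p = ft$p.value - obs_p / 2, stringsAsFactors = FALSE)
}

#' All ordered-pair occupancy-loss vs motif-loss tests, BH corrected
#'
#' @param tf_bound_a,tf_bound_b logical CRM x TF matrices.
#' @param z_dstap matrix of z-standardized dStap values, CRMs x TFs.
#' @param motif_loss_cutoff z threshold for motif loss.
#' @return data.frame over all ordered pairs with bh_q.
#' @export
binding_loss_vs_motif_loss_all <- function(tf_bound_a, tf_bound_b,
                                           z_dstap,
                                           motif_loss_cutoff = 1.0) {
  tfs <- colnames(tf_bound_a)
  rows <- list()
  for (t1 in tfs) for (t2 in tfs) {
    if (t1 == t2) next
    rows[[paste(t1, t2)]] <- binding_loss_vs_motif_loss(
      tf_bound_a, tf_bound_b, z_dstap[, t2], t1, t2, motif_loss_cutoff)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$bh_q <- stats::p.adjust(out$fisher_p, "BH")
  out
}

#' Same-time-point co-binding counts per TF pair
#'
#' Co-binding in the co-divergence tables is any-condition co-binding;
#' this reports, per TF pair, how many species-1 co-bound CRMs are also
#' co-bound at the same time point (both TFs bound at a shared TP).
#'
#' @param binding binary CRM x condition matrix (species 1).
#' @param conditions data.frame(tf, tp, condition).
#' @return data.frame tf1, tf2, n_cobound, n_same_tp_cobound.
#' @export
same_tp_cobinding <- function(binding, conditions) {
  tfs <- unique(conditions$tf)
  tfb <- tf_level_binding(binding, conditions)
  combs <- utils::combn(tfs, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    t1 <- combs[1L, k]; t2 <- combs[2L, k]
    shared_tp <- intersect(conditions$tp[conditions$tf == t1],
                           conditions$tp[conditions$tf == t2])
    same <- rep(FALSE, nrow(binding))
    for (tp in shared_tp) {
      c1 <- paste(t1, tp, sep = "_"); c2 <- paste(t2, tp, sep = "_")
      same <- same | (binding[, c1] == 1L & binding[, c2] == 1L)
    }
    data.frame(tf1 = t1, tf2 = t2,
               n_cobound = sum(tfb[, t1] & tfb[, t2]),
               n_same_tp_cobound = sum(same & tfb[, t1] & tfb[, t2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
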