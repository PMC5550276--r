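BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A PWM is a per-position base-probability model of a TF's motif,
#' scored against a 0-order background as natural-log odds,
#' `score = sum_j ln(p'_j(base) / bg(base))`, where `p'` are the matrix
#' probabilities with a pseudocount added and renormalized.
#'
#' @param name motif name.
#' @param mat numeric matrix, positions in rows, columns A, C, G, T;
#'   rows must sum to 1 (tolerance 1e-9 after an initial renormalization
#'   guard); width must be >= 4.
#' @param background named base frequencies summing to 1; defaults to an
#'   AT-rich fly background, see [patser_background()].
#' @param pseudocount added to each probability before the log-odds ratio
#'   (then renormalized per position).
#' @return object of class `pwm` with elements `name`, `mat`,
#'   `background`, `pseudocount` and the precomputed log-odds `score_mat`.
#' @export
new_pwm <- function(name, mat, background = NULL, pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- BASES
  mat <- mat[, BASES, drop = FALSE]
  if (nrow(mat) < 4L) stop("PWM width must be >= 4")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6)) stop("PWM rows must sum to 1")
  mat <- mat / rs  # exact renormalization within tolerance
  if (is.null(background)) background <- patser_background(0.28, 0.18)
  background <- background[BASES]
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  score_mat <- log(sweep(p, 2L, background, "/"))
  structure(list(name = name, mat = mat, background = background,
                 pseudocount = pseudocount, score_mat = score_mat),
            class = "pwm")
}

#' patser-style background frequencies
#'
#' The original scanner takes `a:t` and `c:g` as the frequency of A and of
#' T each (and of C and of G each). When the four per-base values do not
#' sum to 1 they are normalized to do so, with a warning, so the log-odds
#' background is a proper distribution.
#'
#' @param at frequency of A and of T each.
#' @param cg frequency of C and of G each.
#' @param quiet suppress the normalization warning.
#' @return named numeric of length 4 summing to 1.
#' @export
patser_background <- function(at = 0.28, cg = 0.18, quiet = TRUE) {
  bg <- c(A = at, C = cg, G = cg, T = at)
  s <- sum(bg)
  if (abs(s - 1) > 1e-9) {
    if (!quiet)
      warning(sprintf("background sums to %.3f; normalizing to 1", s))
    bg <- bg / s
  }
  bg
}

#' Reverse complement of a PWM
#' @param pwm a [new_pwm()] object.
#' @return pwm scoring the reverse strand.
#' @export
revcomp_pwm <- function(pwm) {
  m <- pwm$mat[rev(seq_len(nrow(pwm$mat))), rev(BASES), drop = FALSE]
  colnames(m) <- BASES
  new_pwm(paste0(pwm$name, "_rc"), m, pwm$background, pwm$pseudocount)
}

#' Consensus sequence (highest-probability base per position)
#' @param pwm a PWM object.
#' @return character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[max.col(pwm$mat, ties.method = "first")], collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq character DNA string.
#' @return character string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, NULL)[[1L]]), collapse = ""), ""))
}

seq_to_codes <- function(seq) {
  # A=1 C=2 G=3 T=4, N/other = NA
  x <- utf8ToInt(toupper(seq))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[x]
}

window_scores <- function(codes, score_mat) {
  w <- nrow(score_mat)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- score_mat[j, ][codes[j:(j + n - 1L)]]
    sc <- sc + v  # NA propagates for N-containing windows
  }
  sc
}

#' Exact null distribution of PWM scores under the background
#'
#' Dynamic-programming convolution of the per-column score distributions
#' under the 0-order background, discretized at step `eps`. The returned
#' table supports exact p-values: `P(score >= x)` for a random
#' background word of the motif width.
#'
#' @param pwm a PWM object.
#' @param eps discretization step for scores (default 0.01).
#' @return list with `score` (bin centers, ascending), `prob`, and
#'   `pval` = upper-tail probability at each score.
#' @export
pwm_score_distribution <- function(pwm, eps = 0.01) {
  S <- round(pwm$score_mat / eps)  # integer bins per column
  bg <- pwm$background
  lo <- sum(apply(S, 1L, min)); hi <- sum(apply(S, 1L, max))
  cur <- numeric(hi - lo + 1L)  # index = bin - lo + 1
  for (b in 1:4) {
    i <- S[1L, b] - lo + 1L
    cur[i] <- cur[i] + bg[b]
  }
  if (nrow(S) > 1L) for (j in 2:nrow(S)) {
    nxt <- numeric(hi - lo + 1L)
    for (b in 1:4) {
      sh <- S[j, b]
      nz <- which(cur > 0)
      nxt[nz + sh] <- nxt[nz + sh] + cur[nz] * bg[b]
    }
    cur <- nxt
  }
  nz <- which(cur > 0)
  bin <- nz + lo - 1L
  prob <- cur[nz]
  pval <- rev(cumsum(rev(prob)))
  list(score = bin * eps, bin = bin, prob = prob, pval = pval, eps = eps)
}

#' Smallest score whose exact p-value is at or below a threshold
#' @param pwm a PWM object.
#' @param pvalue target p-value.
#' @param eps discretization step.
#' @return numeric score threshold.
#' @export
threshold_for_pvalue <- function(pwm, pvalue, eps = 0.01) {
  d <- pwm_score_distribution(pwm, eps)
  i <- which(d$pval <= pvalue)
  if (!length(i)) return(Inf)
  d$score[min(i)]
}

lookup_pvalue <- function(dist, bins) {
  # bins are sums of the same rounded per-column scores the DP convolved,
  # so every observed bin is an outcome of the distribution
  dist$pval[match(bins, dist$bin)]
}

#' Scan a sequence with a PWM on both strands
#'
#' patser-style scan: every window on both strands is scored as
#' natural-log odds against the 0-order background; windows containing N
#' are skipped. Exact p-values come from [pwm_score_distribution()].
#'
#' @param seq character DNA string over A, C, G, T, N.
#' @param pwm a PWM object.
#' @param min_score keep hits with score >= this value.
#' @param min_pvalue alternatively, keep hits with exact p-value <= this.
#' @param compute_pvalues attach p-values to hits (default TRUE).
#' @param eps discretization step for the p-value DP.
#' @return data.frame with pos (0-based window start on the forward
#'   strand), strand, score, pvalue; sorted by position.
#' @export
scan_pwm <- function(seq, pwm, min_score = NULL, min_pvalue = NULL,
                     compute_pvalues = TRUE, eps = 0.01) {
  need_p <- compute_pvalues || !is.null(min_pvalue)
  codes <- seq_to_codes(seq)
  rc <- revcomp_pwm(pwm)
  fwd <- window_scores(codes, pwm$score_mat)
  rev_ <- window_scores(codes, rc$score_mat)
  if (is.null(min_score)) min_score <- -Inf
  hit_f <- which(!is.na(fwd) & fwd >= min_score)
  hit_r <- which(!is.na(rev_) & rev_ >= min_score)
  out <- data.frame(
    pos = c(hit_f, hit_r) - 1L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r]),
    stringsAsFactors = FALSE
  )
  if (need_p) {
    dist <- pwm_score_distribution(pwm, eps)
    binned_f <- window_scores(codes, round(pwm$score_mat / eps))
    binned_r <- window_scores(codes, round(rc$score_mat / eps))
    out$pvalue <- lookup_pvalue(dist, c(binned_f[hit_f], binned_r[hit_r]))
    if (!is.null(min_pvalue))
      out <- out[out$pvalue <= min_pvalue, , drop = FALSE]
  } else {
    out$pvalue <- NA_real_
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximal hit score of a PWM in a sequence (both strands)
#' @param seq DNA string.
#' @param pwm PWM object.
#' @return numeric; -Inf when no scannable window exists.
#' @export
max_pwm_score <- function(seq, pwm) {
  codes <- seq_to_codes(seq)
  s <- c(window_scores(codes, pwm$score_mat),
         window_scores(codes, revcomp_pwm(pwm)$score_mat))
  s <- s[!is.na(s)]
  if (!length(s)) -Inf else max(s)
}

#' Count scannable windows (both strands) of a motif width in sequences
#' @param seqs character vector of sequences.
#' @param width motif width.
#' @return integer total number of N-free windows over both strands.
#' @export
scannable_positions <- function(seqs, width) {
  sum(vapply(seqs, function(s) {
    codes <- seq_to_codes(s)
    n <- length(codes) - width + 1L
    if (n < 1L) return(0L)
    cs <- c(0L, cumsum(is.na(codes)))
    ok <- (cs[(width + 1L):(length(codes) + 1L)] - cs[1:n]) == 0L
    2L * sum(ok)
  }, integer(1L)))
}

#' ROC curve for region-level motif calibration
#'
#' A region is called positive at threshold x when it contains at least
#' one hit with score >= x; the curve is evaluated at every observed
#' region maximum score.
#'
#' @param pos_scores per-region maximum hit scores for bound regions.
#' @param neg_scores per-region maximum hit scores for background regions.
#' @return list with thresholds (decreasing), tpr, fpr, auc.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  thr <- thr[is.finite(thr)]
  tpr <- vapply(thr, function(x) mean(pos_scores >= x), 0)
  fpr <- vapply(thr, function(x) mean(neg_scores >= x), 0)
  # trapezoidal AUC over (fpr, tpr), extended to (0,0) and (1,1)
  xf <- c(0, fpr, 1); yf <- c(0, tpr, 1)
  auc <- sum(diff(xf) * (utils::head(yf, -1) + utils::tail(yf, -1)) / 2)
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Calibrate a per-species score threshold from bound/unbound regions
#'
#' Positive regions are fixed-width windows centered on bound-CRM peak
#' summits; negative regions are windows centered on a seeded random
#' position within each unbound CRM. The chosen threshold is the smallest
#' score with TPR in `[tpr_lo, tpr_hi]` and FPR <= `fpr_max` in the
#' better-AUC species; the other species receives the score that matches
#' that TPR.
#'
#' @param pwm PWM object.
#' @param bound_regions,unbound_regions character vectors of region
#'   sequences (already windowed, see [summit_windows()]).
#' @return list with the [roc_curve()] fields plus `region_scores`.
#' @export
calibrate_threshold <- function(pwm, bound_regions, unbound_regions) {
  if (length(bound_regions) < 20L || length(unbound_regions) < 20L)
    stop("need >= 20 regions per class")
  ps <- vapply(bound_regions, max_pwm_score, 0, pwm = pwm)
  ns <- vapply(unbound_regions, max_pwm_score, 0, pwm = pwm)
  c(roc_curve(ps, ns), list(pos_scores = unname(ps), neg_scores = unname(ns)))
}

#' Apply the two-species threshold selection rule to two ROC curves
#'
#' @param roc_a,roc_b [calibrate_threshold()] results for the two species.
#' @param tpr_lo,tpr_hi,fpr_max selection bounds (defaults 0.70, 0.80,
#'   0.40).
#' @return list with `threshold_a`, `threshold_b`, `best` ("a" or "b"),
#'   `tpr_at_choice`, and `feasible` (FALSE when no score satisfied the
#'   rule and the nearest-feasible score was used, with a warning).
#' @export
choose_thresholds <- function(roc_a, roc_b, tpr_lo = 0.70, tpr_hi = 0.80,
                              fpr_max = 0.40) {
  best <- if (roc_a$auc >= roc_b$auc) "a" else "b"
  rb <- if (best == "a") roc_a else roc_b
  ro <- if (best == "a") roc_b else roc_a
  ok <- rb$tpr >= tpr_lo & rb$tpr <= tpr_hi & rb$fpr <= fpr_max
  feasible <- any(ok)
  if (feasible) {
    # smallest qualifying score
    thr_best <- min(rb$thresholds[ok])
    tpr_target <- rb$tpr[which(rb$thresholds == thr_best)[1L]]
  } else {
    warning("no score satisfies the TPR/FPR rule; using nearest feasible")
    d <- pmax(tpr_lo - rb$tpr, 0) + pmax(rb$tpr - tpr_hi, 0) +
      pmax(rb$fpr - fpr_max, 0)
    i <- which.min(d)
    thr_best <- rb$thresholds[i]
    tpr_target <- rb$tpr[i]
  }
  io <- which.min(abs(ro$tpr - tpr_target))
  thr_other <- ro$thresholds[io]
  out <- list(best = best, tpr_at_choice = tpr_target, feasible = feasible)
  if (best == "a") {
    out$threshold_a <- thr_best; out$threshold_b <- thr_other
  } else {
    out$threshold_b <- thr_best; out$threshold_a <- thr_other
  }
  out
}

#' Extract fixed-width windows centered on positions within sequences
#'
#' @param seqs named character vector (chromosome sequences).
#' @param chrom,center vectors of chromosome names and 0-based center
#'   positions.
#' @param width window width in bp (default 200).
#' @return character vector of window sequences (clipped at chromosome
#'   bounds).
#' @export
summit_windows <- function(seqs, chrom, center, width = 200L) {
  half <- width %/% 2L
  vapply(seq_along(center), function(i) {
    L <- nchar(seqs[[chrom[i]]])
    s <- max(0L, center[i] - half)
    e <- min(L, center[i] + (width - half))
    substr(seqs[[chrom[i]]], s + 1L, e)
  }, "")
}
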