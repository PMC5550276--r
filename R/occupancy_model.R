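#' Thermodynamic predicted occupancy of a TF on a sequence
#'
#' One-free-parameter sequence-to-affinity model: every window i on both
#' strands contributes a relative affinity `K_i = exp(log-odds_i)`, and
#' the predicted occupancy is `sum_i gamma * K_i / (1 + gamma * K_i)`,
#' with `gamma > 0` a concentration-like parameter. Occupancy is 0 for
#' sequences shorter than the motif.
#'
#' @param seq DNA string.
#' @param pwm PWM object.
#' @param gamma positive scalar.
#' @return non-negative occupancy.
#' @export
predicted_occupancy <- function(seq, pwm, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  K <- site_affinities(seq, pwm)
  sum(gamma * K / (1 + gamma * K))
}

#' Window affinities K = exp(log-odds) over both strands
#' @param seq DNA string.
#' @param pwm PWM object.
#' @return numeric vector (N-containing windows dropped).
#' @export
site_affinities <- function(seq, pwm) {
  codes <- seq_to_codes(seq)
  s <- c(window_scores(codes, pwm$score_mat),
         window_scores(codes, revcomp_pwm(pwm)$score_mat))
  exp(s[!is.na(s)])
}

occupancy_from_K <- function(K_list, gamma) {
  occ_flat(flatten_K(K_list), gamma)
}

flatten_K <- function(K_list) {
  list(K = unlist(K_list, use.names = FALSE),
       grp = rep(seq_along(K_list), lengths(K_list)),
       n = length(K_list))
}

occ_flat <- function(fl, gamma) {
  out <- numeric(fl$n)
  if (length(fl$K)) {
    s <- rowsum(gamma * fl$K / (1 + gamma * fl$K), fl$grp)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Clip-and-scale score normalization
#'
#' Scores above `mu + 3 sigma` (mean and SD of the input, or of the set
#' the params were learned on) are replaced by that cap, then min-max
#' scaled to `[0, 1]`. Applied separately to each data set (ChIP and
#' model scores). When `params` is supplied the transformation is applied
#' forward and outputs are clamped to `[0, 1]`.
#'
#' @param scores numeric vector with at least 2 distinct values (when
#'   learning params).
#' @param params optional previously learned parameters.
#' @return list with `scores` (normalized) and `params` (mu, sigma, cap,
#'   min, max).
#' @export
normalize_scores <- function(scores, params = NULL) {
  if (is.null(params)) {
    if (length(unique(scores)) < 2L)
      stop("constant input: normalization undefined (min = max)")
    mu <- mean(scores); sigma <- stats::sd(scores)
    cap <- mu + 3 * sigma
    clipped <- pmin(scores, cap)
    params <- list(mu = mu, sigma = sigma, cap = cap,
                   min = min(clipped), max = max(clipped))
  }
  clipped <- pmin(scores, params$cap)
  out <- (clipped - params$min) / (params$max - params$min)
  out <- pmin(pmax(out, 0), 1)
  list(scores = out, params = params)
}

fit_gamma <- function(K_list, chip_norm) {
  fl <- flatten_K(K_list)
  obj <- function(g) {
    pred <- occ_flat(fl, g)
    if (max(pred) == min(pred)) return(sum((chip_norm - mean(chip_norm))^2))
    pn <- normalize_scores(pred)$scores
    sum((pn - chip_norm)^2)
  }
  grid <- 10^seq(-5, 2, by = 0.25)
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)
  widened <- FALSE
  if (i == 1L || i == length(grid)) {
    grid <- 10^seq(-8, 4, by = 0.25)
    vals <- vapply(grid, obj, 0)
    i <- which.min(vals)
    widened <- TRUE
    if (i == 1L || i == length(grid))
      warning("gamma optimizer at grid boundary")
  }
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  op <- stats::optimize(function(lg) obj(exp(lg)), c(log(lo), log(hi)))
  gamma <- exp(op$minimum)
  if (op$objective > vals[i]) gamma <- grid[i]  # keep the grid best
  list(gamma = gamma, objective = min(op$objective, vals[i]),
       grid = grid, grid_objectives = vals, widened = widened)
}

#' Train the one-parameter occupancy model
#'
#' The training set is the top peaks plus length-matched random windows
#' with their measured ChIP scores. ChIP scores are clip-normalized; the
#' free parameter gamma is fit by minimizing the squared error between
#' clip-normalized predicted occupancies and normalized ChIP scores
#' (log-spaced grid search refined by 1-D optimization).
#'
#' @param seqs character vector of training sequences (peak regions and
#'   random windows).
#' @param chip_scores their ChIP scores (same order).
#' @param pwm the TF's PWM.
#' @return object of class `stap_model`: pwm name, gamma, normalization
#'   params for ChIP and model scores, in-sample Pearson correlation, and
#'   the fit diagnostics.
#' @export
train_stap <- function(seqs, chip_scores, pwm) {
  stopifnot(length(seqs) == length(chip_scores))
  K_list <- lapply(seqs, site_affinities, pwm = pwm)
  cn <- normalize_scores(chip_scores)
  fit <- fit_gamma(K_list, cn$scores)
  pred <- occupancy_from_K(K_list, fit$gamma)
  sn <- normalize_scores(pred)
  pcc <- stats::cor(sn$scores, cn$scores)
  structure(list(pwm_name = pwm$name, pwm = pwm, gamma = fit$gamma,
                 norm_chip = cn$params, norm_stap = sn$params,
                 fit_pcc = pcc, objective = fit$objective,
                 grid = fit$grid, grid_objectives = fit$grid_objectives),
            class = "stap_model")
}

#' Score sequences with a trained occupancy model
#'
#' Predicted occupancies normalized forward with the model's
#' training-set parameters.
#'
#' @param model a [train_stap()] model.
#' @param seqs character vector.
#' @return numeric normalized model scores in `[0, 1]`.
#' @export
stap_scores <- function(model, seqs) {
  pred <- vapply(seqs, predicted_occupancy, 0, pwm = model$pwm,
                 gamma = model$gamma)
  normalize_scores(pred, model$norm_stap)$scores
}

#' k-fold cross-validation of the occupancy model
#'
#' Seeded fold assignment over the training segments; each fold fits
#' gamma on the remainder and scores the held-out segments; the pooled
#' held-out predictions are compared to the ChIP scores by Pearson
#' correlation. Folds with constant held-out truth are excluded from the
#' per-fold report with a warning.
#'
#' @param seqs,chip_scores,pwm as in [train_stap()].
#' @param folds number of folds (default 4).
#' @param seed fold-assignment seed.
#' @return list with per_fold_pcc, pooled_pcc, fold (assignments),
#'   predictions.
#' @export
crossvalidate_stap <- function(seqs, chip_scores, pwm, folds = 4,
                               seed = 1) {
  n <- length(seqs)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  K_list <- lapply(seqs, site_affinities, pwm = pwm)
  pred <- numeric(n)
  per_fold <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    cn <- normalize_scores(chip_scores[tr])
    fit <- fit_gamma(K_list[tr], cn$scores)
    ptrain <- occupancy_from_K(K_list[tr], fit$gamma)
    sn <- normalize_scores(ptrain)
    pheld <- occupancy_from_K(K_list[!tr], fit$gamma)
    pred[!tr] <- normalize_scores(pheld, sn$params)$scores
    if (length(unique(chip_scores[!tr])) < 2L) {
      warning("fold ", f, " has constant held-out truth; PCC undefined")
    } else {
      per_fold[f] <- stats::cor(pred[!tr], chip_scores[!tr])
    }
  }
  pooled <- stats::cor(pred, chip_scores)
  list(per_fold_pcc = per_fold, pooled_pcc = pooled, fold = fold,
       predictions = pred)
}

#' Interspecies divergence analysis of occupancy vs motif content
#'
#' For each orthologous pair, `dChip = ChIP_sp1 - ChIP_sp2` and `dStap =
#' STAP_sp1 - STAP_sp2` (normalized units), z-standardized within the
#' analysis set. Quadrants follow the scatter-plot convention:
#' red = `z_dStap > 1.5` and `|z_dChip| < 0.7` (motif lost, occupancy
#' kept: TF-collective signature); green = `z_dChip > 1.5` and
#' `|z_dStap| < 0.7` (occupancy lost, motif kept: cooperative
#' recruitment). Per complexity class, the Spearman correlation of dStap
#' and dChip is reported; classes are compared by the Fisher
#' z-transformation, and quadrant excess in HighBound vs Singletons by a
#' one-sided Fisher exact test.
#'
#' @param chip_a,chip_b normalized per-pair ChIP scores for the TF in
#'   each species.
#' @param stap_a,stap_b normalized per-pair model scores.
#' @param class complexity class per pair (see [complexity_class()]).
#' @param ids pair identifiers.
#' @return list with `records` (per-pair data.frame), `spearman` (per
#'   class, NA when n < 5), `fisher_z_p` (HighBound vs Singleton,
#'   two-sided), `quadrant_fisher_p` (one-sided, red), and quadrant
#'   counts.
#' @export
delta_analysis <- function(chip_a, chip_b, stap_a, stap_b, class,
                           ids = seq_along(chip_a)) {
  dchip <- chip_a - chip_b
  dstap <- stap_a - stap_b
  z_dchip <- as.numeric(scale(dchip))
  z_dstap <- as.numeric(scale(dstap))
  quadrant <- ifelse(z_dstap > 1.5 & abs(z_dchip) < 0.7, "red",
                     ifelse(z_dchip > 1.5 & abs(z_dstap) < 0.7, "green",
                            "other"))
  records <- data.frame(id = ids, dchip = dchip, dstap = dstap,
                        z_dchip = z_dchip, z_dstap = z_dstap,
                        class = as.character(class), quadrant = quadrant,
                        stringsAsFactors = FALSE)
  cls <- c("Singleton", "LowBound", "HighBound")
  spearman <- vapply(cls, function(cc) {
    i <- records$class == cc
    if (sum(i) < 5L) return(NA_real_)
    stats::cor(dstap[i], dchip[i], method = "spearman")
  }, 0)
  nn <- vapply(cls, function(cc) sum(records$class == cc), 0)
  fisher_z_p <- NA_real_
  if (!is.na(spearman["Singleton"]) && !is.na(spearman["HighBound"])) {
    z <- if (spearman["Singleton"] == spearman["HighBound"]) 0 else
      (atanh(spearman["Singleton"]) - atanh(spearman["HighBound"])) /
      sqrt(1 / (nn["Singleton"] - 3) + 1 / (nn["HighBound"] - 3))
    fisher_z_p <- unname(2 * stats::pnorm(-abs(z)))
  }
  qtab <- table(factor(records$class, levels = cls),
                factor(records$quadrant, levels = c("red", "green",
                                                    "other")))
  quad_p <- function(colr) {
    tab <- matrix(c(qtab["HighBound", colr],
                    sum(qtab["HighBound", ]) - qtab["HighBound", colr],
                    qtab["Singleton", colr],
                    sum(qtab["Singleton", ]) - qtab["Singleton", colr]),
                  2L, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(records = records, spearman = spearman, n = nn,
       fisher_z_p = fisher_z_p,
       quadrant_counts = qtab,
       quadrant_fisher_p = quad_p("red"),
       quadrant_fisher_p_green = quad_p("green"))
}
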