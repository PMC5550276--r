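#' Binary binding matrix over CRMs
#'
#' A cell is 1 when at least one peak summit of that condition falls
#' inside the CRM interval (summit containment, consistent with
#' summit-based CRM construction).
#'
#' @param crms data.frame id, chrom, start, end.
#' @param peaks data.frame chrom, summit, condition.
#' @param conditions character vector defining the shared condition
#'   universe (column order).
#' @return integer 0/1 matrix, CRM ids in rows, conditions in columns.
#' @export
binding_matrix <- function(crms, peaks, conditions) {
  m <- matrix(0L, nrow(crms), length(conditions),
              dimnames = list(crms$id, conditions))
  gr_c <- GenomicRanges::GRanges(crms$chrom,
                                 IRanges::IRanges(crms$start + 1L, crms$end))
  gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$summit + 1L,
                                                  peaks$summit + 1L))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_c)
  i <- S4Vectors::subjectHits(hits)
  j <- match(peaks$condition[S4Vectors::queryHits(hits)], conditions)
  ok <- !is.na(j)
  m[cbind(i[ok], j[ok])] <- 1L
  m
}

#' Jaccard binding-conservation record for one orthologous pair
#'
#' `J = |intersection| / |union|` over the shared condition universe.
#' Categories: strong (J >= 0.5), intermediate (0 < J < 0.5), none
#' (J = 0); pairs bound at exactly one condition in each species are
#' flagged `excluded_singleton` regardless of whether the conditions
#' match (mismatches are reported via `singleton_match`).
#'
#' @param bound_a,bound_b character vectors of bound conditions per
#'   species.
#' @return list with J, category, n_events_a, n_events_b,
#'   singleton_match.
#' @export
jaccard_conservation <- function(bound_a, bound_b) {
  bound_a <- unique(bound_a); bound_b <- unique(bound_b)
  if (length(bound_a) + length(bound_b) == 0L)
    stop("empty condition union: pair should not exist")
  J <- length(intersect(bound_a, bound_b)) /
    length(union(bound_a, bound_b))
  singleton <- length(bound_a) == 1L && length(bound_b) == 1L
  category <- if (singleton) "excluded_singleton"
    else if (J >= 0.5) "strong"
    else if (J > 0) "intermediate"
    else "none"
  list(J = J, category = category,
       n_events_a = length(bound_a), n_events_b = length(bound_b),
       singleton_match = if (singleton) bound_a == bound_b else NA)
}

#' Conservation records for a set of orthologous pairs
#'
#' @param pairs data.frame with id_a, id_b.
#' @param bm_a,bm_b per-species binding matrices (shared columns) whose
#'   rows cover the pair ids.
#' @return data.frame pair_id, id_a, id_b, J, category, n_events_a,
#'   n_events_b, singleton_match.
#' @export
conservation_records <- function(pairs, bm_a, bm_b) {
  conds <- colnames(bm_a)
  stopifnot(identical(conds, colnames(bm_b)))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- conds[bm_a[pairs$id_a[i], ] == 1L]
    b <- conds[bm_b[pairs$id_b[i], ] == 1L]
    if (length(a) + length(b) == 0L) return(NULL)
    rec <- jaccard_conservation(a, b)
    data.frame(pair_id = paste(pairs$id_a[i], pairs$id_b[i], sep = "|"),
               id_a = pairs$id_a[i], id_b = pairs$id_b[i],
               J = rec$J, category = rec$category,
               n_events_a = rec$n_events_a, n_events_b = rec$n_events_b,
               singleton_match = rec$singleton_match,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

bin_events <- function(n, max_bin = 5L) {
  cut(pmin(n, max_bin), breaks = c(0:(max_bin - 1L) + 0.5, Inf),
      labels = c(as.character(seq_len(max_bin - 1L)),
                 paste0(max_bin, "+")))
}

#' Binding-complexity association between conservation categories
#'
#' Chi-square test, per pairwise category comparison, of the distribution
#' of the total number of species-1 binding events (binned 1, 2, ...,
#' `max_bin`+). Falls back to a Fisher exact test with a warning when any
#' expected cell is below 1.
#'
#' @param records [conservation_records()] output.
#' @param n_events_a total binding events per pair in species 1; defaults
#'   to the records' `n_events_a` column.
#' @param categories categories to compare.
#' @param max_bin top bin (counts >= max_bin pooled).
#' @return data.frame cat1, cat2, statistic, df, p, method.
#' @export
complexity_association <- function(records, n_events_a = records$n_events_a,
                                   categories = c("strong", "intermediate",
                                                  "none"),
                                   max_bin = 5L) {
  present <- intersect(categories, unique(records$category))
  if (length(present) < 2L) stop("need >= 2 populated categories")
  bins <- bin_events(n_events_a, max_bin)
  combs <- utils::combn(present, 2L)
  out <- lapply(seq_len(ncol(combs)), function(k) {
    c1 <- combs[1L, k]; c2 <- combs[2L, k]
    sel <- records$category %in% c(c1, c2)
    tab <- table(records$category[sel], bins[sel])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    suppressWarnings(ct <- stats::chisq.test(tab))
    if (any(ct$expected < 1)) {
      warning("expected cell < 1; using Fisher exact test for ",
              c1, " vs ", c2)
      ft <- stats::fisher.test(tab, workspace = 2e7)
      data.frame(cat1 = c1, cat2 = c2, statistic = NA_real_,
                 df = NA_real_, p = ft$p.value, method = "fisher",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cat1 = c1, cat2 = c2,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 method = "chisq", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Enhancer-activity enrichment by conservation category
#'
#' Per category, a 2x2 Fisher exact test of (mesoderm vs other activity)
#' x (this category vs the rest), with the odds ratio; plus an overall
#' two-sided k-sample proportions test of the mesoderm fraction across
#' categories. CRMs labelled "none" (untested / no activity) are
#' excluded.
#'
#' @param records [conservation_records()] output.
#' @param activity per-pair activity label in mesoderm/other/none,
#'   aligned with records rows.
#' @param categories categories to test.
#' @return list with `per_category` (data.frame category, n_meso,
#'   n_other, odds_ratio, haldane_or, p) and `overall_p`.
#' @export
activity_enrichment <- function(records, activity,
                                categories = c("strong", "intermediate",
                                               "none")) {
  lab <- activity[records$category %in% categories]
  cat <- records$category[records$category %in% categories]
  keep <- lab %in% c("mesoderm", "other")
  lab <- lab[keep]; cat <- cat[keep]
  if (!length(lab)) stop("no labelled CRMs")
  per <- lapply(categories, function(cc) {
    if (!any(cat == cc)) return(NULL)
    tab <- matrix(c(sum(lab == "mesoderm" & cat == cc),
                    sum(lab == "mesoderm" & cat != cc),
                    sum(lab == "other" & cat == cc),
                    sum(lab == "other" & cat != cc)), 2L, 2L)
    ft <- stats::fisher.test(tab)
    hor <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    data.frame(category = cc, n_meso = tab[1, 1], n_other = tab[2, 1],
               odds_ratio = unname(ft$estimate), haldane_or = hor,
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  x <- vapply(per$category, function(cc) sum(lab == "mesoderm" & cat == cc),
              0)
  n <- vapply(per$category, function(cc) sum(cat == cc), 0)
  overall <- if (nrow(per) >= 2L)
    suppressWarnings(stats::prop.test(x, n)$p.value) else NA_real_
  list(per_category = per, overall_p = overall)
}

#' Mean conservation-score profile around CRM centers, by category
#'
#' Position-wise mean of a per-base score track across CRMs anchored at
#' the CRM center, with standard errors. Positions missing from the track
#' are dropped from that offset's denominator.
#'
#' @param records [conservation_records()] output.
#' @param crms data.frame id, chrom, start, end covering `records$id_a`.
#' @param track data.frame chrom, pos (0-based), score.
#' @param flank half-width of the profile in bp.
#' @param categories categories to profile.
#' @return data.frame category, offset, mean, se, n.
#' @export
conservation_profile <- function(records, crms, track, flank = 500,
                                 categories = c("strong", "intermediate",
                                                "none")) {
  tr <- split(track, track$chrom)
  vecs <- lapply(tr, function(d) {
    v <- rep(NA_real_, max(d$pos) + 1L)
    v[d$pos + 1L] <- d$score
    v
  })
  centers <- (crms$start + crms$end) %/% 2
  names(centers) <- crms$id
  chroms <- stats::setNames(crms$chrom, crms$id)
  offs <- (-flank):flank
  out <- lapply(categories, function(cc) {
    ids <- records$id_a[records$category == cc]
    if (!length(ids)) return(NULL)
    mat <- vapply(ids, function(id) {
      v <- vecs[[chroms[id]]]
      p <- centers[id] + offs + 1L
      ok <- p >= 1L & p <= length(v)
      res <- rep(NA_real_, length(offs))
      res[ok] <- v[p[ok]]
      res
    }, numeric(length(offs)))
    n <- rowSums(!is.na(mat))
    mu <- rowMeans(mat, na.rm = TRUE)
    se <- apply(mat, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1L))
    se[n <= 1L] <- 0
    data.frame(category = cc, offset = offs, mean = mu, se = se, n = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward clustering of cross-species quantitative ChIP signal
#'
#' Rows (orthologous CRMs) of the concatenated species-1 + species-2
#' signal matrix are clustered with Ward linkage on the correlation
#' distance `d = 1 - Pearson(row_i, row_j)`. Zero-variance rows (Pearson
#' undefined) are assigned distance 1 to everything and flagged.
#'
#' @param signal_a,signal_b per-species signal matrices with identical
#'   row ids (pair-aligned) and the per-species condition columns.
#' @param ids optional row subset.
#' @return list with `hclust`, `order` (leaf ids), `newick` string and
#'   `flagged` (zero-variance row ids).
#' @export
cluster_signal <- function(signal_a, signal_b, ids = rownames(signal_a)) {
  x <- cbind(signal_a[ids, , drop = FALSE], signal_b[ids, , drop = FALSE])
  if (anyNA(x)) stop("missing cells in signal matrix")
  v <- apply(x, 1L, stats::var)
  flagged <- rownames(x)[v == 0]
  r <- suppressWarnings(stats::cor(t(x)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
  ord <- rownames(x)[hc$order]
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = ord, newick = nwk, flagged = flagged)
}
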