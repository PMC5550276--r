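#' Binding-complexity class of a CRM
#'
#' Singletons are bound by 1 TF in species 1, Low Bound by 2-3, High
#' Bound by 4-5.
#'
#' @param n_tfs number of distinct TFs bound in species 1.
#' @return factor with levels Singleton, LowBound, HighBound.
#' @export
complexity_class <- function(n_tfs) {
  factor(ifelse(n_tfs >= 4L, "HighBound",
                ifelse(n_tfs >= 2L, "LowBound", "Singleton")),
         levels = c("Singleton", "LowBound", "HighBound"))
}

#' TFBS density per CRM, by conservation of the TF's binding
#'
#' For CRMs bound by the TF, hits are counted in the union of 100 bp
#' windows around the TF's peak summits; for unbound CRMs, in one 200 bp
#' window placed uniformly at random (seeded) within the CRM. Density is
#' hits per kb of counted window. CRMs shorter than the window are used
#' whole and flagged.
#'
#' @param crms data.frame id, chrom, start, end (extended coordinates).
#' @param hits motif hits data.frame with chrom, pos (0-based window
#'   start) as from [scan_pwm()] run genome-wide at the calibrated
#'   threshold.
#' @param summits data.frame id (CRM), summit for the TF's peaks (bound
#'   CRMs only).
#' @param bound logical per CRM row: TF bound in this species.
#' @param seed RNG seed for the random unbound windows.
#' @param bound_window,unbound_window window sizes (bp).
#' @return data.frame id, bound, window_bp, n_hits, density (hits/kb),
#'   flagged_short.
#' @export
tfbs_density <- function(crms, hits, summits, bound, seed = 1,
                         bound_window = 100L, unbound_window = 200L) {
  hit_gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$pos + 1L,
                                                    hits$pos + 1L))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(crms)), function(i) {
      if (bound[i]) {
        sm <- summits$summit[summits$id == crms$id[i]]
        if (!length(sm)) return(NULL)
        iv <- IRanges::reduce(IRanges::IRanges(
          pmax(sm - bound_window %/% 2L, crms$start[i]) + 1L,
          pmin(sm + bound_window %/% 2L, crms$end[i])))
        flagged <- FALSE
      } else {
        len <- crms$end[i] - crms$start[i]
        if (len <= unbound_window) {
          iv <- IRanges::IRanges(crms$start[i] + 1L, crms$end[i])
          flagged <- TRUE
        } else {
          s <- crms$start[i] + sample.int(len - unbound_window, 1L)
          iv <- IRanges::IRanges(s + 1L, s + unbound_window)
          flagged <- FALSE
        }
      }
      gr <- GenomicRanges::GRanges(crms$chrom[i], iv)
      nh <- length(unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(hit_gr, gr))))
      wbp <- sum(IRanges::width(iv))
      data.frame(id = crms$id[i], bound = bound[i], window_bp = wbp,
                 n_hits = nh, density = nh / (wbp / 1000),
                 flagged_short = flagged, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Genome-wide background TFBS density
#' @param hits genome-wide hits at the calibrated threshold.
#' @param genome_bp total scanned genome length in bp.
#' @return hits per kb.
#' @export
genome_background_density <- function(hits, genome_bp) {
  nrow(hits) / (genome_bp / 1000)
}

#' Temporally restricted (early / late) bound CRM classes for one TF
#'
#' Early CRMs are bound at the early time point, unbound at every later
#' condition of the TF, and show a linear-scale signal ratio
#' `2^(log2_early - log2_late) > 2`; late CRMs symmetrically. CRMs with
#' missing signal are excluded and counted.
#'
#' @param binding binary CRM x condition matrix.
#' @param signal log2 CRM x condition matrix (same shape).
#' @param tf TF name.
#' @param conditions data.frame(tf, tp, condition) giving the TF's
#'   ordered conditions.
#' @param early_tp,late_tp time points; default first and last condition
#'   of the TF.
#' @return list with `early`, `late` (CRM ids) and `n_excluded_missing`.
#' @export
temporal_classes <- function(binding, signal, tf, conditions,
                             early_tp = NULL, late_tp = NULL) {
  cc <- conditions[conditions$tf == tf, , drop = FALSE]
  if (nrow(cc) < 2L) stop("TF needs at least two conditions")
  early_tp <- early_tp %||% cc$tp[1L]
  late_tp <- late_tp %||% cc$tp[nrow(cc)]
  ce <- paste(tf, early_tp, sep = "_")
  cl <- paste(tf, late_tp, sep = "_")
  stopifnot(ce %in% colnames(binding), cl %in% colnames(binding))
  ei <- which(cc$tp == early_tp); li <- which(cc$tp == late_tp)
  if (!length(ei) || !length(li) || ei >= li)
    stop("early_tp must precede late_tp among the TF's conditions")
  later <- cc$condition[(ei + 1L):nrow(cc)]
  earlier <- cc$condition[seq_len(li - 1L)]
  miss <- is.na(signal[, ce]) | is.na(signal[, cl])
  lr <- signal[, ce] - signal[, cl]  # log2 early/late
  early <- binding[, ce] == 1L &
    rowSums(binding[, later, drop = FALSE]) == 0L & !miss & lr > 1
  late <- binding[, cl] == 1L &
    rowSums(binding[, earlier, drop = FALSE]) == 0L & !miss & -lr > 1
  list(early = rownames(binding)[early], late = rownames(binding)[late],
       n_excluded_missing = sum(miss))
}

#' Differential motif enrichment between early- and late-bound CRMs
#'
#' Re-implementation of total-hits Fisher scoring: per motif, hits with
#' exact p-value <= `match_pvalue` are counted over both strands in each
#' sequence set; the Fisher exact test is applied to
#' `[hits_early, positions_early - hits_early; hits_late,
#' positions_late - hits_late]` with positions = scannable windows (both
#' strands). Reported motifs need `p <= enrich_p` and `|log2 R| > 1`
#' where `R = (hits/kb early) / (hits/kb late)`; a zero count gets a
#' continuity correction of 0.5 hits on both sides for R. Motifs with
#' identical probability matrices are de-duplicated.
#'
#' @param early_seqs,late_seqs character vectors of CRM sequences.
#' @param motif_library list of PWMs (e.g. from [read_meme()]).
#' @param match_pvalue hit-calling exact p-value threshold.
#' @param enrich_p Fisher p threshold for reporting.
#' @return list with `table` (all motifs) and `reported` (filtered rows).
#' @export
differential_enrichment <- function(early_seqs, late_seqs, motif_library,
                                    match_pvalue = 1e-4, enrich_p = 0.05) {
  if (!length(early_seqs) || !length(late_seqs))
    stop("both sequence sets must be non-empty")
  # de-duplicate motifs by matrix identity
  keys <- vapply(motif_library, function(p)
    paste(sprintf("%.6f", p$mat), collapse = ","), "")
  motif_library <- motif_library[!duplicated(keys)]
  kb_e <- sum(nchar(early_seqs)) / 1000
  kb_l <- sum(nchar(late_seqs)) / 1000
  rows <- lapply(motif_library, function(pwm) {
    w <- nrow(pwm$mat)
    he <- sum(vapply(early_seqs, function(s)
      nrow(scan_pwm(s, pwm, min_pvalue = match_pvalue)), 0L))
    hl <- sum(vapply(late_seqs, function(s)
      nrow(scan_pwm(s, pwm, min_pvalue = match_pvalue)), 0L))
    pe <- scannable_positions(early_seqs, w)
    pl <- scannable_positions(late_seqs, w)
    tab <- matrix(c(he, pe - he, hl, pl - hl), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    re <- he / kb_e; rl <- hl / kb_l
    R <- if (hl == 0L || he == 0L)
      ((he + 0.5) / kb_e) / ((hl + 0.5) / kb_l) else re / rl
    data.frame(motif = pwm$name, hits_early = he, hits_late = hl,
               kb_early = kb_e, kb_late = kb_l,
               positions_early = pe, positions_late = pl,
               R = R, log2R = log2(R), fisher_p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  reported <- tab[tab$fisher_p <= enrich_p & abs(tab$log2R) > 1, ,
                  drop = FALSE]
  list(table = tab, reported = reported)
}

#' Extract CRM sequences from chromosome sequences
#' @param seqs named character vector of chromosome sequences.
#' @param crms data.frame chrom, start, end (0-based half-open), id.
#' @return named character vector of CRM sequences.
#' @export
crm_sequences <- function(seqs, crms) {
  out <- vapply(seq_len(nrow(crms)), function(i)
    substr(seqs[[crms$chrom[i]]], crms$start[i] + 1L, crms$end[i]), "")
  names(out) <- crms$id
  out
}
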