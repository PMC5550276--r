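#' Cluster ChIP peak summits into cis-regulatory modules
#'
#' Single-linkage clustering of summits per chromosome: adjacent summits
#' at most `max_gap` bp apart join the same cluster; each cluster becomes
#' the interval `[min_summit - pad, max_summit + pad)`, clipped at
#' chromosome bounds, and any intervals overlapping after padding are
#' merged.
#'
#' @param peaks data.frame with chrom, summit, condition columns (see
#'   [read_narrowpeak()]).
#' @param max_gap maximum distance between adjacent summits (bp).
#' @param pad bp added on each side of the summit span.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, summits outside their chromosome raise an error naming the
#'   peak.
#' @param id_prefix prefix for CRM identifiers.
#' @return list with `crms` (data.frame id, chrom, start, end, n_summits)
#'   and `members` (data.frame crm_id, condition, summit).
#' @export
cluster_summits <- function(peaks, max_gap = 400, pad = 100,
                            chrom_sizes = NULL, id_prefix = "crm") {
  stopifnot(all(c("chrom", "summit") %in% names(peaks)))
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (!is.null(chrom_sizes)) {
    bad <- peaks$summit < 0 | peaks$summit >= chrom_sizes[peaks$chrom]
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[1L]
      stop(sprintf("summit %d outside chromosome %s (peak %d)",
                   peaks$summit[i], peaks$chrom[i], i))
    }
  }
  if (!"condition" %in% names(peaks)) peaks$condition <- NA_character_
  ord <- order(peaks$chrom, peaks$summit)
  pk <- peaks[ord, , drop = FALSE]
  new_cluster <- c(TRUE, diff(pk$summit) > max_gap |
                     pk$chrom[-1L] != pk$chrom[-nrow(pk)])
  cl <- cumsum(new_cluster)
  start <- tapply(pk$summit, cl, min) - pad
  end <- tapply(pk$summit, cl, max) + pad
  chrom <- tapply(pk$chrom, cl, `[`, 1L)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) end <- pmin(end, chrom_sizes[chrom])
  # merge any CRMs overlapping after padding
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), cl = as.integer(names(start)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  merge_new <- c(TRUE, !(df$start[-1L] < df$end[-nrow(df)] &
                           df$chrom[-1L] == df$chrom[-nrow(df)]))
  grp <- cumsum(merge_new)  # 1..G in (chrom, start) order
  out <- data.frame(
    chrom = as.character(tapply(df$chrom, grp, `[`, 1L)),
    start = as.numeric(tapply(df$start, grp, min)),
    end = as.numeric(tapply(df$end, grp, max)),
    stringsAsFactors = FALSE
  )
  out$id <- sprintf("%s_%05d", id_prefix, seq_len(nrow(out)))
  cl_to_grp <- stats::setNames(grp, df$cl)  # original cluster -> group
  members <- data.frame(
    crm_id = out$id[cl_to_grp[as.character(cl)]],
    condition = pk$condition, summit = pk$summit,
    stringsAsFactors = FALSE
  )
  out$n_summits <- as.integer(table(members$crm_id)[out$id])
  rownames(out) <- NULL
  list(crms = out[, c("id", "chrom", "start", "end", "n_summits")],
       members = members)
}

#' Validate an alignment block map
#'
#' Blocks must be non-overlapping and strictly ordered on the source, and
#' ungapped (when a `tgt_end` column is present, target length must equal
#' source length).
#'
#' @param map block map data.frame.
#' @return the map, invisibly; errors on violation.
#' @export
validate_block_map <- function(map) {
  stopifnot(all(c("src_chrom", "src_start", "src_end", "tgt_chrom",
                  "tgt_start", "strand") %in% names(map)))
  if (any(map$src_end <= map$src_start)) stop("empty block in map")
  if ("tgt_end" %in% names(map)) {
    bad <- (map$tgt_end - map$tgt_start) != (map$src_end - map$src_start)
    if (any(bad))
      stop("malformed block: src length != target length (row ",
           which(bad)[1L], ")")
  }
  sp <- split(map, map$src_chrom)
  for (m in sp) {
    o <- order(m$src_start)
    if (any(m$src_start[o][-1L] < m$src_end[o][-nrow(m)]))
      stop("blocks overlap on source chromosome ", m$src_chrom[1L])
  }
  invisible(map)
}

translate_one <- function(start, end, blocks) {
  # blocks: subset on one src chromosome, sorted by src_start
  ov <- which(blocks$src_start < end & blocks$src_end > start)
  if (!length(ov)) return(NULL)
  b <- blocks[ov, , drop = FALSE]
  os <- pmax(b$src_start, start)
  oe <- pmin(b$src_end, end)
  plus <- b$strand != "-"
  ts <- ifelse(plus, b$tgt_start + (os - b$src_start),
               b$tgt_start + (b$src_end - oe))
  te <- ts + (oe - os)
  data.frame(tgt_chrom = b$tgt_chrom, start = ts, end = te,
             stringsAsFactors = FALSE)
}

merge_intervals <- function(df, merge_dist = 0) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df <- df[order(df$tgt_chrom, df$start), , drop = FALSE]
  new <- c(TRUE, df$start[-1L] > df$end[-nrow(df)] + merge_dist |
             df$tgt_chrom[-1L] != df$tgt_chrom[-nrow(df)])
  g <- cumsum(new)
  data.frame(
    tgt_chrom = tapply(df$tgt_chrom, g, `[`, 1L),
    start = as.numeric(tapply(df$start, g, min)),
    end = as.numeric(tapply(df$end, g, max)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Translate an interval through an alignment block map
#'
#' Per-base image of the interval under the block map, merged into
#' maximal target intervals. Bases falling in unaligned gaps are dropped;
#' `mapped_fraction` is the fraction of source bases with an image.
#' Minus-strand blocks reverse coordinates within the block.
#'
#' @param chrom,start,end source interval (0-based half-open).
#' @param map validated block map.
#' @return list with `intervals` (data.frame tgt_chrom, start, end) and
#'   `mapped_fraction`.
#' @export
translate_interval <- function(chrom, start, end, map) {
  validate_block_map(map)
  blocks <- map[map$src_chrom == chrom, , drop = FALSE]
  blocks <- blocks[order(blocks$src_start), , drop = FALSE]
  pieces <- translate_one(start, end, blocks)
  if (is.null(pieces)) {
    return(list(intervals = data.frame(tgt_chrom = character(0),
                                       start = numeric(0), end = numeric(0)),
                mapped_fraction = 0))
  }
  mapped <- sum(pieces$end - pieces$start)
  list(intervals = merge_intervals(pieces),
       mapped_fraction = mapped / (end - start))
}

#' Translate a table of CRMs through a block map
#'
#' Vectorized [translate_interval()] over many CRMs; a CRM counts as
#' translated when `mapped_fraction > 0` and uniquely mapped when its
#' pieces fall on one target chromosome within `merge_dist` of each
#' other.
#'
#' @param crms data.frame with id, chrom, start, end.
#' @param map block map.
#' @param merge_dist bp within which translated pieces are merged into a
#'   single locus (default 1000).
#' @return data.frame id, tgt_chrom, start, end, mapped_fraction, unique;
#'   multi-mapped CRMs contribute one row per locus with unique = FALSE.
#' @export
translate_crms <- function(crms, map, merge_dist = 1000) {
  validate_block_map(map)
  sp <- split(map[order(map$src_start), , drop = FALSE], map$src_chrom)
  out <- vector("list", nrow(crms))
  for (i in seq_len(nrow(crms))) {
    blocks <- sp[[crms$chrom[i]]]
    pieces <- if (is.null(blocks)) NULL
      else translate_one(crms$start[i], crms$end[i], blocks)
    if (is.null(pieces) || !nrow(pieces)) next
    mf <- sum(pieces$end - pieces$start) / (crms$end[i] - crms$start[i])
    loci <- merge_intervals(pieces, merge_dist = merge_dist)
    out[[i]] <- data.frame(id = crms$id[i], tgt_chrom = loci$tgt_chrom,
                           start = loci$start, end = loci$end,
                           mapped_fraction = mf,
                           unique = nrow(loci) == 1L,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = character(0), tgt_chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      mapped_fraction = numeric(0), unique = logical(0))
  rownames(res) <- NULL
  res
}

union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  list(find = find, union = union)
}

#' Derive the conservative one-to-one orthologous CRM pair set
#'
#' Builds the bipartite overlap graph (>= `min_overlap` bp) between
#' species-1 CRMs and uniquely translated species-2 CRMs, and keeps only
#' connected components containing exactly one CRM of each species;
#' components involving more than one CRM of either species are discarded
#' as `multi_clusters`.
#'
#' @param crms_a species-1 (reference-coordinate) CRMs: data.frame id,
#'   chrom, start, end.
#' @param crms_b_translated translated species-2 CRMs in the same
#'   coordinates, as from [translate_crms()] (only `unique` loci are
#'   used).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list with `pairs` (data.frame id_a, id_b, overlap_bp,
#'   overlap_frac of the shorter CRM, len_a, len_b, plus coordinates),
#'   `multi_clusters` (component membership of discarded CRMs) and
#'   `summary` (counts, percentages, median overlap).
#' @export
pair_orthologs <- function(crms_a, crms_b_translated, min_overlap = 1) {
  if (anyDuplicated(crms_a$id)) stop("duplicate CRM ids in species 1")
  b <- crms_b_translated[crms_b_translated$unique, , drop = FALSE]
  if (anyDuplicated(b$id)) stop("duplicate CRM ids in species 2")
  gr_a <- GenomicRanges::GRanges(crms_a$chrom,
                                 IRanges::IRanges(crms_a$start + 1L,
                                                  crms_a$end))
  gr_b <- GenomicRanges::GRanges(b$tgt_chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b,
                                      minoverlap = min_overlap)
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  na <- nrow(crms_a)
  uf <- union_find(na + nrow(b))
  for (k in seq_along(qa)) uf$union(qa[k], na + qb[k])
  comp_a <- vapply(qa, uf$find, 0L)
  comp_b <- vapply(na + qb, uf$find, 0L)  # same roots as comp_a rows
  # component sizes per species over CRMs that overlap anything
  roots_a <- vapply(unique(qa), uf$find, 0L)
  roots_b <- vapply(na + unique(qb), uf$find, 0L)
  n_in_a <- table(roots_a); n_in_b <- table(roots_b)
  edge_root <- comp_a
  one_to_one <- n_in_a[as.character(edge_root)] == 1L &
    n_in_b[as.character(edge_root)] == 1L
  keep <- which(one_to_one)
  ov_start <- pmax(crms_a$start[qa[keep]], b$start[qb[keep]])
  ov_end <- pmin(crms_a$end[qa[keep]], b$end[qb[keep]])
  len_a <- crms_a$end[qa[keep]] - crms_a$start[qa[keep]]
  len_b <- b$end[qb[keep]] - b$start[qb[keep]]
  pairs <- data.frame(
    id_a = crms_a$id[qa[keep]], id_b = b$id[qb[keep]],
    chrom = crms_a$chrom[qa[keep]],
    start_a = crms_a$start[qa[keep]], end_a = crms_a$end[qa[keep]],
    start_b = b$start[qb[keep]], end_b = b$end[qb[keep]],
    len_a = len_a, len_b = len_b,
    overlap_bp = ov_end - ov_start,
    overlap_frac = (ov_end - ov_start) / pmin(len_a, len_b),
    stringsAsFactors = FALSE
  )
  disc_root <- unique(edge_root[!one_to_one])
  multi <- data.frame(
    component = c(edge_root[!one_to_one], edge_root[!one_to_one]),
    id = c(crms_a$id[qa[!one_to_one]], b$id[qb[!one_to_one]]),
    species = rep(c("a", "b"), each = sum(!one_to_one)),
    stringsAsFactors = FALSE
  )
  multi <- unique(multi)
  n_b_all <- nrow(crms_b_translated[!duplicated(crms_b_translated$id), ])
  summary <- list(
    n_crms_a = na,
    n_crms_b_translated = n_b_all,
    n_crms_b_unique = nrow(b),
    n_overlapping_a = length(unique(qa)),
    pct_overlapping_a = summarize_fractions(length(unique(qa)), na),
    n_pairs = nrow(pairs),
    n_multi_components = length(disc_root),
    median_overlap_bp = stats::median(pairs$overlap_bp),
    median_overlap_pct_len = summarize_fractions(
      stats::median(pairs$overlap_frac) * 100, 100)
  )
  list(pairs = pairs, multi_clusters = multi, summary = summary)
}

#' Extend both CRMs of each orthologous pair to a common size
#'
#' Each pair is resized to `S = len_a + len_b`: both intervals are
#' replaced by `[center - floor(S/2), center + ceiling(S/2))` around their
#' original centers. Extension past the chromosome start is clipped and
#' flagged.
#'
#' @param pairs data.frame from [pair_orthologs()].
#' @return pairs with ext_start_a/ext_end_a/ext_start_b/ext_end_b,
#'   `extended_len_S` and a `clipped` flag.
#' @export
extend_to_common_size <- function(pairs) {
  S <- pairs$len_a + pairs$len_b
  ca <- (pairs$start_a + pairs$end_a) %/% 2
  cb <- (pairs$start_b + pairs$end_b) %/% 2
  sa <- ca - S %/% 2; ea <- ca + ceiling(S / 2)
  sb <- cb - S %/% 2; eb <- cb + ceiling(S / 2)
  clipped <- sa < 0 | sb < 0
  pairs$ext_start_a <- pmax(sa, 0); pairs$ext_end_a <- ea
  pairs$ext_start_b <- pmax(sb, 0); pairs$ext_end_b <- eb
  pairs$extended_len_S <- S
  pairs$clipped <- clipped
  pairs
}
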