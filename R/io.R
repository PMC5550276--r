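#' File formats
#'
#' All genomic coordinates are 0-based half-open (BED dialect) both in
#' memory and on disk. Tables are TSV with a header line; lines starting
#' with '#' are metadata comments.
#'
#' @name crmdiverge-io
NULL

#' Write peaks as narrowPeak (BED6+4)
#'
#' Column 10 carries the summit as an offset from `start`; the `name`
#' column encodes condition as `<tf>_<tp>`.
#'
#' @param peaks data.frame with chrom, start, end, summit, score, tf, tp,
#'   condition columns.
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end", "summit", "score", "condition")
                %in% names(peaks)))
  df <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = paste0(peaks$condition, "_pk", seq_len(nrow(peaks))),
    score = 0L,
    strand = ".",
    signalValue = round(peaks$score, 6),
    pValue = -1,
    qValue = -1,
    peak = peaks$summit - peaks$start
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file into the package's peak representation
#'
#' @param path narrowPeak file written by [write_narrowpeak()].
#' @return data.frame with chrom, start, end, summit, score, tf, tp,
#'   condition.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score0", "strand", "signalValue",
                                        "pValue", "qValue", "peak"),
                          stringsAsFactors = FALSE)
  cond <- sub("_pk[0-9]+$", "", df$name)
  parts <- strsplit(cond, "_", fixed = TRUE)
  data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    summit = df$start + df$peak,
    score = df$signalValue,
    tf = vapply(parts, `[`, "", 1L),
    tp = vapply(parts, function(p) paste(p[-1L], collapse = "_"), ""),
    condition = cond,
    stringsAsFactors = FALSE
  )
}

#' Write/read a numeric matrix as TSV with row names
#' @param mat matrix with row and column names.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an alignment block map as TSV
#'
#' Columns: src_chrom, src_start, src_end, tgt_chrom, tgt_start, strand;
#' 0-based half-open; blocks are ungapped so the target span length equals
#' the source span length.
#'
#' @param map block map data.frame.
#' @param path file path.
#' @export
write_block_map <- function(map, path) {
  cols <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start",
            "strand")
  stopifnot(all(cols %in% names(map)))
  utils::write.table(map[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_map
#' @export
read_block_map <- function(path) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_block_map(map)
  map
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Parse a minimal MEME text motif file
#'
#' Supports the MEME version 4+ text format: `MOTIF` blocks with
#' `letter-probability matrix` sections and an optional
#' `Background letter frequencies` line.
#'
#' @param path MEME-format motif file.
#' @param pseudocount pseudocount passed to [new_pwm()].
#' @return list of PWM objects (see [new_pwm()]).
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  bg <- NULL
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
    names(bg) <- tok[c(1, 3, 5, 7)]
    bg <- bg[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    colnames(mat) <- c("A", "C", "G", "T")
    out[[name]] <- new_pwm(name, mat, background = bg,
                           pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in MEME text format
#' @param pwms list of PWM objects.
#' @param path output file.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$mat)), con)
    writeLines(apply(p$mat, 1L, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a JSON report
#' @param x list to serialize.
#' @param path file path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
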