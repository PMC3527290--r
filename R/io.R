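# Alignment readers and writers, column symbolization, and text exports.
#
# Coordinates are 0-based, half-open (BED-style) in all outputs.

#' Read a pairwise alignment and reduce it to column symbols
#'
#' Accepts an aligned FASTA file with exactly two equal-length records, or
#' a MAF file projected onto a chosen species pair.  Columns where both
#' bases are in `{A, C, G, T}` become `IDENTICAL`/`DIFFERENT`; any other
#' character (N, gap, IUPAC ambiguity) becomes `MISSING`.  Soft-masked
#' (lowercase) bases are folded to uppercase by default, or treated as
#' missing with `soft_mask_missing = TRUE`.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"maf"`; guessed from the extension by
#'   default.
#' @param species For MAF input, a character vector of the two species
#'   names (matched against the text before the first `.` of each `s`-line
#'   source); the first is the reference the coordinates follow.
#' @param soft_mask_missing Treat lowercase bases as missing?
#' @return A [column_sequence()].
#' @export
read_alignment <- function(path, format = NULL, species = NULL,
                           soft_mask_missing = FALSE) {
  if (is.null(format)) {
    format <- if (grepl("\\.maf(\\.gz)?$", path, ignore.case = TRUE)) "maf"
      else "fasta"
  }
  format <- match.arg(format, c("fasta", "maf"))
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) != 2L)
      stop("expected exactly two FASTA records, found ", length(seqs))
    if (Biostrings::width(seqs)[1L] != Biostrings::width(seqs)[2L])
      stop("aligned FASTA records must have equal length")
    symbolize_pair(as.character(seqs[[1L]]), as.character(seqs[[2L]]),
                   soft_mask_missing)
  } else {
    read_maf_pair(path, species, soft_mask_missing)
  }
}

symbolize_pair <- function(x, y, soft_mask_missing = FALSE) {
  a <- strsplit(x, "", fixed = TRUE)[[1L]]
  b <- strsplit(y, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  soft <- (a %in% letters) | (b %in% letters)
  a <- toupper(a); b <- toupper(b)
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (soft_mask_missing) valid <- valid & !soft
  sym <- ifelse(!valid, 3L, ifelse(a == b, 1L, 2L))
  column_sequence(sym)
}

# Minimal MAF reader: projects blocks onto the reference species'
# coordinates; reference-gap columns are dropped, query gaps and inter-block
# gaps become MISSING.  Requires plus-strand reference rows.
read_maf_pair <- function(path, species, soft_mask_missing = FALSE) {
  if (is.null(species) || length(species) != 2L)
    stop("MAF input needs `species = c(reference, query)`")
  lines <- readLines(path)
  s_lines <- grep("^s ", lines)
  if (!length(s_lines)) stop("no alignment rows found in MAF file")
  blocks <- split(s_lines, cumsum(grepl("^a", lines))[s_lines])
  rows <- list()
  for (bl in blocks) {
    fields <- lapply(strsplit(lines[bl], "[[:space:]]+"), function(f) f)
    src <- vapply(fields, `[`, character(1L), 2L)
    sp <- sub("\\..*$", "", src)
    i_ref <- which(sp == species[1L])[1L]
    i_qry <- which(sp == species[2L])[1L]
    if (is.na(i_ref) || is.na(i_qry)) next
    ref <- fields[[i_ref]]; qry <- fields[[i_qry]]
    if (ref[5L] != "+") stop("minus-strand reference rows are not supported")
    rows[[length(rows) + 1L]] <- list(
      start = as.integer(ref[3L]),  # 0-based
      ref_seq = ref[7L], qry_seq = qry[7L])
  }
  if (!length(rows)) {
    warning("no MAF blocks contain both requested species; all columns missing")
    return(column_sequence(rep(3L, 1L)))
  }
  span_end <- max(vapply(rows, function(r)
    r$start + sum(strsplit(r$ref_seq, "")[[1L]] != "-"), integer(1L)))
  span_start <- min(vapply(rows, `[[`, integer(1L), "start"))
  sym <- rep(3L, span_end - span_start)
  for (r in rows) {
    rs <- strsplit(r$ref_seq, "", fixed = TRUE)[[1L]]
    qs <- strsplit(r$qry_seq, "", fixed = TRUE)[[1L]]
    keep <- rs != "-"
    pos <- r$start + cumsum(keep)[keep] - 1L  # 0-based ref positions
    pair <- symbolize_pair(paste(rs[keep], collapse = ""),
                           paste(qs[keep], collapse = ""), soft_mask_missing)
    sym[pos - span_start + 1L] <- as.integer(pair)
  }
  out <- column_sequence(sym)
  attr(out, "offset") <- span_start
  out
}

#' Write an alignment as FASTA
#'
#' @param alignment An `im_alignment`.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_alignment <- function(alignment, path, width = 70L) {
  bases <- c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(paste0(">", rownames(alignment)[i]), con)
    s <- paste(bases[alignment[i, ]], collapse = "")
    writeLines(substring(s, seq(1L, nchar(s), width),
                         pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write a TMRCA truth track as BED-like TSV
#'
#' @param arg An `im_arg` (or a data frame with `start`, `end`, `time`).
#' @param path Output file.
#' @param chrom Sequence name.
#' @export
write_tmrca_bed <- function(arg, path, chrom = "sim") {
  tr <- if (inherits(arg, "im_arg")) arg$track else arg
  utils::write.table(
    data.frame(chrom = chrom, start = tr$start - 1L, end = tr$end,
               time = tr$time),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
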