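#' @useDynLib snrcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

snrcm_version <- function() as.character(utils::packageVersion("snrcm"))

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 80 columns; re-reading gives content-identical
#' sequences regardless of the wrapping of the original input.
#'
#' @param x A named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A [Biostrings::DNAStringSet] with a `qualities` column in its
#'   metadata columns. A truncated trailing record raises an error naming
#'   the offending record index.
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in '%s' (%d trailing line(s))",
                 n_lines %/% 4L + 1L, path, n_lines %% 4L), call. = FALSE)
  }
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

#' Write reads to FASTQ
#'
#' @param x A [Biostrings::DNAStringSet] (qualities taken from
#'   `mcols(x)$qualities` if present) or named character vector.
#' @param path Output path.
#' @param quality Constant Phred quality character used when `x` carries no
#'   per-base qualities.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, quality = "I") {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  quals <- S4Vectors::mcols(x)$qualities
  seqs <- as.character(x)
  quals <- if (is.null(quals)) {
    vapply(nchar(seqs), function(w) strrep(quality, w), character(1))
  } else {
    as.character(quals)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  # records written directly (4 lines each): long Nanopore-scale records
  # exceed the line buffer of the usual serializers
  rec <- character(4L * length(seqs))
  rec[seq(1, length(rec), 4)] <- paste0("@", ids)
  rec[seq(2, length(rec), 4)] <- seqs
  rec[seq(3, length(rec), 4)] <- "+"
  rec[seq(4, length(rec), 4)] <- quals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read a GFF3 file into a region table
#'
#' Coordinates stay 1-based inclusive (the GFF3 and R/Bioconductor
#' convention).
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `strand` plus any attribute columns. Malformed lines raise an
#'   error carrying the line number.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated fields, got %d",
                 bad, path, nf[nf != 9L][1]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  names(df)[names(df) == "seqnames"] <- "seqid"
  df$width <- NULL
  df$strand <- as.character(df$strand)
  df$seqid <- as.character(df$seqid)
  df
}

#' Write a region table to GFF3
#'
#' @param df A data.frame with at least `seqid`, `start`, `end` (1-based
#'   inclusive); optional `type`, `strand`, `source` and extra attribute
#'   columns (kept as GFF3 attributes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path) {
  stopifnot(all(c("seqid", "start", "end") %in% names(df)))
  if (is.null(df$strand)) df$strand <- "*"
  if (is.null(df$type)) df$type <- "region"
  gr <- GenomicRanges::makeGRangesFromDataFrame(df, keep.extra.columns = TRUE)
  src <- if (is.null(df$source)) "snrcm" else df$source
  S4Vectors::mcols(gr)$source <- NULL
  rtracklayer::export(gr, path, format = "gff3", source = src)
  invisible(path)
}

#' Read a tab-separated table
#'
#' Skips `#`-prefixed header comments.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a tab-separated table
#'
#' A `#`-prefixed header comment records the tool version.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# snrcm %s", snrcm_version()), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# random DNA with a given GC fraction, using the session RNG
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
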