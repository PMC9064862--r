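#' Containment-mining parameters
#'
#' Thresholds for deciding that a candidate BGC region is completely
#' captured on a single long read. Defaults are explicit conventions of
#' this implementation, exposed for tuning.
#'
#' @param kmer_size Seed k-mer size (>= 8).
#' @param min_chain_coverage Minimum fraction of the region that must be
#'   covered on one read for a `complete_on_single_read` call.
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns) for a complete call.
#' @param band_bp Half-width of the band-limited alignment.
#' @param max_gap_bp Maximum gap between chained seeds, in region or read
#'   coordinates.
#' @param absent_below Calls with covered fraction below this floor are
#'   reported `absent` rather than `partial`.
#' @param match,mismatch,gap Alignment scores (linear gap penalty). The
#'   defaults (1, -2, 2) keep random local alignments in the logarithmic
#'   regime: with cheaper penalties (e.g. gap 1) the expected score of
#'   aligning unrelated DNA is positive and local alignments sprawl over
#'   the whole region, making an `absent` call impossible.
#' @param min_evidence_score A refined alignment scoring below this is no
#'   evidence of presence (covered fraction 0). Random-sequence alignment
#'   scores under the default scoring stay far below 50.
#' @param max_align_per_region At most this many candidate reads per region
#'   are refined by banded alignment (candidates ranked by chained bases);
#'   the rest keep their chain-based statistics.
#' @return An object of class `containment_params`.
#' @export
containment_params <- function(kmer_size = 15, min_chain_coverage = 0.95,
                               min_identity = 0.80, band_bp = 500,
                               max_gap_bp = 2000, absent_below = 0.05,
                               match = 1, mismatch = -2, gap = 2,
                               min_evidence_score = 50,
                               max_align_per_region = 20) {
  stopifnot(kmer_size >= 8, kmer_size <= 31,
            min_chain_coverage > 0, min_chain_coverage <= 1,
            min_identity > 0, min_identity <= 1,
            band_bp >= 1, max_gap_bp >= 0, absent_below >= 0, gap > 0,
            min_evidence_score >= 0)
  structure(list(kmer_size = as.integer(kmer_size),
                 min_chain_coverage = min_chain_coverage,
                 min_identity = min_identity, band_bp = as.integer(band_bp),
                 max_gap_bp = as.integer(max_gap_bp),
                 absent_below = absent_below, match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 min_evidence_score = as.integer(min_evidence_score),
                 max_align_per_region = as.integer(max_align_per_region)),
            class = "containment_params")
}

#' Filter contigs by minimum length
#'
#' Keeps contigs whose length is greater than or equal to `min_len_bp`
#' (inclusive boundary), preserving input order.
#'
#' @param contigs A [Biostrings::DNAStringSet] or named character vector.
#' @param min_len_bp Minimum length in bp (default 40000, the cut used to
#'   discard contigs too short to witness complete clusters).
#' @return The kept subset, same class as the input.
#' @export
filter_contigs <- function(contigs, min_len_bp = 40000) {
  stopifnot(min_len_bp >= 0)
  len <- if (methods::is(contigs, "XStringSet")) Biostrings::width(contigs)
         else nchar(contigs)
  contigs[len >= min_len_bp]
}

#' Import candidate BGC regions from GFF3
#'
#' Validates regions against contig bounds and flags regions on a contig
#' edge (possibly truncated clusters).
#'
#' @param path Path to a GFF3 file whose records carry `ID` (used as
#'   `region_id`) and optionally a `class` attribute.
#' @param contigs Contigs the regions refer to ([Biostrings::DNAStringSet]
#'   or named character).
#' @param edge_margin_bp A region starting or ending within this many bp of
#'   a contig end is flagged `on_contig_edge` (default 0: exact ends only).
#' @return A data.frame: `region_id`, `seqid`, `start`, `end` (1-based
#'   inclusive), `class`, `on_contig_edge`.
#' @export
import_regions <- function(path, contigs, edge_margin_bp = 0) {
  df <- read_gff3(path)
  clen <- if (methods::is(contigs, "XStringSet")) {
    stats::setNames(Biostrings::width(contigs), names(contigs))
  } else stats::setNames(nchar(contigs), names(contigs))
  if (!all(df$seqid %in% names(clen))) {
    stop("regions refer to unknown contigs: ",
         paste(setdiff(df$seqid, names(clen)), collapse = ", "), call. = FALSE)
  }
  id <- if (!is.null(df$ID)) df$ID else sprintf("region_%03d", seq_len(nrow(df)))
  bad <- df$start < 1 | df$end > clen[df$seqid] | df$end < df$start
  if (any(bad)) {
    stop(sprintf("region %s exceeds the bounds of contig %s (%d bp)",
                 id[bad][1], df$seqid[bad][1], clen[df$seqid[bad][1]]),
         call. = FALSE)
  }
  data.frame(
    region_id = id, seqid = df$seqid, start = df$start, end = df$end,
    class = if (!is.null(df$class)) df$class else NA_character_,
    on_contig_edge = df$start <= 1 + edge_margin_bp |
      df$end >= clen[df$seqid] - edge_margin_bp,
    stringsAsFactors = FALSE)
}

# refine one (region, read) candidate chain by banded local alignment in a
# window around the chain; returns covered_fraction/identity from the
# alignment traceback
refine_hit <- function(region_seq, read_seq, hit, params) {
  m <- nchar(region_seq)
  sub <- if (hit$strand < 0) revcomp(read_seq) else read_seq
  lo <- max(1L, hit$r_lo - hit$q_lo - params$band_bp)
  hi <- min(nchar(sub), hit$r_hi + (m - hit$q_hi) + params$band_bp)
  win <- substr(sub, lo, hi)
  al <- cpp_banded_sw(region_seq, win, params$band_bp,
                      params$match, params$mismatch, params$gap)
  if (al$aln_len == 0 || al$score < params$min_evidence_score) {
    return(list(covered = 0, identity = 0))
  }
  list(covered = (al$p_end - al$p_start + 1) / m,
       identity = al$matches / al$aln_len)
}

verdict_call <- function(covered, identity, params) {
  if (covered >= params$min_chain_coverage && identity >= params$min_identity) {
    "complete_on_single_read"
  } else if (covered < params$absent_below) {
    "absent"
  } else {
    "partial"
  }
}

#' Mine single-read containment of candidate BGC regions
#'
#' The core step: for every region, decide whether at least one long read
#' completely contains it. Shared k-mers between region and read (both
#' strands) are chained colinearly with a bounded gap; promising chains are
#' refined by band-limited local alignment, giving the covered fraction of
#' the region and the alignment identity. A region is
#' `complete_on_single_read` when one read reaches both thresholds; reads
#' never combine across strands. Ties among supporting reads break by
#' higher covered fraction, then higher identity, then lexicographic read
#' id.
#'
#' @param regions Data.frame as from [import_regions()] (needs `region_id`,
#'   `seqid`, `start`, `end`), or a named character/DNAStringSet of region
#'   sequences.
#' @param reads Long reads ([Biostrings::DNAStringSet] or named character).
#' @param params A [containment_params()] object.
#' @param contigs Contigs (required when `regions` is a coordinate table).
#' @return An object of class `containment_verdicts`: a data.frame with one
#'   row per region (`region_id`, `call`, `best_read_id`,
#'   `covered_fraction`, `identity`, `n_supporting`) and a `supporting`
#'   attribute listing per-region supporting reads.
#' @export
mine_single_read_containment <- function(regions, reads,
                                         params = containment_params(),
                                         contigs = NULL) {
  if (is.data.frame(regions)) {
    stopifnot(!is.null(contigs))
    cs <- if (methods::is(contigs, "XStringSet")) as.character(contigs)
          else contigs
    region_seqs <- substr(cs[regions$seqid], regions$start, regions$end)
    names(region_seqs) <- regions$region_id
  } else {
    region_seqs <- if (methods::is(regions, "XStringSet")) as.character(regions)
                   else regions
    if (is.null(names(region_seqs)))
      names(region_seqs) <- sprintf("region_%03d", seq_along(region_seqs))
  }
  if (any(nchar(region_seqs) < params$kmer_size)) {
    stop("region shorter than kmer_size: ",
         paste(names(region_seqs)[nchar(region_seqs) < params$kmer_size],
               collapse = ", "), call. = FALSE)
  }
  read_seqs <- if (methods::is(reads, "XStringSet")) as.character(reads)
               else reads
  empty_verdict <- function() {
    data.frame(region_id = names(region_seqs), call = "absent",
               best_read_id = NA_character_, covered_fraction = 0,
               identity = 0, n_supporting = 0L, stringsAsFactors = FALSE)
  }
  if (length(read_seqs) == 0) {
    warning("empty read set: all regions called absent")
    out <- empty_verdict()
    attr(out, "supporting") <- stats::setNames(
      rep(list(character(0)), nrow(out)), out$region_id)
    class(out) <- c("containment_verdicts", class(out))
    return(out)
  }
  if (is.null(names(read_seqs)))
    names(read_seqs) <- sprintf("read_%06d", seq_along(read_seqs))

  min_chain_bases <- max(100L, 3L * params$kmer_size)
  hits <- cpp_anchor_chains(unname(region_seqs), unname(read_seqs),
                            params$kmer_size, params$max_gap_bp,
                            as.integer(min_chain_bases))

  out <- empty_verdict()
  supporting <- stats::setNames(rep(list(character(0)), nrow(out)),
                                out$region_id)
  # refine chains whose span could reach the completeness threshold; others
  # keep chain-based statistics (their call cannot be complete, since exact
  # k-mer anchors cannot span more of the region than the chain does)
  refine_floor <- 0.9 * params$min_chain_coverage
  for (ri in seq_along(region_seqs)) {
    h <- hits[hits$region == ri, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- h[order(-h$chain_bases), , drop = FALSE]
    stats_cov <- h$chain_cov
    stats_id <- rep(NA_real_, nrow(h))
    span_frac <- (h$q_hi - h$q_lo + 1) / nchar(region_seqs[ri])
    do_refine <- which(span_frac >= refine_floor)
    if (length(do_refine) > params$max_align_per_region)
      do_refine <- do_refine[seq_len(params$max_align_per_region)]
    for (i in do_refine) {
      rf <- refine_hit(region_seqs[ri], read_seqs[h$read[i]], h[i, ], params)
      stats_cov[i] <- rf$covered
      stats_id[i] <- rf$identity
    }
    # chain-only hits: identity not alignment-verified; approximate by the
    # anchored fraction of the chain span (conservative, cannot reach the
    # complete call because coverage already failed)
    approx <- is.na(stats_id)
    stats_id[approx] <- pmin(1, h$chain_bases[approx] /
                               pmax(1L, h$q_hi[approx] - h$q_lo[approx] + 1L))
    calls <- mapply(verdict_call, stats_cov, stats_id,
                    MoreArgs = list(params = params))
    ord <- order(-stats_cov, -stats_id, names(read_seqs)[h$read])
    best <- ord[1]
    sup <- which(calls == "complete_on_single_read")
    out$call[ri] <- verdict_call(stats_cov[best], stats_id[best], params)
    out$best_read_id[ri] <- names(read_seqs)[h$read[best]]
    out$covered_fraction[ri] <- stats_cov[best]
    out$identity[ri] <- stats_id[best]
    out$n_supporting[ri] <- length(sup)
    supporting[[ri]] <- names(read_seqs)[h$read[sup]][
      order(-stats_cov[sup], -stats_id[sup], names(read_seqs)[h$read[sup]])]
  }
  attr(out, "supporting") <- supporting
  class(out) <- c("containment_verdicts", class(out))
  out
}

#' @export
print.containment_verdicts <- function(x, ...) {
  n <- table(factor(x$call, levels = c("complete_on_single_read", "partial",
                                       "absent")))
  cat(sprintf("Containment verdicts for %d region(s): %d complete on a single read, %d partial, %d absent\n",
              nrow(x), n[1], n[2], n[3]))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Summarize complete-on-single-read calls by BGC class
#'
#' @param verdicts Result of [mine_single_read_containment()].
#' @param regions Region table with `region_id` and `class` columns
#'   covering every verdict row.
#' @return A named integer vector of per-class counts of regions called
#'   `complete_on_single_read` (empty when there are none).
#' @export
summarize_by_class <- function(verdicts, regions) {
  missing <- setdiff(verdicts$region_id, regions$region_id)
  if (length(missing) > 0) {
    stop("verdicts reference unknown regions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cls <- regions$class[match(verdicts$region_id, regions$region_id)]
  keep <- verdicts$call == "complete_on_single_read"
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tab <- table(cls[keep])
  stats::setNames(as.integer(tab), names(tab))
}
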