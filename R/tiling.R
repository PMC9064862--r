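#' Choose a minimal tiling path of fosmids over a target interval
#'
#' Classical interval covering by greedy furthest reach, which is optimal
#' in cardinality: starting at the target's left end, repeatedly pick among
#' the fosmids overlapping the covered prefix (by at least
#' `min_overlap_bp`, as recombination needs homologous overlap) the one
#' reaching furthest right. Ties break by larger overlap (smaller start),
#' then clone id. Strand-discordant alignments are excluded by default.
#'
#' @param target Numeric `c(start, end)`, 1-based inclusive, on the
#'   reference contig.
#' @param alignments Data.frame of fosmid end-sequencing alignments:
#'   `clone_id`, `start`, `end`, optional `strand`.
#' @param min_overlap_bp Minimum overlap between consecutive fosmids
#'   (default 500).
#' @param allow_reverse Include minus-strand alignments (default FALSE).
#' @return A list of class `tiling_path`: `clone_ids`, `intervals`,
#'   `overlaps_bp` (pairwise, length n-1), `covered_interval`. On a
#'   coverage gap, an error of class `tiling_gap` carrying the first
#'   uncovered interval in `gap`.
#' @export
find_tiling_path <- function(target, alignments, min_overlap_bp = 500,
                             allow_reverse = FALSE) {
  stopifnot(length(target) == 2, target[1] <= target[2])
  a <- alignments
  if (!is.null(a$strand) && !allow_reverse) a <- a[a$strand != "-", , drop = FALSE]
  a <- a[a$end > a$start, , drop = FALSE]
  fail <- function(gap_lo, gap_hi) {
    cond <- structure(class = c("tiling_gap", "error", "condition"),
                      list(message = sprintf(
                        "no fosmid covers reference interval %d-%d",
                        gap_lo, gap_hi),
                        call = NULL, gap = c(gap_lo, gap_hi)))
    stop(cond)
  }
  chosen <- integer(0)
  reach <- target[1] - 1          # rightmost covered coordinate so far
  repeat {
    if (reach >= target[2]) break
    # first pick must cover target start; later picks must overlap the
    # chosen prefix by min_overlap_bp and extend the reach
    max_start <- if (length(chosen) == 0) target[1]
                 else reach - min_overlap_bp + 1
    ok <- which(a$start <= max_start & a$end > reach)
    if (length(ok) == 0) {
      nxt <- suppressWarnings(min(a$start[a$start > max_start & a$end > reach]))
      fail(reach + 1, if (is.finite(nxt)) nxt - 1 else target[2])
    }
    pick <- ok[order(-a$end[ok], a$start[ok], a$clone_id[ok])][1]
    chosen <- c(chosen, pick)
    reach <- a$end[pick]
  }
  iv <- a[chosen, c("clone_id", "start", "end")]
  overlaps <- if (length(chosen) > 1) {
    iv$end[-nrow(iv)] - iv$start[-1] + 1
  } else numeric(0)
  structure(list(clone_ids = iv$clone_id,
                 intervals = iv,
                 overlaps_bp = overlaps,
                 covered_interval = c(min(iv$start), max(iv$end))),
            class = "tiling_path")
}

#' @export
print.tiling_path <- function(x, ...) {
  cat(sprintf("Tiling path of %d fosmid(s) covering %d-%d\n",
              length(x$clone_ids), x$covered_interval[1],
              x$covered_interval[2]))
  for (i in seq_along(x$clone_ids)) {
    cat(sprintf("  %s  %d-%d%s\n", x$clone_ids[i], x$intervals$start[i],
                x$intervals$end[i],
                if (i > 1) sprintf("  (overlap %d bp)", x$overlaps_bp[i - 1])
                else ""))
  }
  invisible(x)
}

#' Predict restriction fragments of a molecule
#'
#' Either scans a sequence for a recognition site (both strands; a
#' palindromic site is counted once) or takes explicit cut positions. The
#' cut falls at the middle of the recognition site. For a circular
#' molecule the fragments are the arcs between consecutive cuts (their
#' count equals the site count and their lengths sum to the molecule
#' length); for a linear molecule the two molecule ends add one fragment.
#'
#' @param seq Molecule sequence (character or DNAString); or NULL when
#'   `length` and `cut_positions` are given.
#' @param site Recognition sequence, length >= 4 (e.g. `"ATTTAAAT"`).
#' @param topology `"circular"` or `"linear"`.
#' @param length Molecule length (only with explicit `cut_positions`).
#' @param cut_positions Optional explicit 1-based cut positions.
#' @return A list of class `digest_result`: `site_positions` (1-based site
#'   starts, or cut positions when given explicitly), `cut_positions`,
#'   `fragment_lengths_bp` (descending), `topology`. Zero sites on a
#'   circular molecule yield zero fragments, with a warning.
#' @export
predict_digest_fragments <- function(seq = NULL, site = NULL,
                                     topology = c("circular", "linear"),
                                     length = NULL, cut_positions = NULL) {
  topology <- match.arg(topology)
  if (!is.null(seq)) {
    seq <- toupper(as.character(seq))
    L <- nchar(seq)
    stopifnot(!is.null(site), nchar(site) >= 4)
    site <- toupper(site)
    subj <- Biostrings::DNAString(seq)
    fwd <- IRanges::start(Biostrings::matchPattern(Biostrings::DNAString(site),
                                                   subj))
    rcs <- revcomp(site)
    pos <- if (rcs == site) fwd else {
      sort(unique(c(fwd, IRanges::start(
        Biostrings::matchPattern(Biostrings::DNAString(rcs), subj)))))
    }
    cuts <- pos + nchar(site) %/% 2
  } else {
    stopifnot(!is.null(length), !is.null(cut_positions))
    L <- length
    pos <- sort(unique(as.integer(cut_positions)))
    cuts <- pos
  }
  cuts <- sort(unique(cuts[cuts >= 1 & cuts <= L]))
  n <- base::length(cuts)
  if (topology == "circular") {
    if (n == 0) {
      warning("no recognition site on circular molecule: zero fragments")
      frags <- numeric(0)
    } else if (n == 1) {
      frags <- L
    } else {
      frags <- diff(c(cuts, cuts[1] + L))
    }
  } else {
    frags <- diff(c(0, cuts, L))
    frags <- frags[frags > 0]
  }
  structure(list(site_positions = pos, cut_positions = cuts,
                 fragment_lengths_bp = sort(frags, decreasing = TRUE),
                 topology = topology, molecule_length = L),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("%s digest: %d cut(s), fragments {%s} bp (molecule %s bp)\n",
              x$topology, length(x$cut_positions),
              paste(format(x$fragment_lengths_bp, big.mark = ",", trim = TRUE),
                    collapse = "; "),
              format(x$molecule_length, big.mark = ",")))
  invisible(x)
}

#' Assign reads to expected fragment sizes
#'
#' A read belongs to an expected size when its length is within
#' `rel_tol * size` of it; a read within tolerance of several sizes goes to
#' the nearer one, ties to the smaller size.
#'
#' @param reads [Biostrings::DNAStringSet], named character vector, or a
#'   numeric vector of read lengths.
#' @param expected_sizes_bp Numeric vector of expected fragment sizes.
#' @param rel_tol Relative tolerance in `[0, 0.5)`.
#' @return A factor (one level per expected size, `NA` for unassigned),
#'   named by read when the input carried names.
#' @export
size_filter_reads <- function(reads, expected_sizes_bp, rel_tol = 0.1) {
  stopifnot(rel_tol >= 0, rel_tol < 0.5)
  len <- if (methods::is(reads, "XStringSet")) Biostrings::width(reads)
         else if (is.numeric(reads)) reads else nchar(reads)
  nm <- if (is.numeric(reads)) names(reads)
        else if (methods::is(reads, "XStringSet")) names(reads) else names(reads)
  sz <- sort(expected_sizes_bp)                 # ties resolve to smaller size
  grp <- vapply(len, function(l) {
    d <- abs(l - sz)
    ok <- d <= rel_tol * sz
    if (!any(ok)) return(NA_real_)
    sz[ok][which.min(d[ok])]
  }, numeric(1))
  out <- factor(grp, levels = sz)
  names(out) <- nm
  out
}

#' Verify an assembled construct from size-filtered reads
#'
#' Each predicted reference fragment must be completely contained in at
#' least one read of its size group (single-read containment with the
#' given thresholds). The assembly passes when every fragment is covered.
#'
#' @param read_groups Named list mapping fragment names to read sets
#'   (character vectors or [Biostrings::DNAStringSet]s).
#' @param reference_fragments Named character vector (or DNAStringSet) of
#'   the expected fragment sequences.
#' @param params A [containment_params()] object.
#' @return A list of class `assembly_verdict`: per-fragment data.frame
#'   (`fragment`, `covered`, `covered_fraction`, `identity`,
#'   `best_read_id`) and `pass`.
#' @export
verify_assembly <- function(read_groups, reference_fragments,
                            params = containment_params()) {
  if (methods::is(reference_fragments, "XStringSet")) {
    reference_fragments <- as.character(reference_fragments)
  }
  stopifnot(!is.null(names(reference_fragments)))
  rows <- lapply(names(reference_fragments), function(fn) {
    reads <- read_groups[[fn]]
    if (is.null(reads) || length(reads) == 0) {
      return(data.frame(fragment = fn, covered = FALSE, covered_fraction = 0,
                        identity = 0, best_read_id = NA_character_,
                        stringsAsFactors = FALSE))
    }
    v <- suppressWarnings(mine_single_read_containment(
      stats::setNames(reference_fragments[fn], fn), reads, params))
    data.frame(fragment = fn, covered = v$call == "complete_on_single_read",
               covered_fraction = v$covered_fraction, identity = v$identity,
               best_read_id = v$best_read_id, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(fragments = tab, pass = all(tab$covered)),
            class = "assembly_verdict")
}

#' @export
print.assembly_verdict <- function(x, ...) {
  cat(sprintf("Assembly verification: %s (%d/%d fragment(s) covered)\n",
              if (x$pass) "PASS" else "FAIL", sum(x$fragments$covered),
              nrow(x$fragments)))
  print.data.frame(x$fragments, digits = 4)
  invisible(x)
}

#' Assemble a tiling path into a circular construct
#'
#' Concatenates the reference interval covered by the path with a vector
#' stub, removes incidental occurrences of the verification site (one base
#' substitution each) and plants exactly two sites: one near the
#' vector/insert boundary and one inside the insert, so the digest
#' releases two fragments bracketing the cluster.
#'
#' @param reference_seq Reference contig sequence.
#' @param path A [find_tiling_path()] result.
#' @param vector_seq Vector stub sequence (default: first 5 kb of the
#'   shipped synthetic backbone).
#' @param site Verification recognition site (default `"ATTTAAAT"`, an
#'   8-bp blunt cutter).
#' @param internal_site_at Position of the second site within the insert,
#'   as a fraction of the insert length (default 0.78).
#' @return A list: `construct` (character, circular), `site`,
#'   `insert_interval` (reference coordinates used).
#' @export
assemble_construct <- function(reference_seq, path, vector_seq = NULL,
                               site = "ATTTAAAT", internal_site_at = 0.78) {
  reference_seq <- toupper(as.character(reference_seq))
  if (is.null(vector_seq)) vector_seq <- substr(vector_backbone(), 1, 5000)
  vector_seq <- toupper(vector_seq)
  x <- path$covered_interval
  insert <- substr(reference_seq, x[1], x[2])
  strip_site <- function(s) {
    repeat {
      hit <- regexpr(site, s, fixed = TRUE)
      if (hit < 0) return(s)
      at <- as.integer(hit) + 3L
      old <- substr(s, at, at)
      substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
  }
  insert <- strip_site(insert)
  vector_seq <- strip_site(vector_seq)
  pos <- max(1L, round(internal_site_at * nchar(insert)) - nchar(site) %/% 2L)
  substr(insert, pos, pos + nchar(site) - 1L) <- site
  substr(vector_seq, 100L, 100L + nchar(site) - 1L) <- site
  list(construct = paste0(vector_seq, insert), site = site,
       insert_interval = c(x[1], x[2]))
}
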