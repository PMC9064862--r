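# designed tiling inserts forcing a 3-clone minimal cover of an oversized
# cluster [s, e] with inserts of length ins_len: the left and right clones
# leave a gap between them, and the middle clone reaches neither cluster end
tiling_inserts <- function(s, e, ins_len, frag_len) {
  L <- e - s + 1L
  a <- round(0.25 * ins_len)    # left insert extends this far before s
  b <- round(0.15 * ins_len)    # right insert extends this far past e
  left <- c(s - a, s - a + ins_len - 1L)
  right <- c(e + b - ins_len + 1L, e + b)
  mid <- c(left[2] - 4000L + 1L, left[2] - 4000L + ins_len)
  ok <- left[1] >= 1L && right[2] <= frag_len &&
    left[2] < right[1] &&                       # no 2-clone cover via ends
    mid[1] > s && mid[2] < e &&                 # middle covers neither end
    mid[1] <= left[2] - 500L && mid[2] >= right[1] + 500L
  if (!ok) {
    stop(sprintf(paste0("cannot lay out a forced 3-clone tiling for a %d bp ",
                        "cluster with %d bp inserts on a %d bp fragment"),
                 L, ins_len, frag_len), call. = FALSE)
  }
  list(left = left, mid = mid, right = right)
}

#' Build an in-silico fosmid library
#'
#' Clones carry an insert drawn from the community fragments ligated into a
#' circular vector backbone. One designed clone per single-insert planted
#' BGC guarantees its capture; an oversized planted cluster receives three
#' designed clones with overlapping inserts (the in-silico counterpart of
#' screening the library for clones carrying overlapping cluster parts).
#' Remaining clones are placed uniformly at random. Clones are assigned to
#' storage pools of `pool_size` in index order.
#'
#' @param community Result of [generate_community()].
#' @param config A [sim_config()] object.
#' @param vector_seq Vector backbone sequence (default: the shipped
#'   synthetic backbone, truncated/recycled to `config$vector_len`).
#' @return A list with `clones` (data.frame: `clone_id`, `pool_id`,
#'   `fragment_id`, `insert_start`, `insert_end`, `insert_strand`,
#'   `designed`, `bgc_id`) and `molecules` (a named
#'   [Biostrings::DNAStringSet] of circular clone sequences, vector first).
#' @export
build_fosmid_library <- function(community, config, vector_seq = NULL) {
  validate_sim_config(config)
  if (length(community$fragments) == 0) stop("no fragments", call. = FALSE)
  set.seed(config$seed + 1L)
  if (is.null(vector_seq)) vector_seq <- vector_backbone()
  vector_seq <- substr(strrep(vector_seq, 2L), 1L, config$vector_len)

  frags <- as.character(community$fragments)
  flen <- nchar(frags)
  if (all(flen < config$insert_len[1])) {
    stop("insert length range exceeds every fragment length", call. = FALSE)
  }

  rows <- list()
  add <- function(fragment_id, s, e, strand, designed, bgc_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fragment_id = fragment_id, insert_start = s, insert_end = e,
      insert_strand = strand, designed = designed, bgc_id = bgc_id,
      stringsAsFactors = FALSE)
  }

  reserved <- character(0)
  regions <- community$regions
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    f <- which(names(community$fragments) == r$seqid)
    blen <- r$end - r$start + 1L
    if (blen + 2000L <= config$insert_len[2]) {
      ilen <- round(stats::runif(1, max(config$insert_len[1], blen + 2000L),
                                 config$insert_len[2]))
      lo <- max(1L, r$end + 1000L - ilen + 1L)
      hi <- min(r$start - 1000L, flen[f] - ilen + 1L)
      if (hi < lo) { lo <- max(1L, r$end - ilen + 1L); hi <- min(r$start, flen[f] - ilen + 1L) }
      s <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo
      add(r$seqid, s, s + ilen - 1L, "+", TRUE, r$region_id)
    } else {
      ti <- tiling_inserts(r$start, r$end, config$insert_len[1], flen[f])
      for (nm in c("left", "mid", "right")) {
        add(r$seqid, ti[[nm]][1], ti[[nm]][2], "+", TRUE, r$region_id)
      }
      if (config$reserve_oversized_fragments) reserved <- c(reserved, r$seqid)
    }
  }

  n_designed <- length(rows)
  n_random <- config$n_clones - n_designed
  if (n_random < 0) stop("n_clones smaller than the number of designed clones",
                         call. = FALSE)
  open_frags <- setdiff(names(community$fragments), reserved)
  open_frags <- open_frags[flen[match(open_frags, names(community$fragments))] >=
                             config$insert_len[1]]
  if (n_random > 0 && length(open_frags) == 0) {
    stop("no fragment long enough for random inserts", call. = FALSE)
  }
  if (n_random > 0) {
    w <- flen[match(open_frags, names(community$fragments))]
    pick <- sample(open_frags, n_random, replace = TRUE, prob = w)
    ilen <- round(stats::runif(n_random, config$insert_len[1],
                               pmin(config$insert_len[2],
                                    w[match(pick, open_frags)])))
    smax <- w[match(pick, open_frags)] - ilen + 1L
    s <- 1L + floor(stats::runif(n_random) * smax)
    strand <- sample(c("+", "-"), n_random, replace = TRUE)
    for (i in seq_len(n_random)) {
      add(pick[i], s[i], s[i] + ilen[i] - 1L, strand[i], FALSE, NA_character_)
    }
  }

  clones <- do.call(rbind, rows)
  clones$clone_id <- sprintf("clone_%05d", seq_len(nrow(clones)))
  clones$pool_id <- (seq_len(nrow(clones)) - 1L) %/% config$pool_size + 1L
  clones <- clones[, c("clone_id", "pool_id", "fragment_id", "insert_start",
                       "insert_end", "insert_strand", "designed", "bgc_id")]

  inserts <- substr(frags[match(clones$fragment_id, names(community$fragments))],
                    clones$insert_start, clones$insert_end)
  flip <- clones$insert_strand == "-"
  if (any(flip)) {
    inserts[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(inserts[flip])))
  }
  molecules <- Biostrings::DNAStringSet(paste0(vector_seq, inserts))
  names(molecules) <- clones$clone_id
  list(clones = clones, molecules = molecules)
}

#' Re-extract a clone insert from its source fragment
#'
#' Round-trip helper: the returned sequence equals the insert portion of the
#' clone molecule (positions after the vector backbone).
#'
#' @param library Result of [build_fosmid_library()].
#' @param community Result of [generate_community()].
#' @param clone_id Single clone identifier.
#' @return The insert sequence as a character string.
#' @export
clone_insert <- function(library, community, clone_id) {
  cl <- library$clones[library$clones$clone_id == clone_id, ]
  if (nrow(cl) != 1) stop("unknown clone_id: ", clone_id, call. = FALSE)
  s <- substr(as.character(community$fragments[[cl$fragment_id]]),
              cl$insert_start, cl$insert_end)
  if (cl$insert_strand == "-") s <- revcomp(s)
  s
}
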