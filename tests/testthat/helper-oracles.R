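# Independent oracles used by the tests. They deliberately avoid the
# package's own code paths: alignment goes through Biostrings' full
# dynamic-programming implementation, ORF enumeration through a literal
# nested-loop translation, set covering through exhaustive subset search,
# and site scanning through a vectorized substring comparison.

oracle_random_dna <- function(n, gc = 0.55) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# point substitutions only (same length)
oracle_substitute <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  paste(ch, collapse = "")
}

# substitutions then per-base insertions/deletions (Bernoulli each)
oracle_mutate <- function(s, sub, ins, del) {
  ch <- strsplit(oracle_substitute(s, sub), "")[[1]]
  out <- character(0)
  for (x in ch) {
    if (stats::runif(1) < del) next
    out <- c(out, x)
    if (stats::runif(1) < ins) out <- c(out, sample(c("A", "C", "G", "T"), 1))
  }
  paste(out, collapse = "")
}

# Full (unbanded) local-alignment DP oracle for single-read containment,
# applying the same thresholds as the miner: best strand by score, covered
# fraction from the aligned region span, identity from alignment columns,
# alignments under min_evidence_score count as no evidence.
oracle_containment_call <- function(region, read, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  best <- NULL
  for (s in c(read, oracle_revcomp(read))) {
    al <- Biostrings::pairwiseAlignment(
      pattern = region, subject = s, type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = params$gap)
    if (is.null(best) || Biostrings::score(al) > Biostrings::score(best)) {
      best <- al
    }
  }
  if (Biostrings::score(best) < params$min_evidence_score) {
    covered <- 0; identity <- 0
  } else {
    pat <- Biostrings::pattern(best)
    covered <- (IRanges::end(pat) - IRanges::start(pat) + 1) / nchar(region)
    identity <- Biostrings::nmatch(best) / Biostrings::nchar(best)
  }
  if (covered >= params$min_chain_coverage && identity >= params$min_identity) {
    "complete_on_single_read"
  } else if (covered < params$absent_below) {
    "absent"
  } else {
    "partial"
  }
}

# Brute-force precursor enumeration: literal translation of the rules,
# written as plain nested loops. Returns one row per accepted
# (ORF, leader/core split, acceptor position), keyed on forward-strand ORF
# coordinates.
oracle_precursors <- function(dna, cfg) {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  code <- Biostrings::GENETIC_CODE
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else oracle_revcomp(dna)
    for (st in seq_len(n - 2)) {
      if (!(substr(s, st, st + 2) %in% cfg$start_codons)) next
      aa <- character(0)
      pos <- st
      stopped <- FALSE
      while (pos + 2 <= n) {
        a <- unname(code[substr(s, pos, pos + 2)])
        if (is.na(a)) break
        if (a == "*") { stopped <- TRUE; break }
        aa <- c(aa, if (length(aa) == 0) "M" else a)
        pos <- pos + 3
      }
      if (!stopped) next
      L <- length(aa)
      if (L < cfg$orf_len_aa[1] || L > cfg$orf_len_aa[2]) next
      orf_end_local <- st + (L + 1) * 3 - 1      # includes the stop codon
      if (strand == "+") {
        fs <- st; fe <- orf_end_local
      } else {
        fs <- n - orf_end_local + 1; fe <- n - st + 1
      }
      for (split in seq_len(L)) {
        if (split - 1 < cfg$min_leader_aa) next
        if (split > L - 1) next
        if (!(aa[split] %in% cfg$donor_set)) next
        if (!(aa[split - 2] %in% cfg$minus2)) next
        for (ap in cfg$acceptor_pos) {
          ix <- split + ap - 1
          if (ix > L) next
          if (!(aa[ix] %in% cfg$acceptor)) next
          if ((L - split + 1) - ap < cfg$min_tail_aa) next
          rows[[length(rows) + 1]] <- data.frame(
            orf_start = fs, orf_end = fe, strand = strand,
            leader_len = split - 1, ring_acceptor_pos = ap,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(orf_start = integer(0), orf_end = integer(0),
                      strand = character(0), leader_len = integer(0),
                      ring_acceptor_pos = integer(0)))
  }
  unique(do.call(rbind, rows))
}

# candidate key set for comparing scanner output with the oracle
precursor_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  leader_len <- if (!is.null(df$leader_len)) df$leader_len
                else nchar(df$leader_seq)
  sort(sprintf("%d:%d:%s:%d:%d", df$orf_start, df$orf_end, df$strand,
               leader_len, df$ring_acceptor_pos))
}

# Exhaustive minimum-cardinality cover of target by intervals, under the
# same semantics as the tiling planner (first interval must cover the
# target start; each later one must overlap the covered prefix by at least
# min_overlap and extend it). Returns Inf when no subset covers.
oracle_min_cover <- function(target, alignments, min_overlap) {
  a <- alignments[alignments$end > alignments$start, , drop = FALSE]
  n <- nrow(a)
  feasible <- function(idx) {
    o <- idx[order(a$start[idx])]
    reach <- target[1] - 1
    for (k in seq_along(o)) {
      lim <- if (k == 1) target[1] else reach - min_overlap + 1
      if (a$start[o[k]] > lim) return(FALSE)
      if (a$end[o[k]] <= reach) return(FALSE)
      reach <- a$end[o[k]]
    }
    reach >= target[2]
  }
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k)
    for (j in seq_len(ncol(sets))) {
      if (feasible(sets[, j])) return(k)
    }
  }
  Inf
}

# naive overlapping substring scan for a recognition site, both strands
oracle_site_positions <- function(seq, site) {
  seq <- toupper(seq); site <- toupper(site)
  n <- nchar(seq); w <- nchar(site)
  if (n < w) return(integer(0))
  windows <- substring(seq, 1:(n - w + 1), w:n)
  hits <- which(windows == site)
  rc <- oracle_revcomp(site)
  if (rc != site) hits <- union(hits, which(windows == rc))
  sort(hits)
}

# deterministic reverse translation for constructing test ORFs
oracle_aa2dna <- function(aa) {
  codon <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC",
             G = "GGT", H = "CAT", I = "ATC", K = "AAA", L = "CTG",
             M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
             S = "TCT", T = "ACC", V = "GTT", W = "TGG", Y = "TAC")
  paste(codon[strsplit(aa, "")[[1]]], collapse = "")
}
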