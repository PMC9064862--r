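#' Simulate Nanopore-like long reads from clone molecules
#'
#' Read lengths are log-normal, truncated to `[1000, molecule length]`
#' (fosmid molecules cap read length near insert + vector). Start positions
#' are uniform on the circular molecule, so reads may span the
#' vector/insert junction (flagged in the truth table). Errors are applied
#' substitutions first, then insertions/deletions, each per-position
#' Bernoulli. With all error rates zero every read is an exact substring of
#' its (doubled, for wrap-around) molecule.
#'
#' @param library Result of [build_fosmid_library()].
#' @param config A [sim_config()] object.
#' @param coverage Per-molecule coverage; defaults to
#'   `config$long_read_coverage`.
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: `read_id`, `clone_id`, `start`, `length`,
#'   `strand`, `wraps`, `truncated`, `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_long_reads <- function(library, config, coverage = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  if (is.null(coverage)) coverage <- config$long_read_coverage
  rates <- config$long_read_error
  p <- config$long_read_len
  mols <- as.character(library$molecules)
  ids <- names(library$molecules)

  seqs <- vector("list", length(mols))
  truth <- vector("list", length(mols))
  for (ci in seq_along(mols)) {
    mol <- mols[ci]
    L <- nchar(mol)
    dbl <- strrep(mol, 2L)
    target <- coverage * L
    drawn <- 0
    lens <- integer(0); starts <- integer(0); trunc <- logical(0)
    while (drawn < target) {
      raw <- round(stats::rlnorm(1, p["meanlog"], p["sdlog"]))
      tr <- raw > L
      len <- max(1000L, min(L, raw))
      lens <- c(lens, len); trunc <- c(trunc, tr)
      starts <- c(starts, sample.int(L, 1L))
      drawn <- drawn + len
    }
    n <- length(lens)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    out <- character(n)
    ns <- integer(n); ni <- integer(n); nd <- integer(n)
    for (i in seq_len(n)) {
      s <- substr(dbl, starts[i], starts[i] + lens[i] - 1L)
      if (strand[i] == "-") s <- revcomp(s)
      mut <- cpp_mutate(s, rates["sub"], rates["ins"], rates["del"])
      out[i] <- mut$seq
      ns[i] <- mut$n_sub; ni[i] <- mut$n_ins; nd[i] <- mut$n_del
    }
    seqs[[ci]] <- out
    truth[[ci]] <- data.frame(
      read_id = sprintf("%s_r%04d", ids[ci], seq_len(n)),
      clone_id = ids[ci], start = starts, length = lens, strand = strand,
      wraps = starts + lens - 1L > L, truncated = trunc,
      n_sub = ns, n_ins = ni, n_del = nd, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  reads <- Biostrings::DNAStringSet(unlist(seqs, use.names = FALSE))
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth)
}

#' Simulate paired short reads from clone molecules
#'
#' Deterministic pair-count mode: each clone yields
#' `ceiling(coverage * L / (2 * read_len))` pairs. Fragment sizes are
#' normal; positions are uniform on the circular molecule. R1 is the
#' forward start of the fragment, R2 the reverse complement of its end.
#'
#' @param library Result of [build_fosmid_library()].
#' @param config A [sim_config()] object.
#' @param coverage Target coverage; defaults to
#'   `config$short_read_coverage`.
#' @param error_sub Per-base substitution rate (default 0).
#' @return A list with `r1`, `r2` (named [Biostrings::DNAStringSet]s) and
#'   `truth` (data.frame: `pair_id`, `clone_id`, `frag_start`, `frag_len`).
#' @export
simulate_short_reads <- function(library, config, coverage = NULL,
                                 error_sub = 0) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  if (is.null(coverage)) coverage <- config$short_read_coverage
  rl <- config$short_read_len
  fp <- config$short_insert_len
  mols <- as.character(library$molecules)
  ids <- names(library$molecules)

  r1 <- list(); r2 <- list(); truth <- list()
  for (ci in seq_along(mols)) {
    mol <- mols[ci]; L <- nchar(mol); dbl <- strrep(mol, 2L)
    n <- ceiling(coverage * L / (2 * rl))
    flen <- pmax(2L * rl, round(stats::rnorm(n, fp["mean"], fp["sd"])))
    flen <- pmin(flen, L)
    fs <- sample.int(L, n, replace = TRUE)
    frag <- substr(rep(dbl, n), fs, fs + flen - 1L)
    a <- substr(frag, 1L, rl)
    b <- vapply(substr(frag, flen - rl + 1L, flen), revcomp, character(1),
                USE.NAMES = FALSE)
    if (error_sub > 0) {
      a <- vapply(a, function(x) cpp_mutate(x, error_sub, 0, 0)$seq,
                  character(1), USE.NAMES = FALSE)
      b <- vapply(b, function(x) cpp_mutate(x, error_sub, 0, 0)$seq,
                  character(1), USE.NAMES = FALSE)
    }
    r1[[ci]] <- a; r2[[ci]] <- b
    truth[[ci]] <- data.frame(
      pair_id = sprintf("%s_p%05d", ids[ci], seq_len(n)),
      clone_id = ids[ci], frag_start = fs, frag_len = flen,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  r1 <- Biostrings::DNAStringSet(unlist(r1, use.names = FALSE))
  r2 <- Biostrings::DNAStringSet(unlist(r2, use.names = FALSE))
  names(r1) <- paste0(truth$pair_id, "/1")
  names(r2) <- paste0(truth$pair_id, "/2")
  list(r1 = r1, r2 = r2, truth = truth)
}
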