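#' Load the lasso gene-classification rule table
#'
#' Keyword/size rules mapping gene evidence (size, BLAST-style description,
#' domain tag) to the lasso peptide gene roles A, B1, B2, C, D. Shipped as
#' a data file so new keywords need no code change. Regexes are matched
#' case-insensitively; the `A_size_scan` rule additionally requires a
#' passing precursor scan.
#'
#' @param path Optional path to an alternative rule TSV (columns `label`,
#'   `rule_id`, `domain_regex`, `desc_regex`, `min_bp`, `max_bp`).
#' @return A data.frame of rules.
#' @export
lasso_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lasso_rules.tsv", package = "snrcm")
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  rules$domain_regex[is.na(rules$domain_regex)] <- ""
  rules$desc_regex[is.na(rules$desc_regex)] <- ""
  rules
}

# precedence on multi-match (higher wins)
LASSO_PRECEDENCE <- c(B2 = 5, B1 = 4, C = 3, D = 2, A = 1)

#' Classify a gene as a lasso peptide biosynthesis gene
#'
#' Applies the rule table to one evidence record. A rule fires when the
#' size window holds and either its domain regex matches the domain tag or
#' its description regex matches the description (case-insensitive). The
#' `A_size_scan` rule fires only for small genes with a passing precursor
#' scan (`precursor_ok`). On multiple matching labels the precedence
#' B2 > B1 > C > D > A decides; all fired rules are reported.
#'
#' @param size_bp Gene size in bp.
#' @param description BLAST-style free-text description (may be empty).
#' @param domain_tag Domain annotation tag (e.g. `PF05402`), or `"-"`.
#' @param precursor_ok Logical: did a precursor scan accept this gene's
#'   translation? `NA` (default) counts as FALSE.
#' @param rules Rule table from [lasso_rules()].
#' @return A list with `label` (one of `"A"`, `"B1"`, `"B2"`, `"C"`, `"D"`,
#'   `"none"`) and `rationale` (character vector of fired rule ids; empty
#'   iff label is `"none"`).
#' @export
classify_gene <- function(size_bp, description = "", domain_tag = "",
                          precursor_ok = NA, rules = lasso_rules()) {
  stopifnot(length(size_bp) == 1, size_bp > 0)
  description <- if (is.na(description)) "" else description
  domain_tag <- if (is.na(domain_tag)) "" else domain_tag
  fired <- character(0)
  labels <- character(0)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (size_bp < r$min_bp || size_bp > r$max_bp) next
    hit <- FALSE
    if (r$rule_id == "A_size_scan") {
      hit <- isTRUE(precursor_ok)
    } else {
      if (nzchar(r$domain_regex) &&
          grepl(r$domain_regex, domain_tag, ignore.case = TRUE)) hit <- TRUE
      if (!hit && nzchar(r$desc_regex) &&
          grepl(r$desc_regex, description, ignore.case = TRUE)) hit <- TRUE
    }
    if (hit) {
      fired <- c(fired, r$rule_id)
      labels <- c(labels, r$label)
    }
  }
  if (length(labels) == 0) {
    return(list(label = "none", rationale = character(0)))
  }
  label <- names(which.max(LASSO_PRECEDENCE[unique(labels)]))
  list(label = label, rationale = fired)
}

#' Classify a table of gene evidence records
#'
#' Vectorized [classify_gene()] over a data.frame with columns `size_bp`,
#' `description`, `domain_tag` and optionally `precursor_ok`.
#'
#' @param evidence Evidence data.frame.
#' @param rules Rule table from [lasso_rules()].
#' @return The input with `label` and `rationale` (collapsed with `;`)
#'   columns appended.
#' @export
classify_genes <- function(evidence, rules = lasso_rules()) {
  stopifnot(all(c("size_bp", "description", "domain_tag") %in% names(evidence)))
  pk <- if (!is.null(evidence$precursor_ok)) evidence$precursor_ok
        else rep(NA, nrow(evidence))
  res <- lapply(seq_len(nrow(evidence)), function(i) {
    classify_gene(evidence$size_bp[i], evidence$description[i],
                  evidence$domain_tag[i], pk[i], rules)
  })
  evidence$label <- vapply(res, `[[`, character(1), "label")
  evidence$rationale <- vapply(res, function(r)
    paste(r$rationale, collapse = ";"), character(1))
  evidence
}

#' Precursor-scan configuration
#'
#' @param donor Allowed residues at core position 1 (the macrolactam ring
#'   donor). `"strict"` = Gly only; `"relaxed"` adds Ala/Ser/Cys.
#' @param acceptor Allowed ring acceptor residues (Asp/Glu side chains).
#' @param acceptor_pos Allowed core positions for the acceptor (ring of
#'   7-9 residues).
#' @param min_tail_aa Minimum tail length after the acceptor.
#' @param min_leader_aa Minimum leader length.
#' @param minus2 Allowed residues at leader position -2 relative to the
#'   core (Thr is canonical; similar-size substitutions allowed).
#' @param orf_len_aa ORF length window (aa) for candidate precursors.
#' @param start_codons Accepted start codons.
#' @return A list of class `precursor_config`.
#' @export
precursor_config <- function(donor = c("strict", "relaxed"),
                             acceptor = c("D", "E"),
                             acceptor_pos = 7:9,
                             min_tail_aa = 3,
                             min_leader_aa = 8,
                             minus2 = c("T", "S", "L", "A", "C", "V", "I"),
                             orf_len_aa = c(20, 70),
                             start_codons = c("ATG", "GTG", "TTG")) {
  donor_set <- if (match.arg(donor) == "strict") "G" else c("G", "A", "S", "C")
  structure(list(donor_set = donor_set, acceptor = acceptor,
                 acceptor_pos = acceptor_pos, min_tail_aa = min_tail_aa,
                 min_leader_aa = min_leader_aa, minus2 = minus2,
                 orf_len_aa = orf_len_aa, start_codons = start_codons),
            class = "precursor_config")
}

# enumerate ORFs (start codon .. next in-frame stop) on both strands;
# returns data.frame with 1-based coordinates on the forward strand
find_orfs <- function(dna, cfg) {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    starts_at <- which(substring(s, seq_len(n - 2), seq_len(n - 2) + 2) %in%
                         cfg$start_codons)
    stops <- c("TAA", "TAG", "TGA")
    for (st in starts_at) {
      # walk in-frame to the next stop
      pos <- seq(st, n - 2, by = 3)
      cod <- substring(s, pos, pos + 2)
      stop_idx <- which(cod %in% stops)[1]
      if (is.na(stop_idx)) next
      aa_len <- stop_idx - 1L
      if (aa_len < cfg$orf_len_aa[1] || aa_len > cfg$orf_len_aa[2]) next
      orf_nt <- substr(s, st, st + stop_idx * 3 - 1)
      aa <- paste0("M", as.character(Biostrings::translate(
        Biostrings::DNAString(substr(orf_nt, 4, aa_len * 3)),
        no.init.codon = TRUE)))
      # forward-strand coordinates of the ORF including the stop codon
      if (strand == "+") {
        coords <- c(st, st + stop_idx * 3 - 1)
      } else {
        coords <- c(n - (st + stop_idx * 3 - 1) + 1, n - st + 1)
      }
      out[[length(out) + 1L]] <- data.frame(
        start = coords[1], end = coords[2], strand = strand,
        aa = aa, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa = character(0)))
  }
  unique(do.call(rbind, out))
}

#' Scan a DNA region for lasso precursor candidates
#'
#' Enumerates small open reading frames on both strands and every
#' leader/core split, accepting a split when the core starts with a ring
#' donor residue, an Asp/Glu acceptor sits 7-9 residues in, at least 3 tail
#' residues follow, the leader is at least 8 aa, and the residue two
#' positions before the core is Thr-like. One candidate is reported per
#' (ORF, split, acceptor position); candidates are ranked by (strict Gly
#' donor, Asp over Glu, Thr at -2, shorter tail) and all fired criteria are
#' reported — no silent selection among ties.
#'
#' @param dna Region sequence (character or DNAString), >= 60 bp.
#' @param config A [precursor_config()].
#' @return A data.frame of candidates: `orf_start`, `orf_end`, `strand`,
#'   `aa_sequence`, `leader_seq`, `core_seq`, `ring_acceptor_pos`,
#'   `tail_len_aa`, `minus2_residue`, `rank`. Empty (zero rows) when no
#'   ORF or split qualifies.
#' @export
scan_precursors <- function(dna, config = precursor_config()) {
  dna <- as.character(dna)
  if (nchar(dna) < 60) stop("region must be at least 60 bp", call. = FALSE)
  orfs <- find_orfs(dna, config)
  out <- list()
  for (i in seq_len(nrow(orfs))) {
    aa <- strsplit(orfs$aa[i], "")[[1]]
    L <- length(aa)
    if (L < config$min_leader_aa + 2L) next
    for (split in (config$min_leader_aa + 1L):L) {  # core starts at `split`
      core_len <- L - split + 1L
      if (core_len < 2) next
      if (!(aa[split] %in% config$donor_set)) next
      if (!(aa[split - 2L] %in% config$minus2)) next
      for (ap in config$acceptor_pos) {
        if (split + ap - 1L > L) next
        res <- aa[split + ap - 1L]
        if (!(res %in% config$acceptor)) next
        tail_len <- core_len - ap
        if (tail_len < config$min_tail_aa) next
        out[[length(out) + 1L]] <- data.frame(
          orf_start = orfs$start[i], orf_end = orfs$end[i],
          strand = orfs$strand[i], aa_sequence = orfs$aa[i],
          leader_seq = paste(aa[1:(split - 1L)], collapse = ""),
          core_seq = paste(aa[split:L], collapse = ""),
          ring_acceptor_pos = ap, acceptor_residue = res,
          tail_len_aa = tail_len, minus2_residue = aa[split - 2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orf_start = integer(0), orf_end = integer(0),
                      strand = character(0), aa_sequence = character(0),
                      leader_seq = character(0), core_seq = character(0),
                      ring_acceptor_pos = integer(0),
                      acceptor_residue = character(0),
                      tail_len_aa = integer(0), minus2_residue = character(0),
                      rank = integer(0)))
  }
  cand <- do.call(rbind, out)
  key <- order(!startsWith(cand$core_seq, "G"),      # strict Gly donor first
               cand$acceptor_residue != "D",         # Asp over Glu
               cand$minus2_residue != "T",           # canonical Thr at -2
               cand$tail_len_aa,                     # shorter tail
               cand$orf_start, cand$ring_acceptor_pos)
  cand <- cand[key, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Assess lasso BGC completeness from gene labels
#'
#' The minimal biosynthetic set is A + B + C, where B is satisfied by both
#' B1 and B2 (split) or by one fused B gene carrying both kinds of
#' evidence. A D gene (ABC transporter) is not required but is flagged, as
#' antimicrobial lasso clusters often carry one.
#'
#' @param labels Either a character vector of labels (`"A"`, `"B1"`, ...;
#'   `"B"` counts as fused) or a classification data.frame from
#'   [classify_genes()] (fused B detected from rationale codes).
#' @return A list of class `lasso_completeness` with `present`, `status`
#'   (`"complete"` or `"incomplete"`), `missing`, `has_transporter`.
#' @export
assess_completeness <- function(labels) {
  fused_b <- FALSE
  if (is.data.frame(labels)) {
    rat <- strsplit(labels$rationale, ";", fixed = TRUE)
    fused_b <- any(vapply(rat, function(r)
      any(startsWith(r, "B1")) && any(startsWith(r, "B2")), logical(1)))
    labels <- labels$label
  }
  present <- setdiff(unique(labels), "none")
  if ("B" %in% present) fused_b <- TRUE
  b_ok <- fused_b || all(c("B1", "B2") %in% present)
  need <- c("A", "C")
  missing <- setdiff(need, present)
  if (!b_ok) missing <- c(missing, setdiff(c("B1", "B2"), present))
  status <- if (length(missing) == 0) "complete" else "incomplete"
  structure(list(present = sort(present), status = status,
                 missing = sort(missing),
                 has_transporter = "D" %in% present),
            class = "lasso_completeness")
}

#' @export
print.lasso_completeness <- function(x, ...) {
  cat(sprintf("Lasso BGC %s: genes present {%s}%s%s\n", x$status,
              paste(x$present, collapse = ", "),
              if (length(x$missing)) paste0("; missing {",
                                            paste(x$missing, collapse = ", "),
                                            "}") else "",
              if (x$has_transporter) "; ABC transporter present" else ""))
  invisible(x)
}

#' Annotate a candidate lasso BGC region
#'
#' Full annotation: classify every evidence record; for small genes still
#' unlabelled, run the precursor scanner on the gene's own sequence and, on
#' a pass, reclassify with `precursor_ok = TRUE` (the in-silico analogue of
#' manually annotating tiny precursor genes). Then assess completeness.
#'
#' @param region_seq The region's DNA sequence (character or DNAString).
#' @param evidence Gene evidence data.frame with `gene_id`, `size_bp`,
#'   `description`, `domain_tag` and region-relative `start`, `end` columns
#'   (the last two needed for the precursor rescue of small genes).
#' @param rules Rule table from [lasso_rules()].
#' @param scan_config A [precursor_config()].
#' @return A list with `genes` (classification table), `precursors`
#'   (candidates found in rescued genes) and `completeness`.
#' @export
annotate_lasso_region <- function(region_seq, evidence, rules = lasso_rules(),
                                  scan_config = precursor_config()) {
  region_seq <- as.character(region_seq)
  genes <- classify_genes(evidence, rules)
  precursors <- list()
  rescue <- which(genes$label == "none" & genes$size_bp <= 210 &
                    !is.null(genes$start))
  for (i in rescue) {
    lo <- max(1L, genes$start[i] - 60L)
    hi <- min(nchar(region_seq), genes$end[i] + 60L)
    cand <- scan_precursors(substr(region_seq, lo, hi), scan_config)
    if (nrow(cand) > 0) {
      genes$precursor_ok <- if (is.null(genes$precursor_ok))
        rep(NA, nrow(genes)) else genes$precursor_ok
      genes$precursor_ok[i] <- TRUE
      cand$gene_id <- genes$gene_id[i]
      precursors[[length(precursors) + 1L]] <- cand
      res <- classify_gene(genes$size_bp[i], genes$description[i],
                           genes$domain_tag[i], TRUE, rules)
      genes$label[i] <- res$label
      genes$rationale[i] <- paste(res$rationale, collapse = ";")
    }
  }
  list(genes = genes,
       precursors = if (length(precursors)) do.call(rbind, precursors)
                    else NULL,
       completeness = assess_completeness(genes))
}
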