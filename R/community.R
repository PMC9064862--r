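# --- gene construction ------------------------------------------------------

# one fixed codon per amino acid, for deterministic reverse translation
AA_CODON <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC",
              G = "GGT", H = "CAT", I = "ATC", K = "AAA", L = "CTG",
              M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
              S = "TCT", T = "ACC", V = "GTT", W = "TGG", Y = "TAC")

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# random open reading frame of exactly size_bp (multiple of 3): ATG, sense
# codons, TAA -- no in-frame stops
random_orf <- function(size_bp) {
  stopifnot(size_bp %% 3 == 0, size_bp >= 9)
  n_codons <- size_bp / 3 - 2
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

reverse_translate <- function(aa) {
  paste(AA_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

# A lasso precursor open reading frame: 24-aa leader ending in Thr at
# position -2 relative to the core, then a core whose first residue (Gly)
# and the Asp at ring position 8 form the macrolactam, with a 9-aa tail.
lasso_precursor_orf <- function() {
  leader <- "MSKEQQTAPEVGKVNDLAKSAETL"   # [-2] = T, [-1] = L
  core <- "GAFNSGQDFLGRWTDGK"            # G...D at core position 8, tail 9 aa
  paste0(reverse_translate(paste0(leader, core)), "TAA")
}

# gene cassette for one planted BGC; returns list(seq, genes) where genes is a
# data.frame of per-gene truth and evidence relative to the cassette start
bgc_cassette <- function(class, length_bp, transporter = FALSE) {
  spacer <- function(n = 150) random_dna(n)
  if (class == "lasso") {
    specs <- list(
      list(role = "C", seq = random_orf(1905),
           desc = "Hypothetical protein", domain = "Asn_synthase"),
      list(role = "B2", seq = random_orf(423),
           desc = "Lasso peptide biosynthesis B2 protein", domain = "PF13471"),
      list(role = "B1", seq = random_orf(294),
           desc = "PqqD family peptide modification chaperone",
           domain = "PF05402"),
      list(role = "A", seq = lasso_precursor_orf(),
           desc = "Hypothetical protein", domain = "-")
    )
    if (transporter) {
      specs <- c(specs, list(
        list(role = "D", seq = random_orf(822),
             desc = "ABC transporter permease", domain = "-")))
    }
  } else {
    # generic cassette: a few ORFs filling ~70% of the requested length
    stopifnot(!is.na(length_bp))
    n_genes <- max(2L, min(6L, length_bp %/% 9000L + 2L))
    per <- (length_bp * 0.7) %/% n_genes
    per <- max(300, per - per %% 3)
    specs <- lapply(seq_len(n_genes), function(i) {
      list(role = "orf", seq = random_orf(per),
           desc = "Hypothetical protein", domain = "-")
    })
  }
  pieces <- character(0)
  rows <- list()
  pos <- 1L
  lead <- spacer(100)
  pieces <- c(pieces, lead); pos <- pos + nchar(lead)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    len <- nchar(sp$seq)
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%02d", i), role = sp$role,
      start = pos, end = pos + len - 1L, strand = "+",
      size_bp = len, description = sp$desc, domain_tag = sp$domain,
      stringsAsFactors = FALSE)
    gap <- spacer()
    pieces <- c(pieces, sp$seq, gap)
    pos <- pos + len + nchar(gap)
  }
  seq <- paste(pieces, collapse = "")
  if (!is.na(length_bp) && nchar(seq) < length_bp) {
    seq <- paste0(seq, random_dna(length_bp - nchar(seq)))
  }
  list(seq = seq, genes = do.call(rbind, rows))
}

# --- community generation ---------------------------------------------------

#' Generate a synthetic metagenome community with planted BGCs
#'
#' Builds random DNA fragments (stand-ins for assembled soil-metagenome
#' contigs) and plants one biosynthetic gene cluster per plan row, cycling
#' over fragments. Lasso clusters carry real gene sequences (precursor A,
#' B1, B2, C and optionally D) so the rule-based annotator can rediscover
#' them; other classes carry generic open reading frames.
#'
#' @param config A [sim_config()] object.
#' @return A list with `fragments` (named [Biostrings::DNAStringSet]),
#'   `regions` (truth table: `region_id`, `seqid`, `start`, `end`, `class`),
#'   and `genes` (per-gene truth with evidence columns, absolute fragment
#'   coordinates).
#' @export
generate_community <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  plan <- config$bgc_plan
  frag_len <- round(stats::runif(config$n_fragments,
                                 config$fragment_len[1], config$fragment_len[2]))
  frag_id <- sprintf("fragment_%02d", seq_len(config$n_fragments))

  # assign each BGC to a fragment (round robin); oversized clusters go last
  # so a long fragment can host them
  assign_frag <- ((seq_len(nrow(plan)) - 1L) %% config$n_fragments) + 1L
  if (any(!is.na(plan$length_bp))) {
    big <- which.max(ifelse(is.na(plan$length_bp), 0, plan$length_bp))
    assign_frag[big] <- which.max(frag_len)
  }

  fragments <- character(config$n_fragments)
  regions <- list(); genes <- list()
  for (f in seq_len(config$n_fragments)) {
    seq <- random_dna(frag_len[f], config$gc)
    here <- which(assign_frag == f)
    cursor <- 1000L
    for (b in here) {
      cass <- bgc_cassette(plan$class[b], plan$length_bp[b], plan$transporter[b])
      blen <- nchar(cass$seq)
      # oversized clusters keep wide margins so tiling inserts can extend
      # beyond the cluster on both sides
      mg <- if (blen > 20000L) 12000L else 1000L
      cursor <- max(cursor, mg)
      if (cursor + blen + mg > frag_len[f]) {
        stop(sprintf("fragment %s (%d bp) too short to host BGC %s (%d bp)",
                     frag_id[f], frag_len[f], plan$bgc_id[b], blen),
             call. = FALSE)
      }
      # random start within the remaining room
      room <- frag_len[f] - mg - blen - cursor
      start <- cursor + sample.int(max(1L, room %/% max(1L, length(here))), 1L)
      substr(seq, start, start + blen - 1L) <- cass$seq
      g <- cass$genes
      g$start <- g$start + start - 1L
      g$end <- g$end + start - 1L
      g <- cbind(bgc_id = plan$bgc_id[b], g, stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <- g
      regions[[length(regions) + 1L]] <- data.frame(
        region_id = plan$bgc_id[b], seqid = frag_id[f],
        start = start, end = start + blen - 1L,
        class = plan$class[b], stringsAsFactors = FALSE)
      cursor <- start + blen
    }
    fragments[f] <- seq
  }
  fragments <- Biostrings::DNAStringSet(fragments)
  names(fragments) <- frag_id
  list(fragments = fragments,
       regions = do.call(rbind, regions),
       genes = do.call(rbind, genes))
}

#' Write community truth regions as GFF3
#'
#' @param community Result of [generate_community()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(community, path) {
  df <- community$regions
  df$type <- "BGC_region"
  df$ID <- df$region_id
  df$class <- df$class
  write_gff3(df[, c("seqid", "start", "end", "type", "ID", "class")], path)
}
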