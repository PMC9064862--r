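#' Default planted-BGC plan
#'
#' Six clusters: five small enough to fit a single fosmid insert — two lasso
#' peptide clusters (one with an ABC-transporter D gene), a bacteriocin, a
#' terpene and a lanthipeptide — plus one ~58 kb NRPS-like cluster that
#' cannot fit any insert and must be recovered by tiling several fosmids.
#'
#' @return A data.frame with columns `bgc_id`, `class`, `length_bp`,
#'   `transporter`.
#' @export
default_bgc_plan <- function() {
  data.frame(
    bgc_id = c("bgc40.1", "bgc482.1", "bgc07.1", "bgc12.1", "bgc21.1", "bgc76.1"),
    class = c("lasso", "lasso", "bacteriocin", "terpene", "lanthipeptide",
              "NRPS-like"),
    length_bp = c(NA, NA, 3600L, 5400L, 6300L, 58000L),
    transporter = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All knobs for the synthetic community, fosmid library and read
#' simulators. Identical configuration plus identical seed yields
#' byte-identical outputs.
#'
#' @param n_fragments Number of metagenome fragments in the community.
#' @param fragment_len Length range (bp) for fragments, `c(min, max)`.
#' @param gc GC fraction of simulated DNA, in `[0, 1]`.
#' @param n_clones Total fosmid clones in the library (the real library held
#'   ~83,700; simulations here use a few hundred to a few thousand).
#' @param pool_size Clones per storage pool (default 2000, the library's
#'   pooling unit).
#' @param insert_len Insert length range in bp (default 30-45 kb).
#' @param vector_len Vector backbone length in bp (default 8,139; a
#'   synthetic pCC1FOS-like placeholder shipped with the package).
#' @param long_read_error Named rates `c(sub=, ins=, del=)`, each in `[0,1)`.
#' @param long_read_len Log-normal read-length parameters
#'   `c(meanlog=, sdlog=)`; draws are truncated to `[1000, molecule length]`.
#' @param long_read_coverage Mean long-read coverage per clone molecule.
#' @param short_read_len Short read length in bp (default 150, paired).
#' @param short_insert_len Short-read fragment size `c(mean=, sd=)` in bp.
#' @param short_read_coverage Target short-read coverage per clone
#'   (deterministic pair-count mode).
#' @param bgc_plan Planted-BGC plan, see [default_bgc_plan()].
#' @param reserve_oversized_fragments If TRUE (default), fragments hosting a
#'   cluster too large for one insert receive only the designed tiling
#'   clones, emulating the screening step that singles out the clones
#'   carrying overlapping cluster parts.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_fragments = 6,
                       fragment_len = c(60000, 139000),
                       gc = 0.55,
                       n_clones = 500,
                       pool_size = 2000,
                       insert_len = c(30000, 45000),
                       vector_len = 8139,
                       long_read_error = c(sub = 0.05, ins = 0.015, del = 0.015),
                       long_read_len = c(meanlog = log(20000), sdlog = 0.45),
                       long_read_coverage = 20,
                       short_read_len = 150,
                       short_insert_len = c(mean = 400, sd = 40),
                       short_read_coverage = 5,
                       bgc_plan = default_bgc_plan(),
                       reserve_oversized_fragments = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_fragments = as.integer(n_fragments), fragment_len = as.numeric(fragment_len),
    gc = gc, n_clones = as.integer(n_clones), pool_size = as.integer(pool_size),
    insert_len = as.numeric(insert_len), vector_len = as.integer(vector_len),
    long_read_error = long_read_error, long_read_len = long_read_len,
    long_read_coverage = long_read_coverage, short_read_len = as.integer(short_read_len),
    short_insert_len = short_insert_len, short_read_coverage = short_read_coverage,
    bgc_plan = bgc_plan,
    reserve_oversized_fragments = isTRUE(reserve_oversized_fragments),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- function(...) stop(sprintf(...), call. = FALSE)
  if (cfg$n_fragments < 1) err("n_fragments must be >= 1")
  if (length(cfg$fragment_len) != 2 || diff(cfg$fragment_len) < 0)
    err("fragment_len must be c(min, max)")
  if (cfg$gc < 0 || cfg$gc > 1) err("gc must be in [0, 1]")
  if (cfg$n_clones < 1) err("n_clones must be >= 1")
  if (cfg$pool_size < 1) err("pool_size must be >= 1")
  if (cfg$insert_len[1] < 1000) err("insert_len minimum must be >= 1 kb")
  if (diff(cfg$insert_len) < 0) err("insert_len must be c(min, max)")
  rates <- cfg$long_read_error
  if (!all(c("sub", "ins", "del") %in% names(rates)))
    err("long_read_error must name sub, ins and del rates")
  if (any(rates < 0) || any(rates >= 1)) err("error rates must be in [0, 1)")
  if (!all(c("meanlog", "sdlog") %in% names(cfg$long_read_len)))
    err("long_read_len must name meanlog and sdlog")
  need <- c("bgc_id", "class", "length_bp", "transporter")
  if (!all(need %in% names(cfg$bgc_plan)))
    err("bgc_plan must have columns %s", paste(need, collapse = ", "))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulated fosmid-library configuration\n")
  cat(sprintf("  community: %d fragments of %s-%s bp (GC %.2f)\n",
              x$n_fragments, format(x$fragment_len[1], big.mark = ","),
              format(x$fragment_len[2], big.mark = ","), x$gc))
  cat(sprintf("  library:   %d clones in pools of %d; inserts %s-%s bp + %s bp vector\n",
              x$n_clones, x$pool_size,
              format(x$insert_len[1], big.mark = ","),
              format(x$insert_len[2], big.mark = ","),
              format(x$vector_len, big.mark = ",")))
  cat(sprintf("  long reads: %gx coverage, error sub/ins/del = %g/%g/%g\n",
              x$long_read_coverage, x$long_read_error["sub"],
              x$long_read_error["ins"], x$long_read_error["del"]))
  cat(sprintf("  planted BGCs: %d (%s)\n", nrow(x$bgc_plan),
              paste(x$bgc_plan$class, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Load the synthetic fosmid vector backbone
#'
#' A fixed 8,139 bp synthetic stand-in for a pCC1FOS-style vector, shipped
#' as a FASTA fixture so clone molecules are reproducible.
#'
#' @return A single-character vector backbone sequence.
#' @export
vector_backbone <- function() {
  path <- system.file("extdata", "vector_synthetic.fasta", package = "snrcm")
  as.character(read_fasta(path)[[1]])
}
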