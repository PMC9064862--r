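#' Load a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are rejected.
#' A `bgc_plan` key may hold a list of records with `bgc_id`, `class`,
#' `length_bp`, `transporter`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$bgc_plan) && !is.data.frame(raw$bgc_plan)) {
    raw$bgc_plan <- do.call(rbind, lapply(raw$bgc_plan, function(r)
      data.frame(bgc_id = r$bgc_id, class = r$class,
                 length_bp = if (is.null(r$length_bp)) NA_integer_
                             else as.integer(r$length_bp),
                 transporter = isTRUE(r$transporter),
                 stringsAsFactors = FALSE)))
  }
  for (nm in c("long_read_error", "long_read_len", "short_insert_len")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML
#'
#' Round-trips through [read_sim_config()] unchanged.
#'
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$bgc_plan <- lapply(seq_len(nrow(config$bgc_plan)), function(i)
    as.list(config$bgc_plan[i, ]))
  x$long_read_error <- as.list(config$long_read_error)
  x$long_read_len <- as.list(config$long_read_len)
  x$short_insert_len <- as.list(config$short_insert_len)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

stage_file_checksums <- function(files) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  stats::setNames(unname(sums), basename(files))
}

#' Run the end-to-end in-silico recovery pipeline
#'
#' Chains the stages simulate (community, library, long reads), mine
#' (contig filter, region import, single-read containment), annotate
#' (lasso rule engine on planted lasso clusters), dilution (recovery plan
#' and one stochastic recovery per complete cluster's pool) and tar
#' (tiling path, construct assembly, digest and size-filtered read
#' verification for clusters too large for one insert). Stage outputs are
#' written under `out_dir`; a JSON manifest with per-file checksums makes
#' reruns comparable. Each stage draws from its own seed, derived from the
#' configuration seed by fixed offsets, so stages are individually
#' reproducible.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "mine", "annotate", "dilution",
#'   "tar")`; later stages require earlier ones in the same call.
#' @param min_contig_len Contig filter for mining (default 40000).
#' @param containment A [containment_params()] object.
#' @param n_tubes Tubes per dilution round.
#' @param verify_error Substitution rate of simulated verification reads.
#' @return A list of class `snrcm_run` with per-stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "mine", "annotate",
                                    "dilution", "tar"),
                         min_contig_len = 40000,
                         containment = containment_params(),
                         n_tubes = 16, verify_error = 0.02) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  manifest <- list(tool = "snrcm", version = snrcm_version(),
                   seed = config$seed, started = format(t0), stages = list())
  ord <- c("simulate", "mine", "annotate", "dilution", "tar")
  stages <- ord[ord %in% stages]
  need <- function(stage, what) {
    if (is.null(res[[what]])) {
      stop(sprintf("stage '%s' requires stage '%s' in the same run",
                   stage, what), call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    community <- generate_community(config)
    lib <- build_fosmid_library(community, config)
    lr <- simulate_long_reads(lib, config)
    files <- file.path(out_dir, c("fragments.fasta", "truth_regions.gff3",
                                  "genes.tsv", "clones.tsv",
                                  "long_reads.fastq", "long_read_truth.tsv"))
    write_fasta(community$fragments, files[1])
    write_truth_gff3(community, files[2])
    write_tsv(community$genes, files[3])
    write_tsv(lib$clones, files[4])
    write_fastq(lr$reads, files[5])
    write_tsv(lr$truth, files[6])
    res$simulate <- list(community = community, library = lib, reads = lr)
    manifest$stages$simulate <- list(checksums = as.list(stage_file_checksums(files)))
  }

  if ("mine" %in% stages) {
    need("mine", "simulate")
    community <- res$simulate$community
    contigs <- filter_contigs(community$fragments, min_contig_len)
    regions <- import_regions(file.path(out_dir, "truth_regions.gff3"),
                              community$fragments)
    regions <- regions[regions$seqid %in% names(contigs), , drop = FALSE]
    verdicts <- mine_single_read_containment(regions, res$simulate$reads$reads,
                                             containment,
                                             contigs = community$fragments)
    by_class <- summarize_by_class(verdicts, regions)
    vf <- file.path(out_dir, "verdicts.tsv")
    write_tsv(as.data.frame(verdicts), vf)
    sf <- file.path(out_dir, "mine_summary.json")
    jsonlite::write_json(list(n_regions = nrow(regions),
                              calls = as.list(table(verdicts$call)),
                              complete_by_class = as.list(by_class)),
                         sf, auto_unbox = TRUE, pretty = TRUE)
    res$mine <- list(regions = regions, verdicts = verdicts,
                     by_class = by_class)
    manifest$stages$mine <- list(checksums = as.list(stage_file_checksums(c(vf, sf))))
  }

  if ("annotate" %in% stages) {
    need("annotate", "simulate")
    community <- res$simulate$community
    lasso <- community$regions[community$regions$class == "lasso", ,
                               drop = FALSE]
    ann <- list()
    for (i in seq_len(nrow(lasso))) {
      r <- lasso[i, ]
      seq <- substr(as.character(community$fragments[[r$seqid]]),
                    r$start, r$end)
      ev <- community$genes[community$genes$bgc_id == r$region_id, ,
                            drop = FALSE]
      ev$start <- ev$start - r$start + 1L
      ev$end <- ev$end - r$start + 1L
      a <- annotate_lasso_region(seq, ev)
      a$genes$bgc_id <- r$region_id
      ann[[r$region_id]] <- a
    }
    tab <- do.call(rbind, lapply(ann, function(a)
      a$genes[, c("bgc_id", "gene_id", "size_bp", "description",
                  "domain_tag", "label", "rationale")]))
    af <- file.path(out_dir, "lasso_annotation.tsv")
    write_tsv(tab, af)
    res$annotate <- ann
    manifest$stages$annotate <- list(checksums = as.list(stage_file_checksums(af)))
  }

  if ("dilution" %in% stages) {
    plans <- standard_dilution_plan(n_tubes)
    dil <- data.frame(
      round = seq_along(plans),
      cells_per_ml = vapply(plans, `[[`, numeric(1), "cells_per_ml"),
      volume_ml = vapply(plans, `[[`, numeric(1), "inoculum_volume_ml"),
      cells_per_tube = vapply(plans, `[[`, numeric(1),
                              "expected_cells_per_tube"),
      n_tubes = vapply(plans, `[[`, integer(1), "n_tubes"),
      p_tube_positive = vapply(plans, `[[`, numeric(1), "p_tube_positive"),
      p_round_success = vapply(plans, `[[`, numeric(1), "p_round_success"))
    outcome <- simulate_recovery(plans, seed = config$seed + 4L)
    df <- file.path(out_dir, "dilution_plan.tsv")
    write_tsv(dil, df)
    res$dilution <- list(plans = plans, table = dil, outcome = outcome)
    manifest$stages$dilution <- list(checksums = as.list(stage_file_checksums(df)))
  }

  if ("tar" %in% stages) {
    need("tar", "simulate")
    need("tar", "mine")
    community <- res$simulate$community
    clones <- res$simulate$library$clones
    verdicts <- res$mine$verdicts
    regions <- res$mine$regions
    big <- regions[regions$region_id %in%
                     verdicts$region_id[verdicts$call != "complete_on_single_read"] &
                     (regions$end - regions$start + 1) > config$insert_len[2], ,
                   drop = FALSE]
    tar <- list()
    set.seed(config$seed + 5L)
    for (i in seq_len(nrow(big))) {
      r <- big[i, ]
      al <- clones[clones$fragment_id == r$seqid, , drop = FALSE]
      al <- data.frame(clone_id = al$clone_id, start = al$insert_start,
                       end = al$insert_end, strand = al$insert_strand,
                       stringsAsFactors = FALSE)
      path <- find_tiling_path(c(r$start, r$end), al)
      ref <- as.character(community$fragments[[r$seqid]])
      asm <- assemble_construct(ref, path)
      dig <- predict_digest_fragments(asm$construct, asm$site, "circular")
      # fragment sequences of the (circular) construct between cuts
      cuts <- dig$cut_positions
      dbl <- strrep(asm$construct, 2L)
      frag_seqs <- substr(rep(dbl, length(cuts)), cuts,
                          c(cuts[-1], cuts[1] + nchar(asm$construct)) - 1L)
      names(frag_seqs) <- sprintf("%s_frag%d", r$region_id,
                                  seq_along(frag_seqs))
      # full-length verification reads per fragment, then size filtering
      reads <- unlist(lapply(frag_seqs, function(s)
        vapply(1:3, function(k) cpp_mutate(s, verify_error, 0, 0)$seq,
               character(1))))
      names(reads) <- sprintf("vread_%02d", seq_along(reads))
      grp <- size_filter_reads(nchar(reads), nchar(frag_seqs), 0.1)
      groups <- lapply(stats::setNames(nchar(frag_seqs), names(frag_seqs)),
                       function(sz) reads[!is.na(grp) & grp == as.character(sz)])
      verdict <- verify_assembly(groups, frag_seqs, containment)
      tar[[r$region_id]] <- list(path = path, digest = dig,
                                 verification = verdict)
    }
    tf <- file.path(out_dir, "tar_report.json")
    jsonlite::write_json(lapply(tar, function(t) list(
      clones = t$path$clone_ids,
      overlaps_bp = t$path$overlaps_bp,
      fragment_lengths_bp = t$digest$fragment_lengths_bp,
      pass = t$verification$pass)), tf, auto_unbox = TRUE, pretty = TRUE)
    res$tar <- tar
    manifest$stages$tar <- list(checksums = as.list(stage_file_checksums(tf)))
  }

  manifest$finished <- format(Sys.time())
  cfg_file <- tempfile(fileext = ".yaml")
  write_sim_config(config, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "snrcm_run"
  invisible(res)
}

#' @export
print.snrcm_run <- function(x, ...) {
  cat("snrcm pipeline run\n")
  cat("  stages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$mine)) {
    cat(sprintf("  mined %d region(s): %s complete on a single read\n",
                nrow(x$mine$verdicts),
                sum(x$mine$verdicts$call == "complete_on_single_read")))
  }
  if (!is.null(x$tar)) {
    for (nm in names(x$tar)) {
      cat(sprintf("  tiling %s: %d clones, verification %s\n", nm,
                  length(x$tar[[nm]]$path$clone_ids),
                  if (x$tar[[nm]]$verification$pass) "PASS" else "FAIL"))
    }
  }
  invisible(x)
}

#' The packaged demonstration configuration
#'
#' A small library (500 clones, pools of 2000, 20x long-read coverage,
#' 8 percent total read error) with six planted clusters: five that fit a
#' single insert and one ~58 kb NRPS-like cluster spanning three designed
#' fosmids.
#'
#' @param seed Integer seed (default 20).
#' @return A [sim_config()] object.
#' @export
demo_config <- function(seed = 20L) {
  sim_config(seed = seed)
}
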