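test_that("planted cluster regions have the configured length and content", {
  cfg <- tiny_config(seed = 11L)
  com <- generate_community(cfg)
  expect_equal(names(com$fragments), c("fragment_01", "fragment_02"))
  r <- com$regions
  expect_setequal(r$region_id, c("t_terp", "t_bact"))
  expect_equal(r$end[r$region_id == "t_terp"] -
                 r$start[r$region_id == "t_terp"] + 1, 5400)
  expect_equal(r$end[r$region_id == "t_bact"] -
                 r$start[r$region_id == "t_bact"] + 1, 3600)
  # gene truth sits inside its region
  for (i in seq_len(nrow(com$genes))) {
    g <- com$genes[i, ]
    reg <- r[r$region_id == g$bgc_id, ]
    expect_gte(g$start, reg$start)
    expect_lte(g$end, reg$end)
    frag <- as.character(com$fragments[[reg$seqid]])
    # every planted gene starts with a start codon and is in-frame stop-free
    orf <- substr(frag, g$start, g$end)
    expect_true(substr(orf, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_equal(nchar(orf) %% 3, 0)
  }
})

test_that("community generation is deterministic given config and seed", {
  a <- generate_community(tiny_config(seed = 5L))
  b <- generate_community(tiny_config(seed = 5L))
  expect_identical(as.character(a$fragments), as.character(b$fragments))
  expect_identical(a$regions, b$regions)
  c2 <- generate_community(tiny_config(seed = 6L))
  expect_false(identical(as.character(a$fragments),
                         as.character(c2$fragments)))
})

test_that("a fragment too short for a planted cluster raises an error", {
  plan <- data.frame(bgc_id = "big", class = "NRPS-like", length_bp = 58000L,
                     transporter = FALSE, stringsAsFactors = FALSE)
  cfg <- sim_config(n_fragments = 1, fragment_len = c(40000, 40000),
                    n_clones = 5, bgc_plan = plan, seed = 1L)
  expect_error(generate_community(cfg), "too short to host")
})

test_that("fosmid clones capture their cluster and respect pool arithmetic", {
  cfg <- tiny_config(seed = 11L)
  com <- generate_community(cfg)
  lib <- build_fosmid_library(com, cfg)
  expect_equal(nrow(lib$clones), cfg$n_clones)
  # designed clones contain their cluster entirely
  des <- lib$clones[lib$clones$designed, ]
  expect_setequal(des$bgc_id, c("t_terp", "t_bact"))
  for (i in seq_len(nrow(des))) {
    reg <- com$regions[com$regions$region_id == des$bgc_id[i], ]
    expect_lte(des$insert_start[i], reg$start)
    expect_gte(des$insert_end[i], reg$end)
  }
  # pools fill in index order: 12 clones in pools of 5 -> 5/5/2
  expect_equal(as.vector(table(lib$clones$pool_id)), c(5, 5, 2))
  # molecule = vector backbone + insert; insert round-trips
  cl <- lib$clones$clone_id[1]
  mol <- as.character(lib$molecules[[cl]])
  expect_equal(nchar(mol),
               cfg$vector_len + lib$clones$insert_end[1] -
                 lib$clones$insert_start[1] + 1)
  expect_identical(substr(mol, cfg$vector_len + 1, nchar(mol)),
                   clone_insert(lib, com, cl))
  # insert lengths stay within the configured range
  ilen <- lib$clones$insert_end - lib$clones$insert_start + 1
  expect_true(all(ilen >= cfg$insert_len[1] & ilen <= cfg$insert_len[2]))
})

test_that("error-free long reads are exact substrings of their molecule", {
  cfg <- tiny_config(seed = 13L, n_clones = 3,
                     long_read_error = c(sub = 0, ins = 0, del = 0),
                     long_read_coverage = 2)
  com <- generate_community(cfg)
  lib <- build_fosmid_library(com, cfg)
  lr <- simulate_long_reads(lib, cfg)
  expect_gt(nrow(lr$truth), 0)
  for (i in seq_len(nrow(lr$truth))) {
    t <- lr$truth[i, ]
    dbl <- strrep(as.character(lib$molecules[[t$clone_id]]), 2)
    expected <- substr(dbl, t$start, t$start + t$length - 1)
    if (t$strand == "-") expected <- oracle_revcomp(expected)
    expect_identical(as.character(lr$reads[[t$read_id]]), expected)
  }
  expect_true(all(lr$truth$n_sub == 0 & lr$truth$n_ins == 0 &
                    lr$truth$n_del == 0))
})

test_that("realized substitution rate matches the configured rate", {
  cfg <- tiny_config(seed = 17L, n_clones = 3,
                     long_read_error = c(sub = 0.05, ins = 0, del = 0),
                     long_read_coverage = 3)
  com <- generate_community(cfg)
  lib <- build_fosmid_library(com, cfg)
  lr <- simulate_long_reads(lib, cfg)
  # substitution-only reads keep their length; compare to the true
  # substring position by position (independent of the simulator's own
  # mutation counters)
  total_bases <- 0; total_mm <- 0
  for (i in seq_len(min(40, nrow(lr$truth)))) {
    t <- lr$truth[i, ]
    dbl <- strrep(as.character(lib$molecules[[t$clone_id]]), 2)
    ref <- substr(dbl, t$start, t$start + t$length - 1)
    if (t$strand == "-") ref <- oracle_revcomp(ref)
    got <- as.character(lr$reads[[t$read_id]])
    expect_equal(nchar(got), nchar(ref))
    a <- strsplit(ref, "")[[1]]; b <- strsplit(got, "")[[1]]
    total_bases <- total_bases + length(a)
    total_mm <- total_mm + sum(a != b)
  }
  rate <- total_mm / total_bases
  # > 100 kb of bases: binomial 3-sigma is well under 0.005
  expect_gt(total_bases, 1e5)
  expect_lt(abs(rate - 0.05), 0.005)
})

test_that("long reads respect length bounds and coverage accounting", {
  cfg <- tiny_config(seed = 19L, n_clones = 4, long_read_coverage = 5)
  com <- generate_community(cfg)
  lib <- build_fosmid_library(com, cfg)
  lr <- simulate_long_reads(lib, cfg)
  L <- Biostrings::width(lib$molecules)[match(lr$truth$clone_id,
                                              names(lib$molecules))]
  expect_true(all(lr$truth$length >= 1000))
  expect_true(all(lr$truth$length <= L))
  # drawn bases reach the coverage target per molecule
  drawn <- tapply(lr$truth$length, lr$truth$clone_id, sum)
  expect_true(all(drawn >= 5 * Biostrings::width(lib$molecules)[
    match(names(drawn), names(lib$molecules))]))
})

test_that("paired short reads follow the deterministic pair-count formula", {
  cfg <- tiny_config(seed = 23L, n_clones = 2, short_read_coverage = 4)
  com <- generate_community(cfg)
  lib <- build_fosmid_library(com, cfg)
  sr <- simulate_short_reads(lib, cfg)
  counts <- table(sr$truth$clone_id)
  L <- Biostrings::width(lib$molecules)[match(names(counts),
                                              names(lib$molecules))]
  expect_equal(as.vector(counts),
               as.vector(ceiling(4 * L / (2 * cfg$short_read_len))))
  expect_true(all(Biostrings::width(sr$r1) == cfg$short_read_len))
  expect_true(all(Biostrings::width(sr$r2) == cfg$short_read_len))
  # error-free R1/R2 match the fragment ends on the doubled molecule
  t1 <- sr$truth[1, ]
  dbl <- strrep(as.character(lib$molecules[[t1$clone_id]]), 2)
  frag <- substr(dbl, t1$frag_start, t1$frag_start + t1$frag_len - 1)
  expect_identical(as.character(sr$r1[[paste0(t1$pair_id, "/1")]]),
                   substr(frag, 1, cfg$short_read_len))
  expect_identical(as.character(sr$r2[[paste0(t1$pair_id, "/2")]]),
                   oracle_revcomp(substr(frag, t1$frag_len - cfg$short_read_len + 1,
                                         t1$frag_len)))
})
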