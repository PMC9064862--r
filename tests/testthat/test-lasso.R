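# a designed precursor ORF with exactly one qualifying leader/core split:
# 18-aa leader (no Gly, Thr at -2), core GWNFKHRDWFRK (Gly donor, single
# Asp acceptor at ring position 8, 4-aa tail)
designed_precursor <- function(leader = "MNKWKNQLRLFNPKWMTL",
                               core = "GWNFKHRDWFRK") {
  paste0(oracle_aa2dna(paste0(leader, core)), "TAA")
}

embed_orf <- function(orf, seed) {
  set.seed(seed)
  list(seq = paste0(oracle_random_dna(150), orf, oracle_random_dna(150)),
       start = 151L, end = 150L + nchar(orf))
}

test_that("gene classification follows rule precedence and size windows", {
  # B2 outranks B1 when both fire
  both <- classify_gene(350, "PqqD-like lasso peptide biosynthesis B2 protein",
                        "-")
  expect_equal(both$label, "B2")
  expect_true(any(startsWith(both$rationale, "B1")))
  expect_true(any(startsWith(both$rationale, "B2")))
  # size windows are inclusive and exclude out-of-range evidence
  expect_equal(classify_gene(1500, "asparagine synthetase B", "-")$label, "C")
  expect_equal(classify_gene(1499, "asparagine synthetase B", "-")$label, "none")
  expect_equal(classify_gene(600, "ABC transporter permease", "-")$label, "D")
  expect_equal(classify_gene(1300, "ABC transporter permease", "-")$label,
               "none")
  # the small-gene scan rule needs a passing precursor scan
  expect_equal(classify_gene(141, "Hypothetical protein", "-")$label, "none")
  expect_equal(classify_gene(141, "Hypothetical protein", "-",
                             precursor_ok = TRUE)$label, "A")
  expect_equal(classify_gene(211, "Hypothetical protein", "-",
                             precursor_ok = TRUE)$label, "none")
  # 'none' carries an empty rationale
  expect_identical(classify_gene(975, "Hypothetical protein", "-")$rationale,
                   character(0))
})

test_that("the designed precursor is found with its single split", {
  orf <- designed_precursor()
  emb <- embed_orf(orf, 41)
  cand <- scan_precursors(emb$seq)
  hit <- cand[cand$orf_start == emb$start & cand$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$core_seq, "GWNFKHRDWFRK")
  expect_equal(hit$ring_acceptor_pos, 8L)
  expect_equal(hit$acceptor_residue, "D")
  expect_equal(hit$minus2_residue, "T")
  expect_equal(hit$tail_len_aa, 4L)
  expect_equal(hit$orf_end, emb$end)
})

test_that("every precursor rule is individually falsifiable by knockout", {
  base_leader <- "MNKWKNQLRLFNPKWMTL"
  no_hit_at <- function(orf, seed) {
    emb <- embed_orf(orf, seed)
    cand <- scan_precursors(emb$seq)
    nrow(cand[cand$orf_start == emb$start & cand$strand == "+", ])
  }
  # donor Gly -> Trp
  expect_equal(no_hit_at(designed_precursor(core = "WWNFKHRDWFRK"), 42), 0)
  # acceptor Asp -> Asn (no Glu anywhere in the core)
  expect_equal(no_hit_at(designed_precursor(core = "GWNFKHRNWFRK"), 43), 0)
  # Thr at leader -2 -> Pro
  expect_equal(no_hit_at(designed_precursor(
    leader = "MNKWKNQLRLFNPKWMPL"), 44), 0)
  # tail shorter than 3 residues
  expect_equal(no_hit_at(designed_precursor(core = "GWNFKHRDWF"), 45), 0)
  # acceptor outside ring positions 7-9
  expect_equal(no_hit_at(designed_precursor(core = "GWNFKHRWNDFRK"), 46), 0)
  # leader shorter than 8 aa
  expect_equal(no_hit_at(paste0(
    oracle_aa2dna("MNKWMTLGWNFKHRDWFRKWNQRK"), "TAA"), 47), 0)
})

test_that("relaxing the donor set only ever adds candidates", {
  set.seed(48)
  for (i in 1:5) {
    dna <- oracle_random_dna(1500)
    strict <- scan_precursors(dna, precursor_config(donor = "strict"))
    relaxed <- scan_precursors(dna, precursor_config(donor = "relaxed"))
    expect_true(all(precursor_keys(strict) %in% precursor_keys(relaxed)))
  }
  # an Ala-donor core is found only by the relaxed scan
  orf <- designed_precursor(core = "AWNFKHRDWFRK")
  emb <- embed_orf(orf, 49)
  s <- scan_precursors(emb$seq, precursor_config(donor = "strict"))
  r <- scan_precursors(emb$seq, precursor_config(donor = "relaxed"))
  expect_equal(nrow(s[s$orf_start == emb$start & s$strand == "+", ]), 0)
  expect_equal(nrow(r[r$orf_start == emb$start & r$strand == "+", ]), 1)
})

test_that("completeness needs A, C and both halves of B (or a fused B)", {
  expect_equal(assess_completeness(c("A", "B1", "B2", "C"))$status, "complete")
  expect_equal(assess_completeness(c("A", "B", "C"))$status, "complete")
  inc <- assess_completeness(c("A", "B1", "C"))
  expect_equal(inc$status, "incomplete")
  expect_equal(inc$missing, "B2")
  expect_true(assess_completeness(c("A", "B1", "B2", "C", "D"))$has_transporter)
  # a fused gene firing both B1 and B2 rules satisfies B
  fused <- classify_genes(data.frame(
    gene_id = c("g1", "g2", "g3"),
    size_bp = c(141, 350, 1905),
    description = c("Hypothetical protein",
                    "PqqD-like lasso peptide biosynthesis B2 protein",
                    "asparagine synthetase"),
    domain_tag = "-", precursor_ok = c(TRUE, NA, NA),
    stringsAsFactors = FALSE))
  expect_equal(assess_completeness(fused)$status, "complete")
})

test_that("region annotation rescues unlabelled small genes via the scanner", {
  cfg <- sim_config(n_fragments = 1, fragment_len = c(60000, 60000),
                    n_clones = 2, insert_len = c(30000, 35000),
                    bgc_plan = data.frame(bgc_id = "L1", class = "lasso",
                                          length_bp = NA_integer_,
                                          transporter = TRUE,
                                          stringsAsFactors = FALSE),
                    seed = 51L)
  com <- generate_community(cfg)
  r <- com$regions[1, ]
  region_seq <- substr(as.character(com$fragments[[r$seqid]]), r$start, r$end)
  ev <- com$genes
  ev$start <- ev$start - r$start + 1L
  ev$end <- ev$end - r$start + 1L
  ann <- annotate_lasso_region(region_seq, ev)
  got <- setNames(ann$genes$label, ann$genes$role)
  expect_equal(got[["A"]], "A")
  expect_equal(got[["B1"]], "B1")
  expect_equal(got[["B2"]], "B2")
  expect_equal(got[["C"]], "C")
  expect_equal(got[["D"]], "D")
  expect_equal(ann$completeness$status, "complete")
  expect_true(ann$completeness$has_transporter)
  expect_gt(nrow(ann$precursors), 0)
})
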