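test_that("tiling covers worked examples with the expected clone counts", {
  # one fosmid suffices when it spans the whole target
  one <- find_tiling_path(c(1000, 20000),
                          data.frame(clone_id = "cA", start = 500,
                                     end = 21000))
  expect_equal(one$clone_ids, "cA")
  expect_length(one$overlaps_bp, 0)
  # two overlapping fosmids with a 5 kb overlap
  two <- find_tiling_path(c(1, 58000),
                          data.frame(clone_id = c("cA", "cB"),
                                     start = c(1, 35001),
                                     end = c(40000, 70000)))
  expect_equal(two$clone_ids, c("cA", "cB"))
  expect_equal(two$overlaps_bp, 5000)
  expect_equal(two$covered_interval, c(1, 70000))
})

test_that("an uncoverable target raises a gap error with the gap interval", {
  al <- data.frame(clone_id = c("cA", "cB"), start = c(1, 50000),
                   end = c(30000, 80000))
  err <- tryCatch(find_tiling_path(c(1, 58000), al, min_overlap_bp = 500),
                  tiling_gap = identity)
  expect_s3_class(err, "tiling_gap")
  expect_equal(err$gap, c(30001, 49999))
  # insufficient overlap also fails even though the union covers
  al2 <- data.frame(clone_id = c("cA", "cB"), start = c(1, 29900),
                    end = c(30000, 60000))
  expect_error(find_tiling_path(c(1, 58000), al2, min_overlap_bp = 500),
               class = "tiling_gap")
  expect_equal(find_tiling_path(c(1, 58000), al2, min_overlap_bp = 100)$
                 clone_ids, c("cA", "cB"))
})

test_that("minus-strand alignments are excluded unless allowed", {
  al <- data.frame(clone_id = c("cA", "cB"), start = c(1, 1),
                   end = c(9000, 10000), strand = c("+", "-"))
  p <- find_tiling_path(c(1, 8000), al)
  expect_equal(p$clone_ids, "cA")
  p2 <- find_tiling_path(c(1, 8000), al, allow_reverse = TRUE)
  expect_equal(p2$clone_ids, "cB")
})

test_that("greedy tiling is minimum-cardinality on random instances", {
  set.seed(61)
  for (i in 1:25) {
    target <- c(1, sample(5000:40000, 1))
    n <- sample(3:9, 1)
    start <- sort(sample.int(target[2], n)) - sample.int(3000, n)
    len <- sample(4000:25000, n, replace = TRUE)
    al <- data.frame(clone_id = sprintf("c%02d", 1:n),
                     start = pmax(1, start), end = pmax(1, start) + len)
    oracle <- oracle_min_cover(target, al, 500)
    got <- tryCatch(length(find_tiling_path(target, al, 500)$clone_ids),
                    tiling_gap = function(e) Inf)
    expect_equal(got, oracle, info = paste("instance", i))
  }
})

test_that("digest arithmetic matches worked examples on both topologies", {
  circ <- predict_digest_fragments(topology = "circular", length = 73000,
                                   cut_positions = c(1, 57001))
  expect_equal(sort(circ$fragment_lengths_bp), c(16000, 57000))
  lin <- predict_digest_fragments(topology = "linear", length = 10000,
                                  cut_positions = 4000)
  expect_equal(sort(lin$fragment_lengths_bp), c(4000, 6000))
  one <- predict_digest_fragments(topology = "circular", length = 5000,
                                  cut_positions = 2000)
  expect_equal(one$fragment_lengths_bp, 5000)
  expect_warning(
    none <- predict_digest_fragments(topology = "circular", length = 5000,
                                     cut_positions = integer(0)),
    "zero fragments")
  expect_length(none$fragment_lengths_bp, 0)
})

test_that("site scanning finds planted sites on both strands", {
  set.seed(62)
  site <- "GACGTG"                       # non-palindromic
  backbone <- gsub("GACGTG|CACGTC", "ATATAT", oracle_random_dna(20000))
  s <- backbone
  substr(s, 3000, 3005) <- site
  substr(s, 9000, 9005) <- oracle_revcomp(site)
  dig <- predict_digest_fragments(s, site, "linear")
  expect_equal(dig$site_positions, oracle_site_positions(s, site))
  expect_equal(dig$site_positions, c(3000, 9000))
  # palindromic sites are counted once
  p <- backbone
  substr(p, 5000, 5007) <- "ATTTAAAT"
  digp <- predict_digest_fragments(p, "ATTTAAAT", "linear")
  expect_equal(digp$site_positions,
               oracle_site_positions(p, "ATTTAAAT"))
})

test_that("digest fragments conserve molecule length", {
  set.seed(63)
  for (i in 1:10) {
    L <- sample(5000:30000, 1)
    s <- oracle_random_dna(L)
    site <- "ATTTAAAT"
    for (k in 1:3) {
      at <- sample(100:(L - 100), 1)
      substr(s, at, at + 7) <- site
    }
    circ <- predict_digest_fragments(s, site, "circular")
    if (length(circ$fragment_lengths_bp) > 0) {
      expect_equal(sum(circ$fragment_lengths_bp), L)
    }
    lin <- predict_digest_fragments(s, site, "linear")
    expect_equal(sum(lin$fragment_lengths_bp), L)
  }
})

test_that("size filtering assigns reads to the nearest expected size", {
  got <- size_filter_reads(c(16500, 57100, 30000, 16000 * 1.11),
                           c(57000, 16000), rel_tol = 0.1)
  expect_equal(as.character(got), c("16000", "57000", NA, NA))
  # zero tolerance demands exact lengths; ties go to the smaller size
  exact <- size_filter_reads(c(100, 101), c(100, 200), rel_tol = 0)
  expect_equal(as.character(exact), c("100", NA))
  tie <- size_filter_reads(150, c(120, 180), rel_tol = 0.3)
  expect_equal(as.character(tie), "120")
})

test_that("assembly verification passes on faithful reads and fails on a deletion", {
  set.seed(64)
  frags <- c(fragA = oracle_random_dna(8000), fragB = oracle_random_dna(3000))
  good <- list(fragA = c(rA = oracle_substitute(frags[["fragA"]], 0.02)),
               fragB = c(rB = oracle_substitute(frags[["fragB"]], 0.02)))
  v <- verify_assembly(good, frags)
  expect_true(v$pass)
  # delete 2.5 kb (~31%) from the fragA read: containment must fail
  broken <- good
  rA <- broken$fragA[["rA"]]
  broken$fragA <- c(rA = paste0(substr(rA, 1, 3000), substr(rA, 5501, 8000)))
  v2 <- verify_assembly(broken, frags)
  expect_false(v2$pass)
  expect_false(v2$fragments$covered[v2$fragments$fragment == "fragA"])
  expect_true(v2$fragments$covered[v2$fragments$fragment == "fragB"])
  # a fragment with no reads at all is uncovered
  v3 <- verify_assembly(good["fragA"], frags)
  expect_false(v3$pass)
})

test_that("assembled constructs digest into exactly two fragments", {
  set.seed(65)
  ref <- oracle_random_dna(60000)
  path <- find_tiling_path(c(5000, 45000),
                           data.frame(clone_id = c("c1", "c2"),
                                      start = c(2000, 25000),
                                      end = c(30000, 50000)))
  asm <- assemble_construct(ref, path)
  dig <- predict_digest_fragments(asm$construct, asm$site, "circular")
  expect_length(dig$fragment_lengths_bp, 2)
  expect_equal(sum(dig$fragment_lengths_bp), nchar(asm$construct))
  expect_equal(asm$insert_interval, c(2000, 50000))
})
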