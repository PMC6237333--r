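test_that("motif scanning finds hits on both strands", {
  hits <- scan_motifs("AAATGTAAA", "ATGTA", 0)
  h <- hits[hits$strand == "H", ]
  expect_equal(h$position, 3L)
  # the complement motif is seen on the light strand at the same window
  hits2 <- scan_motifs("AAATGTAAA", "TACAT", 0)
  expect_true(any(hits2$strand == "L" & hits2$position == 3L))
  # motif longer than region: no hits, no error
  expect_equal(nrow(scan_motifs("ACGT", "ACGTACGTACGT", 0)), 0L)
})

test_that("planted motifs are recovered exactly from a random region", {
  set.seed(5)
  region <- sample(c("A", "C", "G", "T"), 866, replace = TRUE,
                   prob = c(0.35, 0.2, 0.12, 0.33))
  offsets <- c(101, 400, 777)
  for (o in offsets) region[o:(o + 6)] <- strsplit("GGTTTTT", "")[[1]]
  # break accidental copies elsewhere: rejection over the scan itself would
  # bias the test, so just assert the planted ones are among the hits
  hits <- scan_motifs(paste(region, collapse = ""), "GGTTTTT", 0)
  h <- hits[hits$strand == "H", ]
  expect_true(all(offsets %in% h$position))
  expect_true(all(h$mismatches == 0L))
})

test_that("mismatch allowances are honoured and reported", {
  hits <- scan_motifs("AACTTAATGAA", "CTTAATG", 0)
  expect_equal(hits$position[hits$strand == "H"], 3L)
  hits1 <- scan_motifs("AACTTACTGAA", data.frame(
    name = "conserved", sequence = "CTTAATG", max_mismatch = 1L))
  expect_true(any(hits1$strand == "H" & hits1$mismatches == 1L))
  expect_equal(nrow(scan_motifs("AACTTACTGAA", "CTTAATG", 0)[
    scan_motifs("AACTTACTGAA", "CTTAATG", 0)$strand == "H", , drop = FALSE]), 0L)
})

test_that("tandem repeats match the brute-force oracle", {
  r <- find_tandem_repeats("ACGACGACG")
  expect_equal(r$period, 3L)
  expect_equal(r$copies, 3)
  r2 <- find_tandem_repeats("AAAA", min_period = 1)
  expect_equal(r2$period, 1L)
  expect_equal(r2$copies, 4)
  set.seed(9)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                      prob = runif(4) + 0.2), collapse = "")
    got <- find_tandem_repeats(s, 1, 10, 2)
    want <- oracle_tandem(s, 1, 10, 2)
    expect_equal(got[c("start", "period", "copies", "span")],
                 want[c("start", "period", "copies", "span")],
                 ignore_attr = TRUE)
  }
})

test_that("repeat-free sequences yield an empty repeat table", {
  # a square-free word (Thue morphism a->abc, b->ac, c->b over three
  # letters) contains no tandem array of any period
  w <- "a"
  while (nchar(w) < 200) {
    w <- paste(unlist(lapply(strsplit(w, "")[[1]], function(x)
      switch(x, a = c("a", "b", "c"), b = c("a", "c"), c = "b"))),
      collapse = "")
  }
  s <- chartr("abc", "ACG", substr(w, 1, 200))
  expect_equal(nrow(oracle_tandem(s, 1, 10, 2)), 0L)
  expect_equal(nrow(find_tandem_repeats(s, 1, 10, 2)), 0L)
})

test_that("hairpin detection finds the maximal terminal stem", {
  h <- hairpin_check("GGGGAAAACCCC")
  expect_equal(h$stem_length, 4L)
  expect_equal(h$loop_length, 4L)
  expect_equal(h$paired_fraction, 8 / 12)
  expect_equal(hairpin_check("AAAAAAAA")$stem_length, 0L)
  # designed 38-mer from its own reverse complement folds deeply
  set.seed(2)
  half <- paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
  pal <- paste0(half, "AAAA", reverse_complement(half))
  expect_gte(hairpin_check(pal)$stem_length, 10L)
  expect_error(hairpin_check("ACGT"), "short")
})

test_that("the synthetic control region carries its planted signals", {
  sim <- get_sim()
  cr <- sim$truth$gene_seqs$CR
  hits <- scan_motifs(cr, default_csb_profile())
  planted <- sim$truth$cr_motifs
  for (k in seq_len(nrow(planted))) {
    expect_true(any(hits$position == planted$position[k] &
                      hits$mismatches == 0L))
  }
  ol <- sim$truth$gene_seqs$OL
  expect_gte(hairpin_check(ol)$stem_length, 10L)
})
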