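code <- genetic_code(2)

test_that("the vertebrate mitochondrial code has its table-2 idiosyncrasies", {
  expect_equal(length(code$map), 64L)
  expect_equal(unname(code$map["ATA"]), "M")
  expect_equal(unname(code$map["TGA"]), "W")
  expect_setequal(code$stop_codons, c("TAA", "TAG", "AGA", "AGG"))
  expect_equal(length(code$sense_codons), 60L)
  expect_setequal(code$families[["M"]], c("ATA", "ATG"))
  expect_equal(length(code$families[["L"]]), 6L)
  expect_equal(length(code$families[["S"]]), 6L)  # TCN + AGT/AGC
})

test_that("codon extraction classifies complete and incomplete stops", {
  res <- extract_codons("ATGAAATAA", code)
  expect_equal(res$codons, c("ATG", "AAA"))
  expect_equal(res$classification$stop_codon, "TAA")
  expect_true(res$classification$stop_complete)

  # a 691 bp CDS like cox2: 230 codons plus an incomplete T stop
  sim <- get_sim()
  f <- sim$table$features
  cox2 <- extract_gene_sequence(sim$record, f[f$name == "cox2", ])
  expect_equal(nchar(cox2), 691L)
  res2 <- extract_codons(cox2, code)
  expect_equal(length(res2$codons), 230L)
  expect_equal(res2$classification$stop_codon, "T")
  expect_false(res2$classification$stop_complete)

  res3 <- extract_codons("ATGAAACA", code)  # length mod 3 = 2
  expect_equal(res3$classification$stop_codon, "CA")
  expect_false(res3$classification$stop_complete)

  expect_error(extract_codons("ATGTAAAAATAA", code), "internal stop")

  # bookkeeping: 3 * codons + stop length = CDS length
  for (g in c("nad1", "cox2", "nad4", "cytb", "atp8")) {
    s <- extract_gene_sequence(sim$record, f[f$name == g, ])
    r <- extract_codons(s, code)
    stop_len <- if (is.na(r$classification$stop_codon)) 0L else
      nchar(r$classification$stop_codon)
    expect_equal(3L * length(r$codons) + stop_len, nchar(s))
  }
})

test_that("published CDS lengths leave the right incomplete-stop remainders", {
  ft <- hquoyi_feature_table()
  f <- ft$features[ft$features$class == "PCG", ]
  lens <- f$end - f$start + 1L
  rem <- stats::setNames(lens %% 3L, f$name)
  expect_setequal(names(rem)[rem == 1L], c("cox2", "nad4", "cytb"))
  expect_true(all(rem[!names(rem) %in% c("cox2", "nad4", "cytb")] == 0L))
  expect_setequal(f$name[f$stop_codon == "T"], c("cox2", "nad4", "cytb"))
  expect_equal(f$start_codon[f$name == "cox1"], "GTG")
  expect_true(all(f$start_codon[f$name != "cox1"] == "ATG"))
})

test_that("start-codon classification flags non-canonical initiators", {
  expect_false(classify_start("GTGAAA", code)$canonical)
  expect_true(classify_start("GTGAAA", code)$initiator)
  expect_true(classify_start("ATGAAA", code)$canonical)
  res <- classify_start("TTTAAA", code)
  expect_equal(res$codon, "TTT")
  expect_false(res$canonical)
  expect_false(res$initiator)
})

test_that("RSCU normalizes to family mean 1 and handles edge cases", {
  counts <- stats::setNames(integer(64), names(code$map))
  counts[c("TTA", "CTA", "CTG")] <- c(2L, 1L, 1L)
  r <- rscu(counts, code)
  expect_equal(r$rscu[r$codon == "TTA"], 3.0)  # 2 / (4/6)
  # uniform 4-fold family
  counts2 <- stats::setNames(integer(64), names(code$map))
  counts2[c("GCT", "GCC", "GCA", "GCG")] <- 5L
  r2 <- rscu(counts2, code)
  expect_true(all(r2$rscu[r2$aa == "A"] == 1))
  # zero-total family is NA, not zero
  expect_true(all(is.na(r2$rscu[r2$aa == "K"])))
  # family means equal 1 for random counts
  set.seed(3)
  for (i in 1:10) {
    cnt <- stats::setNames(rpois(64, 8), names(code$map))
    cnt[code$stop_codons] <- 0L
    rr <- rscu(cnt, code)
    means <- tapply(rr$rscu, rr$aa, mean)
    expect_true(all(abs(means - 1) < 1e-12))
  }
  # stop-codon counts are ignored with a warning
  cnt <- stats::setNames(integer(64), names(code$map))
  cnt["AGA"] <- 3L
  expect_warning(rscu(cnt, code), "stop")
})

test_that("translation follows the mitochondrial code", {
  expect_equal(as.character(translate_cds("ATATGA", code)), "MW")
  tr <- translate_cds("ATGAGA", code)
  expect_equal(as.character(tr), "M")
  expect_equal(attr(tr, "terminal_stop"), "AGA")
  expect_equal(as.character(translate_cds("ATGNNNAAA", code)), "MXK")
  expect_error(translate_cds("TAA", code), "empty translation")
})

test_that("codon counting respects the start/stop exclusion conventions", {
  cds <- "ATGAAAAAATAA"
  with_start <- codon_counts(cds, code, exclude_start = FALSE)
  without <- codon_counts(cds, code, exclude_start = TRUE)
  expect_equal(unname(with_start["ATG"]), 1L)
  expect_equal(unname(without["ATG"]), 0L)
  expect_equal(unname(without["AAA"]), 2L)
  expect_equal(unname(without["TAA"]), 0L)
})
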