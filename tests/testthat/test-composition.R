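test_that("skews follow the (A-T)/(A+T), (G-C)/(G+C) definitions", {
  expect_equal(round(at_skew(4838, 4550), 4), 0.0307)
  expect_equal(round(gc_skew(2534, 4603), 4), -0.2899)
  rep <- base_composition("ATATAT")
  expect_equal(rep$at_skew, 0)
  expect_true(is.na(rep$gc_skew))
  expect_error(base_composition(""), "non-empty")
})

test_that("skews are antisymmetric under reverse complement and bounded", {
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                      prob = runif(4)), collapse = "")
    a <- base_composition(s)
    b <- base_composition(reverse_complement(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
    expect_true(abs(a$at_skew) <= 1 && abs(a$gc_skew) <= 1)
  }
  # equal A and T counts give zero AT skew
  expect_equal(base_composition("AATTGG")$at_skew, 0)
})

test_that("N bases are excluded from counts used for skew and percentages", {
  rep <- base_composition("AANNTT")
  expect_equal(rep$at_skew, 0)
  expect_equal(sum(rep$counts[c("A", "C", "G", "T")]), 4L)
  expect_equal(rep$at_pct, 100)
})

test_that("codon-position composition matches a direct per-position tally", {
  sim <- get_sim()
  res <- pcg_concat_composition(sim$record, sim$table)
  f <- sim$table$features[sim$table$features$class == "PCG", ]
  # brute-force tally: walk every gene base by base with a 1,2,3 cycle
  tally <- matrix(0L, nrow = 3, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(f))) {
    s <- extract_gene_sequence(sim$record, f[i, ])
    ch <- strsplit(s, "")[[1]]
    for (k in seq_along(ch)) {
      pos <- ((k - 1) %% 3) + 1
      tally[pos, ch[k]] <- tally[pos, ch[k]] + 1L
    }
  }
  for (pos in 1:3) {
    got <- res[[paste0("pos", pos)]]$counts[c("A", "C", "G", "T")]
    expect_equal(unname(got), unname(tally[pos, ]))
  }
  expect_equal(unname(res$overall$counts[c("A", "C", "G", "T")]),
               unname(colSums(tally)))
  # a table missing PCGs is refused with the absent genes listed
  rec <- genome_record("toy", "ATGAAATAA", circular = FALSE)
  tab <- feature_table(data.frame(name = "nad1", class = "PCG",
                                  strand = "H", start = 1, end = 9))
  expect_error(pcg_concat_composition(rec, tab), "missing PCGs")
})

test_that("concatenation order does not change overall composition", {
  sim <- get_sim()
  f <- sim$table$features[sim$table$features$class == "PCG", ]
  seqs <- vapply(seq_len(nrow(f)),
                 function(i) extract_gene_sequence(sim$record, f[i, ]),
                 character(1))
  a <- base_composition(paste(seqs, collapse = ""))
  b <- base_composition(paste(rev(seqs), collapse = ""))
  expect_equal(a$counts, b$counts)
  expect_equal(a$at_skew, b$at_skew)
})

test_that("sliding GC skew agrees with per-window composition", {
  expect_true(all(sliding_gc_skew(strrep("G", 40), 10, 10)$gc_skew == 1))
  expect_true(all(sliding_gc_skew(strrep("GC", 20), 2, 2)$gc_skew == 0))
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  win <- sliding_gc_skew(s, 100, 50)
  for (k in seq_len(nrow(win))) {
    sub <- substr(s, win$start[k], win$start[k] + 99)
    expect_equal(win$gc_skew[k], base_composition(sub)$gc_skew)
  }
  expect_error(sliding_gc_skew(s, 0), "window")
  expect_error(sliding_gc_skew(s, 2000), "exceeds")
})

test_that("synthetic genomes hit their skew targets within 0.01", {
  sim <- get_sim()
  comp <- base_composition(sim$record$sequence)
  expect_lt(abs(comp$at_skew - 0.03), 0.01)
  expect_lt(abs(comp$gc_skew - (-0.29)), 0.01)
})
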