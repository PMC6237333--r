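test_that("simulation configs validate their invariants", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(target_at_skew = 1.2))
  expect_error(simulation_config(omega = -1))
  expect_error(generate_trna(trna_arms_spec(acceptor = 12)), "grid")
})

test_that("the synthetic mitogenome has canonical content and annotations", {
  sim <- get_sim()
  f <- sim$table$features
  expect_equal(nrow(f), 39L)  # 13 + 22 + 2 + OL + CR
  expect_equal(sum(f$class == "PCG"), 13L)
  expect_equal(sum(f$class == "tRNA"), 22L)
  expect_equal(f$start_codon[f$name == "cox1"], "GTG")
  expect_true(all(f$start_codon[f$class == "PCG" & f$name != "cox1"] == "ATG"))
  expect_setequal(f$name[!is.na(f$stop_codon) & f$stop_codon == "T"],
                  c("cox2", "nad4", "cytb"))
  # strand layout mirrors the vertebrate plan: nad6 + 8 tRNAs on L
  expect_equal(f$name[f$class == "PCG" & f$strand == "L"], "nad6")
  expect_equal(sum(f$class == "tRNA" & f$strand == "L"), 8L)
  # every PCG translates without internal stops
  code <- genetic_code(2)
  for (i in which(f$class == "PCG")) {
    cds <- extract_gene_sequence(sim$record, f[i, ])
    tr <- translate_cds(cds, code)
    expect_true(is.na(attr(tr, "internal_stop")))
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_mitogenome(simulation_config(seed = 3))
  b <- generate_mitogenome(simulation_config(seed = 3))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$table$features, b$table$features)
  t1 <- generate_trna(trna_arms_spec(), seed = 12)
  t2 <- generate_trna(trna_arms_spec(), seed = 12)
  expect_identical(t1, t2)
  e1 <- evolve_codon_alignment("ATGAAACCC", "(x:0.1,y:0.1);", seed = 5)
  e2 <- evolve_codon_alignment("ATGAAACCC", "(x:0.1,y:0.1);", seed = 5)
  expect_identical(e1, e2)
})

test_that("codon evolution respects its limit cases", {
  code <- genetic_code(2)
  set.seed(31)
  anc <- paste(sample(code$sense_codons, 200, replace = TRUE), collapse = "")
  # omega 0: every realized substitution is synonymous, so all three
  # protein sequences coincide while the DNA has diverged
  aln <- evolve_codon_alignment(anc, "(x:0.3,y:0.3);", omega = 0, seed = 2)
  expect_false(aln[["x"]] == aln[["y"]])
  expect_equal(as.character(translate_cds(aln[["x"]], code)),
               as.character(translate_cds(anc, code)))
  expect_equal(as.character(translate_cds(aln[["y"]], code)),
               as.character(translate_cds(anc, code)))
  r <- kaks_pair(aln[["x"]], aln[["y"]], code)
  expect_gt(r$Sd, 0)
  expect_lt(r$Ka, r$Ks)
  # zero branch lengths: descendants identical to the ancestor
  aln0 <- evolve_codon_alignment(anc, "(x:0,y:0);", omega = 0.1, seed = 2)
  expect_equal(unname(aln0[["x"]]), anc)
  # no stop codons ever appear
  for (s in aln) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% code$stop_codons))
  }
  expect_error(evolve_codon_alignment(anc, "(x:0.1,y:0.1);", omega = -0.5),
               "omega")
  expect_error(evolve_codon_alignment("ATGTAA", "(x:0.1,y:0.1);"), "stop")
})

test_that("synthetic genomes pass the package's own validation cleanly", {
  sim <- get_sim()
  expect_warning(regardless <- characterize(sim$table, sim$record), NA)
  expect_true(all(vapply(regardless[c("architecture", "composition", "codon",
                                      "control_region", "trna")],
                         function(s) s$status == "ok", logical(1))))
  # the designed tRNA truths are recovered by the structural stage
  models <- regardless$trna$result$models
  expect_equal(regardless$trna$result$dhu_less, "trnS2")
  for (nm in names(models)) {
    expect_equal(models[[nm]]$anticodon_arm$anticodon,
                 sim$truth$trna[[nm]]$anticodon)
  }
  expect_equal(regardless$trna$result$gu_total,
               sum(vapply(sim$truth$trna, function(t) t$gu_pairs, integer(1))))
})
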