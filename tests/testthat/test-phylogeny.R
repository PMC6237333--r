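toy_alignments <- list(
  g1 = c(A = "AAACCC", B = "AAACCG", C = "AAACGG"),
  g2 = c(A = "TTTGGGAAA", B = "TTTGGGAAC", C = "TTTGGCAAC")
)

test_that("supermatrix concatenation tracks widths and partitions", {
  sm <- concatenate_alignments(toy_alignments)
  expect_equal(nchar(sm$seqs[["A"]]), 15L)
  expect_equal(sm$partitions$start, c(1L, 7L))
  expect_equal(sm$partitions$end, c(6L, 15L))
  # permuting gene order changes the partition map, not the column multiset
  sm2 <- concatenate_alignments(rev(toy_alignments))
  expect_equal(sm2$partitions$gene, c("g2", "g1"))
  expect_equal(sort(strsplit(sm$seqs[["A"]], "")[[1]]),
               sort(strsplit(sm2$seqs[["A"]], "")[[1]]))
  # taxon holes are refused with the gene x taxon location
  broken <- toy_alignments
  broken$g2 <- broken$g2[c("A", "B")]
  expect_error(concatenate_alignments(broken), "g2")
  # unaligned input is refused
  ragged <- list(g1 = c(A = "AAA", B = "AAAA", C = "AAA"))
  expect_error(concatenate_alignments(ragged), "not aligned")
})

test_that("supermatrix width equals the summed gene lengths on simulated data", {
  tree <- ape::rtree(26, br = 0.05)
  genes <- stats::setNames(c(30L, 45L, 60L), c("nad1", "cox1", "cytb"))
  aln <- simulate_gene_alignments(tree, genes, seed = 8)
  sm <- concatenate_alignments(aln)
  expect_equal(nchar(sm$seqs[[1L]]), sum(3L * genes))
  expect_equal(length(sm$taxa), 26L)
  # canonical gene order applies to recognized PCG names
  expect_equal(sm$partitions$gene, c("nad1", "cox1", "cytb"))
})

test_that("distance models behave as their closed forms dictate", {
  sm <- concatenate_alignments(list(g = c(a = "ACGT", b = "ACGT", c = "ACGT")))
  D <- distance_matrix(sm, "p")
  expect_true(all(D == 0))
  # 100 nt with 10 transitions, no transversions: K2P = -0.5 log(0.8)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  sm2 <- concatenate_alignments(list(g = c(x = a, y = b)))
  expect_equal(distance_matrix(sm2, "K2P")["x", "y"], -0.5 * log(0.8),
               tolerance = 1e-9)
  expect_equal(distance_matrix(sm2, "p")["x", "y"], 0.1, tolerance = 1e-9)
  # JC69 >= p across the defined range
  set.seed(30)
  for (i in 1:10) {
    n <- 300
    nm <- sample(10:200, 1)
    x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    y <- x
    pos <- sample(n, nm)
    y[pos] <- vapply(y[pos], function(bb)
      sample(setdiff(c("A", "C", "G", "T"), bb), 1), character(1))
    smi <- concatenate_alignments(list(g = c(x = paste(x, collapse = ""),
                                             y = paste(y, collapse = ""))))
    p <- distance_matrix(smi, "p")["x", "y"]
    jc <- distance_matrix(smi, "JC69")["x", "y"]
    if (!is.nan(jc)) expect_gte(jc, p)
  }
})

test_that("neighbor joining solves the three-taxon closed form and additive matrices", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.5, 1.5, 2.5))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  # tree-additive matrices return the generating topology
  set.seed(12)
  for (i in 1:10) {
    t0 <- ape::rtree(sample(5:10, 1), br = stats::runif(18, 0.05, 0.5))
    Dm <- ape::cophenetic.phylo(t0)
    expect_equal(robinson_foulds(neighbor_joining(Dm), t0), 0)
  }
  # a minimally perturbed 4-taxon matrix still yields a tree
  t4 <- ape::rtree(4, br = 0.3)
  D4 <- ape::cophenetic.phylo(t4)
  D4[1, 2] <- D4[2, 1] <- D4[1, 2] * 1.05
  expect_s3_class(neighbor_joining(D4), "phylo")
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # zero-variation matrix: every replicate reproduces the same tree
  sm <- concatenate_alignments(list(g = c(a = strrep("ACGT", 25),
                                          b = strrep("ACGT", 25),
                                          c = strrep("ACGT", 25),
                                          d = strrep("ACGT", 25))))
  tr <- bootstrap_nj(sm, replicates = 10, seed = 3)
  expect_true(all(as.numeric(tr$node.label[-1]) == 100))
  # long-branch-separated 8-taxon tree: true bipartitions strongly supported
  t8 <- ape::read.tree(text = paste0(
    "(((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3):0.3,",
    "((e:0.02,f:0.02):0.3,(g:0.02,h:0.02):0.3):0.3);"))
  aln <- simulate_gene_alignments(t8, c(gene = 250L), omega = 0.5, seed = 14)
  sm8 <- concatenate_alignments(aln)
  tr8 <- bootstrap_nj(sm8, replicates = 100, seed = 9)
  expect_equal(robinson_foulds(tr8, t8), 0)
  supports <- as.numeric(tr8$node.label[-1])
  expect_true(all(supports >= 95))
  # fixed seed reproduces supports exactly
  tr8b <- bootstrap_nj(sm8, replicates = 100, seed = 9)
  expect_identical(tr8$node.label, tr8b$node.label)
})

test_that("monophyly testing roots on the outgroup and names intruders", {
  expect_true(is_monophyletic_group("((A,B),(C,D));", c("A", "B"), "D")$monophyletic)
  res <- is_monophyletic_group("((A,(B,X)),out);", c("A", "B"), "out")
  expect_false(res$monophyletic)
  expect_equal(res$intruders, "X")
  expect_error(is_monophyletic_group("((A,B),(C,D));", c("A", "Z"), "D"),
               "unknown taxa")
})

test_that("supermatrix exports are readable text formats", {
  sm <- concatenate_alignments(toy_alignments)
  phy <- tempfile(); write_phylip(sm, phy)
  first <- readLines(phy, n = 1)
  expect_equal(first, "3 15")
  nex <- tempfile(); write_nexus(sm, nex)
  txt <- readLines(nex)
  expect_true(any(grepl("CHARSET g1 = 1-6;", txt)))
  expect_true(any(grepl("NTAX=3 NCHAR=15", txt)))
})
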