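ft <- hquoyi_feature_table()

test_that("feature lengths reproduce the published annotation arithmetic", {
  lens <- feature_lengths(ft)
  expect_equal(unname(lens["nad5"]), 1839L)
  expect_equal(unname(lens["rrnS"]), 944L)
  expect_equal(unname(lens["rrnL"]), 1687L)
  expect_equal(unname(lens["CR"]), 866L)
  expect_equal(unname(lens["OL"]), 38L)
  expect_equal(unname(lens["atp8"]), 168L)
  pcg <- ft$features$name[ft$features$class == "PCG"]
  expect_equal(sum(lens[pcg]), 11433L)
  expect_equal(names(which.max(lens[pcg])), "nad5")
  # single-base feature
  one <- feature_table(data.frame(name = "x", class = "tRNA", strand = "H",
                                  start = 5, end = 5))
  expect_equal(unname(feature_lengths(one)), 1L)
})

test_that("adjacent gaps classify overlaps, spacers and abutting pairs", {
  g <- adjacent_gaps(ft)
  ov <- g$overlaps
  expect_equal(ov$bp[ov$upstream == "atp8" & ov$downstream == "atp6"], 11L)
  expect_equal(ov$bp[ov$upstream == "nad4l" & ov$downstream == "nad4"], 7L)
  # with OL as a feature the trnN-trnC region is two abutting joints
  expect_false(any(g$spacers$upstream == "trnN"))
  # excluding OL exposes the 38 bp spacer hosting the replication origin
  g2 <- adjacent_gaps(ft, ol_as_feature = FALSE)
  expect_equal(g2$spacers$bp[g2$spacers$upstream == "trnN" &
                               g2$spacers$downstream == "trnC"], 38L)
  expect_equal(max(g2$spacers$bp), 38L)
  # abutting features contribute to neither list
  toy <- feature_table(data.frame(name = c("a", "b"), class = "tRNA",
                                  strand = "H", start = c(1, 11), end = c(10, 20)),
                       circular = FALSE)
  gt <- adjacent_gaps(toy)
  expect_equal(nrow(gt$overlaps), 0L)
  expect_equal(nrow(gt$spacers), 0L)
})

test_that("strand distribution matches the published gene orientations", {
  sd <- strand_distribution(ft)
  expect_equal(sd$n[sd$class == "tRNA" & sd$strand == "L"], 8L)
  expect_equal(sd$n[sd$class == "PCG" & sd$strand == "L"], 1L)
  expect_equal(sd$n[sd$class == "PCG" & sd$strand == "H"], 12L)
  empty <- feature_table(data.frame(name = character(), class = character(),
                                    strand = character(), start = integer(),
                                    end = integer()), genome_length = 100L)
  expect_true(all(strand_distribution(empty)$n == 0L))
})

test_that("pairwise gaps agree with interval intersection on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    starts <- sort(sample(1:200, n))
    lens <- sample(5:40, n, replace = TRUE)
    ends <- starts + lens
    ends <- cummax(ends)  # no containment, ends non-decreasing
    tab <- feature_table(data.frame(name = paste0("f", 1:n), class = "tRNA",
                                    strand = "H", start = starts, end = ends),
                         genome_length = max(ends) + 10L, circular = FALSE)
    g <- adjacent_gaps(tab)
    f <- tab$features
    for (i in seq_len(n - 1)) {
      inter <- max(0L, min(f$end[i], f$end[i + 1]) - f$start[i + 1] + 1L)
      hit <- g$overlaps[g$overlaps$upstream == f$name[i], ]
      expect_equal(if (nrow(hit)) hit$bp else 0L, inter)
    }
  }
})

test_that("a fully tiled circular genome balances lengths, gaps and spacers", {
  sim <- get_sim()
  rep <- architecture_report(sim$table)
  g <- rep$gaps_ol_feature
  expect_equal(sum(rep$feature_lengths) - sum(g$overlaps$bp) + sum(g$spacers$bp),
               sim$table$genome_length)
  expect_equal(rep$pcg_total_length,
               sum(rep$feature_lengths[sim$table$features$class == "PCG"]))
})
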