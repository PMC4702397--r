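test_that("window genotype follows the 13-of-15 homozygote rule", {
  sm <- smooth_line(rep("A", 15), 1:15)
  expect_equal(sm$genotype, "A")
  sm <- smooth_line(c(rep("A", 13), "B", "B"), 1:15)
  expect_equal(sm$genotype, "A")
  sm <- smooth_line(c(rep("A", 12), rep("B", 3)), 1:15)
  expect_equal(sm$genotype, "H")
  sm <- smooth_line(c(rep("A", 8), rep("B", 7)), 1:15)
  expect_equal(sm$genotype, "H")
})

test_that("missing calls are skipped so each window holds 15 informative", {
  calls <- rep(c("A", NA), length.out = 40)        # 20 informative
  sm <- smooth_line(calls, 1:40)
  expect_equal(nrow(sm), 20 - 15 + 1)
  expect_true(all(sm$genotype == "A"))
  short <- smooth_line(rep(c("A", NA), 7), 1:14)   # 7 informative
  expect_true(isTRUE(attr(short, "uncallable")))
  expect_equal(nrow(short), 0)
})

test_that("breakpoints sit midway between the flanking supporting SNPs", {
  # A-run and B-run with flanking SNPs at 100,000 and 102,000 bp
  pos <- c(seq(2000, 100000, by = 2000), seq(102000, 200000, by = 2000))
  calls <- c(rep("A", 50), rep("B", 50))
  sm <- smooth_line(calls, pos)
  b <- detect_breakpoints(sm, "l", "s", extent = range(pos),
                          calls = calls, pos = pos)
  bp <- attr(b, "breakpoints")
  expect_equal(nrow(b), 2)
  expect_equal(bp$pos, 101000)
  expect_equal(b$genotype, c("A", "B"))
  # all-A line: a single block from first to last marker
  sm1 <- smooth_line(rep("A", 60), 1:60)
  b1 <- detect_breakpoints(sm1, "l", "s", extent = c(1, 60))
  expect_equal(nrow(b1), 1)
  expect_equal(c(b1$start, b1$end), c(1, 60))
  # A, H, B structure: 2 breakpoints, 3 blocks
  calls3 <- c(rep("A", 40), rep("H", 12), rep("B", 40))
  pos3 <- seq_along(calls3) * 100
  b3 <- detect_breakpoints(smooth_line(calls3, pos3), "l", "s",
                           extent = range(pos3), calls = calls3, pos = pos3)
  expect_equal(b3$genotype, c("A", "H", "B"))
  expect_equal(nrow(attr(b3, "breakpoints")), 2)
})

test_that("one flipped call inside a homozygous run never creates a block", {
  set.seed(99)
  for (rep_ in 1:150) {
    n <- sample(20:80, 1)
    calls <- rep("A", n)
    calls[sample(n, 1)] <- sample(c("B", "H"), 1)
    pos <- sort(sample(1e6, n))
    b <- detect_breakpoints(smooth_line(calls, pos), "l", "s",
                            extent = range(pos), calls = calls, pos = pos)
    expect_equal(nrow(b), 1)
    expect_equal(b$genotype, "A")
  }
})

test_that("bin boundaries are the union of breakpoints (K+1 counting)", {
  # two lines recombining at different positions on one sequence
  pos <- seq(1000, 120000, by = 1000)
  l1 <- c(rep("A", 40), rep("B", 80))
  l2 <- c(rep("A", 80), rep("B", 40))
  l3 <- rep("A", 120)
  gm <- structure(list(
    markers = data.frame(marker_id = paste0("m", seq_along(pos)),
                         scaffold = "s", pos = pos,
                         stringsAsFactors = FALSE),
    lines = c("l1", "l2", "l3"),
    calls = rbind(l1 = l1, l2 = l2, l3 = l3)), class = "genotype_matrix")
  colnames(gm$calls) <- gm$markers$marker_id
  blocks <- call_blocks(gm)
  bm <- build_bins(blocks)
  expect_equal(nrow(bm$bins), 3)             # 2 distinct breakpoints + 1
  expect_equal(unname(bm$geno["l1", ]), c("A", "B", "B"))
  expect_equal(unname(bm$geno["l2", ]), c("A", "A", "B"))
  expect_equal(unname(bm$geno["l3", ]), c("A", "A", "A"))
  expect_silent(check_bins(bm, blocks))
  # population with no breakpoints: one bin per sequence
  gm0 <- gm
  gm0$calls <- rbind(l1 = l3, l2 = l3)
  gm0$lines <- c("l1", "l2")
  bm0 <- build_bins(call_blocks(gm0))
  expect_equal(nrow(bm0$bins), 1)
})

test_that("a transition within a window of the sequence end is recovered", {
  # only 8 markers beyond the junction: no window can call the tail
  pos <- seq(1000, 48000, by = 1000)
  calls <- c(rep("A", 40), rep("B", 8))
  b <- detect_breakpoints(smooth_line(calls, pos), "l", "s",
                          extent = range(pos), calls = calls, pos = pos)
  expect_equal(b$genotype, c("A", "B"))
  expect_equal(attr(b, "breakpoints")$pos, 40500)
  # a genuine heterozygous tail is not converted into a homozygote
  calls2 <- c(rep("A", 40), rep("H", 8))
  b2 <- detect_breakpoints(smooth_line(calls2, pos), "l", "s",
                           extent = range(pos), calls = calls2, pos = pos)
  expect_true(all(b2$genotype %in% c("A", "H")))
  expect_false("B" %in% b2$genotype)
})

test_that("no bin contains a breakpoint of any line after re-scanning", {
  g <- simulate_genome(n_chrom = 2, chrom_len_bp = 6e6, cm_per_mb = 5,
                       n_scaffolds = 6, seed = 41)
  tr <- simulate_cross(g, n_lines = 80, n_generations = 8, seed = 42)
  gm <- observe_markers(tr, markers_per_scaffold = 40,
                        missing_rate = 0.2, error_rate = 0.005, seed = 43)
  blocks <- call_blocks(gm)
  bm <- build_bins(blocks)
  expect_silent(check_bins(bm, blocks))
})
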