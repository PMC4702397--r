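mk_calls <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("mk%d", seq_len(nrow(m)))
  m
}

test_that("allele calls are coded against the parental homozygotes", {
  parents <- mk_calls(c("G/G", "T/T"), c("A/A", "C/C"), c("G/G", "T/T"))
  lines <- mk_calls(c("G/G", "T/G", "./."),
                    c("C/C", "A/C", "A/A"),
                    c("T/T", "G/T", "G/G"))
  colnames(lines) <- c("l1", "l2", "l3")
  gm <- code_genotypes(parents, lines)
  expect_equal(unname(gm$calls["l1", ]), c("A", "B", "B"))
  expect_equal(unname(gm$calls["l2", ]), c("H", "H", "H"))
  expect_equal(unname(gm$calls["l3", ]), c(NA, "A", "A"))
  expect_equal(unname(gm$parent_calls[1, ]), c("A", "A", "A"))
  expect_equal(unname(gm$parent_calls[2, ]), c("B", "B", "B"))
})

test_that("multi-allelic sites are dropped with a logged reason", {
  parents <- mk_calls(c("G/G", "T/T"), c("G/G", "T/T"))
  lines <- mk_calls(c("G/G", "C/C"), c("G/T", "G/T"))
  colnames(lines) <- c("l1", "l2")
  gm <- code_genotypes(parents, lines)
  expect_equal(ncol(gm$calls), 1)
  dropped <- attr(gm, "dropped")
  expect_equal(dropped$reason, "multi-allelic")
})

test_that("marker filters apply the missingness, parent and distortion rules", {
  set.seed(42)
  n <- 430
  lines <- sprintf("l%03d", seq_len(n))
  calls <- matrix("A", nrow = n, ncol = 4,
                  dimnames = list(lines, paste0("m", 1:4)))
  calls[, 1] <- sample(c("A", "B"), n, replace = TRUE)      # balanced
  calls[seq_len(round(0.72 * n)), 2] <- NA                  # 72% missing
  calls[, 3] <- c(rep("A", 300), rep("B", 130))             # distorted
  calls[, 4] <- sample(c("A", "B"), n, replace = TRUE)
  pc <- matrix(rep(c("A", "B"), 4), nrow = 2,
               dimnames = list(c("P1", "P2"), paste0("m", 1:4)))
  pc[1, 4] <- "H"                                           # het parent
  gm <- structure(list(
    markers = data.frame(marker_id = paste0("m", 1:4), scaffold = "s",
                         pos = 1:4, stringsAsFactors = FALSE),
    lines = lines, calls = calls, parent_calls = pc),
    class = "genotype_matrix")
  flt <- filter_markers(gm)
  rep_ <- flt$report
  expect_false(rep_$removed[rep_$marker_id == "m1"])
  expect_equal(rep_$reason[rep_$marker_id == "m2"], "missingness")
  expect_equal(rep_$reason[rep_$marker_id == "m3"], "distortion")
  expect_equal(rep_$reason[rep_$marker_id == "m4"],
               "parent not homozygous")
  # chi-square oracle: (300-215)^2/215 + (130-215)^2/215 on A:B counts
  expect_equal(rep_$chisq[rep_$marker_id == "m3"],
               (300 - 215)^2 / 215 + (130 - 215)^2 / 215)
  # counts 200:230 survive: chisq 2.093, P ~ 0.148
  calls[, 3] <- c(rep("A", 200), rep("B", 230))
  gm$calls <- calls
  flt2 <- filter_markers(gm)
  expect_false(flt2$report$removed[3])
  expect_equal(flt2$report$chisq[3], (200 - 215)^2 / 215 + (230 - 215)^2 / 215)
  expect_equal(flt2$report$p[3], pchisq(2.093023, 1, lower.tail = FALSE),
               tolerance = 1e-5)
  # idempotence
  flt3 <- filter_markers(flt2$matrix)
  expect_identical(flt3$matrix$markers, flt2$matrix$markers)
  expect_false(any(flt3$report$removed))
  # all removed -> explicit error
  gm_bad <- gm
  gm_bad$parent_calls[1, ] <- "H"
  expect_error(filter_markers(gm_bad), "all markers removed")
})

test_that("distortion filter removes about seg_alpha of null markers", {
  set.seed(7)
  n <- 430; n_mk <- 2000
  calls <- matrix(sample(c("A", "B"), n * n_mk, replace = TRUE), nrow = n,
                  dimnames = list(sprintf("l%d", 1:n),
                                  sprintf("m%d", 1:n_mk)))
  gm <- structure(list(
    markers = data.frame(marker_id = colnames(calls), scaffold = "s",
                         pos = seq_len(n_mk), stringsAsFactors = FALSE),
    lines = rownames(calls), calls = calls,
    parent_calls = matrix(rep(c("A", "B"), n_mk), nrow = 2,
                          dimnames = list(c("P1", "P2"), colnames(calls)))),
    class = "genotype_matrix")
  frac <- mean(filter_markers(gm)$report$removed)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n_mk))
})

test_that("thinning caps markers per scaffold and keeps the ends", {
  g <- simulate_genome(n_chrom = 1, chrom_len_bp = 2e6, cm_per_mb = 4,
                       n_scaffolds = 2, seed = 31)
  tr <- simulate_cross(g, n_lines = 20, n_generations = 8, seed = 32)
  gm <- observe_markers(tr, markers_per_scaffold = 50, seed = 33)
  th <- thin_markers(gm, 10)
  cnt <- table(th$markers$scaffold)
  expect_true(all(cnt <= 10))
  for (s in unique(gm$markers$scaffold)) {
    full <- gm$markers[gm$markers$scaffold == s, ]
    kept <- th$markers[th$markers$scaffold == s, ]
    expect_equal(min(kept$pos), min(full$pos))
    expect_equal(max(kept$pos), max(full$pos))
  }
})
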