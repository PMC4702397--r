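# shared scan fixture: one chromosome of bins with markov-chain genotypes
make_scan_fixture <- function(n = 430, k = 40, step_r = 0.02, seed = 3) {
  set.seed(seed)
  g <- matrix("", n, k, dimnames = list(sprintf("l%03d", 1:n),
                                        sprintf("b%02d", 1:k)))
  g[, 1] <- sample(c("A", "B"), n, replace = TRUE)
  for (j in 2:k) {
    flip <- runif(n) < step_r
    g[, j] <- ifelse(flip, ifelse(g[, j - 1] == "A", "B", "A"), g[, j - 1])
  }
  bm <- toy_binmap(g)
  map <- build_genetic_map(bm, lod_min = 3)
  list(bm = bm, map = map, g = g)
}

test_that("a phenotype independent of genotype scans flat", {
  fx <- make_scan_fixture()
  set.seed(11)
  y <- setNames(rnorm(430), rownames(fx$g))
  pr <- lod_scan(fx$bm, fx$map, toy_pheno(y), "T")
  expect_lt(max(pr$lod), 4)
  expect_lt(mean(pr$lod), 0.7)
  expect_equal(call_qtls(pr, threshold = 3, binmap = fx$bm),
               call_qtls(pr, threshold = 3, binmap = fx$bm))
  expect_equal(nrow(call_qtls(pr, threshold = 3)), 0)
})

test_that("a perfect additive signal is recovered exactly", {
  fx <- make_scan_fixture()
  x <- ifelse(fx$g[, 20] == "A", 1, -1)
  y <- setNames(10 + 5 * x, rownames(fx$g))
  pr <- lod_scan(fx$bm, fx$map, toy_pheno(y), "T")
  at <- pr[pr$bin_id == "b20", ]
  expect_equal(at$additive, 5, tolerance = 1e-9)
  expect_equal(at$r2, 1, tolerance = 1e-9)
  expect_true(is.finite(at$lod) && at$lod > 100)   # guarded maximum
  expect_equal(pr$bin_id[which.max(pr$lod)], "b20")
})

test_that("simulated effect and R2 are estimated consistently", {
  fx <- make_scan_fixture()
  set.seed(12)
  x <- ifelse(fx$g[, 20] == "A", 1, -1)
  y <- setNames(5 * x + rnorm(430, 0, 5), rownames(fx$g))
  pr <- lod_scan(fx$bm, fx$map, toy_pheno(y), "T")
  at <- pr[which.max(pr$lod), ]
  expect_lt(abs(at$additive - 5), 0.5)
  expect_lt(abs(at$r2 - 0.5), 0.1)                 # a^2/(a^2+sigma^2)
  # lod and r2 invariant under affine transformation of the phenotype
  pr2 <- lod_scan(fx$bm, fx$map, toy_pheno(3 * y + 100), "T")
  expect_equal(pr2$lod, pr$lod, tolerance = 1e-8)
  expect_equal(pr2$r2, pr$r2, tolerance = 1e-8)
  expect_equal(pr2$additive, 3 * pr$additive, tolerance = 1e-8)
})

test_that("permutation threshold is a deterministic order statistic", {
  fx <- make_scan_fixture()
  set.seed(13)
  y <- setNames(rnorm(430), rownames(fx$g))
  ph <- toy_pheno(y)
  t1 <- permutation_threshold(fx$bm, fx$map, ph, "T", n_perm = 200, seed = 7)
  t2 <- permutation_threshold(fx$bm, fx$map, ph, "T", n_perm = 200, seed = 7)
  expect_equal(as.numeric(t1), as.numeric(t2))
  ml <- attr(t1, "max_lods")
  expect_length(ml, 200)
  expect_equal(as.numeric(t1), sort(ml)[ceiling(0.95 * 200)])
  # alpha = 1: the minimum of the max-lods
  t_all <- permutation_threshold(fx$bm, fx$map, ph, "T", n_perm = 200,
                                 alpha = 1, seed = 7)
  expect_equal(as.numeric(t_all), min(attr(t_all, "max_lods")))
  expect_warning(permutation_threshold(fx$bm, fx$map, ph, "T",
                                       n_perm = 50, seed = 7), "unstable")
})

test_that("peak calling names, brackets and merges across environments", {
  # long chromosome: the two QTLs are far enough apart that the profile
  # dips below the threshold between them
  fx <- make_scan_fixture(k = 80, step_r = 0.04, seed = 19)
  set.seed(14)
  x1 <- ifelse(fx$g[, 10] == "A", 1, -1)
  x2 <- ifelse(fx$g[, 70] == "A", 1, -1)
  prs <- lapply(c("E1", "E2"), function(e) {
    y <- setNames(4 * x1 + 4 * x2 + rnorm(430, 0, 4), rownames(fx$g))
    lod_scan(fx$bm, fx$map, toy_pheno(y, env = e), "T", env = e)
  })
  qq <- call_qtls(prs, threshold = 3, binmap = fx$bm)
  expect_equal(nrow(qq), 2)
  expect_equal(qq$name, c("qT-1.1", "qT-1.2"))     # indexed in cM order
  expect_true(all(qq$n_envs == 2))
  expect_true(all(qq$lod >= 3))
  # flanking bins bracket the peak
  ord <- fx$map$table$bin_id
  for (i in seq_len(nrow(qq))) {
    pk <- match(qq$bin_id[i], ord)
    expect_equal(qq$flank_left[i], ord[pk - 1])
    expect_equal(qq$flank_right[i], ord[pk + 1])
  }
})

test_that("composite interval mapping reduces to the plain scan without cofactors", {
  fx <- make_scan_fixture(n = 200, k = 40)
  set.seed(15)
  x <- ifelse(fx$g[, 12] == "A", 1, -1)
  y <- setNames(3 * x + rnorm(200, 0, 4), rownames(fx$g))
  ph <- toy_pheno(y)
  pr0 <- lod_scan(fx$bm, fx$map, ph, "T")
  pr_cim0 <- cim_scan(fx$bm, fx$map, ph, "T", n_cofactors = 0)
  expect_equal(pr_cim0$lod, pr0$lod, tolerance = 1e-8)
  expect_equal(pr_cim0$additive, pr0$additive, tolerance = 1e-8)
  # with cofactors, the profile far from the QTL window is deflated
  pr_cim <- cim_scan(fx$bm, fx$map, ph, "T", n_cofactors = 3)
  expect_true(length(attr(pr_cim, "cofactors")) >= 1)
  common <- intersect(pr_cim$bin_id, pr0$bin_id)
  peak_cm <- pr0$pos_cm[which.max(pr0$lod)]
  far <- common[abs(pr0$pos_cm[match(common, pr0$bin_id)] - peak_cm) > 15]
  expect_lte(mean(pr_cim$lod[match(far, pr_cim$bin_id)]),
             mean(pr0$lod[match(far, pr0$bin_id)]) + 0.5)
})

test_that("two linked QTLs in coupling are separated with cofactors", {
  fx <- make_scan_fixture(n = 430, k = 60, step_r = 0.015, seed = 16)
  set.seed(17)
  x1 <- ifelse(fx$g[, 15] == "A", 1, -1)
  x2 <- ifelse(fx$g[, 45] == "A", 1, -1)
  y <- setNames(2.5 * x1 + 2.5 * x2 + rnorm(430, 0, 4), rownames(fx$g))
  ph <- toy_pheno(y)
  pr_cim <- cim_scan(fx$bm, fx$map, ph, "T", n_cofactors = 5,
                     window_cm = 10)
  qq <- call_qtls(pr_cim, threshold = 3, binmap = fx$bm)
  expect_gte(nrow(qq), 2)
})
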