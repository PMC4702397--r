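test_that("two-point estimates match the plug-in likelihood formulas", {
  lines <- sprintf("l%03d", 1:100)
  g <- matrix(sample(c("A", "B"), 100, replace = TRUE), 100, 2,
              dimnames = list(lines, c("b1", "b2")))
  g[, 2] <- g[, 1]
  tp <- pairwise_rf(toy_binmap(g))
  expect_equal(tp$R["b1", "b2"], 0)
  expect_equal(tp$lod["b1", "b2"], 100 * log10(2))
  # 10 recombinants of 100
  g2 <- g
  flip <- 1:10
  g2[flip, 2] <- ifelse(g2[flip, 1] == "A", "B", "A")
  tp2 <- pairwise_rf(toy_binmap(g2))
  expect_equal(tp2$R["b1", "b2"], 0.1)
  expect_equal(tp2$lod["b1", "b2"], 90 * log10(1.8) + 10 * log10(0.2))
  expect_equal(tp2$r["b1", "b2"], 0.1 / (2 * 0.9))
  # H and missing excluded pairwise
  g3 <- g2
  g3[1:5, 1] <- "H"; g3[6:8, 2] <- NA
  tp3 <- pairwise_rf(toy_binmap(g3))
  expect_equal(tp3$n_inf["b1", "b2"], 92)
  # independent columns: R ~ 0.5, lod ~ 0
  set.seed(1)
  g4 <- matrix(sample(c("A", "B"), 2000, replace = TRUE), 1000, 2,
               dimnames = list(sprintf("l%d", 1:1000), c("b1", "b2")))
  tp4 <- pairwise_rf(toy_binmap(g4))
  expect_lt(abs(tp4$R["b1", "b2"] - 0.5), 0.05)
  expect_lt(tp4$lod["b1", "b2"], 1)
})

test_that("grouping is a transitive closure at the LOD threshold", {
  set.seed(5)
  n <- 200
  base1 <- sample(c("A", "B"), n, replace = TRUE)
  base2 <- sample(c("A", "B"), n, replace = TRUE)
  mut <- function(b, k) { i <- sample(n, k); b[i] <- ifelse(b[i] == "A", "B", "A"); b }
  g <- cbind(c1a = base1, c1b = mut(base1, 5), c1c = mut(base1, 10),
             c2a = base2, c2b = mut(base2, 5))
  rownames(g) <- sprintf("l%03d", 1:n)
  tp <- pairwise_rf(toy_binmap(g))
  grp <- group_bins(tp, lod_min = 4)
  expect_length(grp$groups, 2)
  expect_setequal(grp$groups[["LG01"]], c("c1a", "c1b", "c1c"))
  expect_setequal(grp$groups[["LG02"]], c("c2a", "c2b"))
  # infinite threshold: everything unplaced
  grp_inf <- group_bins(tp, lod_min = Inf)
  expect_length(grp_inf$groups, 0)
  expect_length(grp_inf$unplaced, 5)
})

test_that("ordering recovers a noiseless chain and never worsens in 2-opt", {
  set.seed(8)
  n <- 300
  k <- 12
  # markov chain of bins along a chromosome: few recombinants per step
  g <- matrix("", n, k, dimnames = list(sprintf("l%d", 1:n),
                                        sprintf("b%02d", 1:k)))
  g[, 1] <- sample(c("A", "B"), n, replace = TRUE)
  for (j in 2:k) {
    flip <- runif(n) < 0.04
    g[, j] <- ifelse(flip, ifelse(g[, j - 1] == "A", "B", "A"), g[, j - 1])
  }
  perm <- sample(k)
  tp <- pairwise_rf(toy_binmap(g[, perm]))
  ordr <- order_group(colnames(g)[perm], tp)
  expect_true(identical(ordr, sprintf("b%02d", 1:k)) ||
                identical(ordr, sprintf("b%02d", k:1)))
  # objective of the returned order does not exceed the identity order
  cost <- function(o) sum(tp$r[cbind(o[-length(o)], o[-1])])
  expect_lte(cost(ordr), cost(sort(colnames(g))))
  # 2-bin group: deterministic canonical order
  tp2 <- pairwise_rf(toy_binmap(g[, 1:2]))
  expect_equal(order_group(c("b02", "b01"), tp2), c("b01", "b02"))
})

test_that("Kosambi distances accumulate and surface inconsistent orders", {
  set.seed(9)
  n <- 400
  g <- matrix("", n, 3, dimnames = list(sprintf("l%d", 1:n), c("x", "y", "z")))
  g[, 1] <- sample(c("A", "B"), n, replace = TRUE)
  g[, 2] <- ifelse(runif(n) < 0.1, ifelse(g[, 1] == "A", "B", "A"), g[, 1])
  g[, 3] <- ifelse(runif(n) < 0.1, ifelse(g[, 2] == "A", "B", "A"), g[, 2])
  tp <- pairwise_rf(toy_binmap(g))
  gd <- genetic_distances(c("x", "y", "z"), tp)
  expect_equal(gd$pos_cm[1], 0)
  expect_equal(diff(gd$pos_cm),
               kosambi_d(tp$r[cbind(c("x", "y"), c("y", "z"))]))
  # r >= 0.5 between adjacent bins is an error, not a silent clamp
  g_bad <- g
  g_bad[, 3] <- sample(c("A", "B"), n, replace = TRUE)
  tp_bad <- pairwise_rf(toy_binmap(g_bad))
  if (tp_bad$r["y", "z"] >= 0.5)
    expect_error(genetic_distances(c("x", "y", "z"), tp_bad))
})

test_that("map summary arithmetic matches the counting identities", {
  st <- map_interval_stats(1522, 13, 1090.99)
  expect_equal(st$n_intervals, 1509)
  expect_equal(st$mean_interval_cm, 1090.99 / 1509)
  expect_equal(st$mean_group_length_cm, 1090.99 / 13)
  # degenerate map: one group, one bin
  st1 <- map_interval_stats(1, 1, 0)
  expect_true(is.na(st1$mean_interval_cm))
  expect_equal(st1$mean_group_length_cm, 0)
})
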