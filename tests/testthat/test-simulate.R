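test_that("simulated genome tiles chromosomes and records chimeras", {
  g <- simulate_genome(n_chrom = 3, chrom_len_bp = 5e6, cm_per_mb = 4,
                       n_scaffolds = 12, n_chimeras = 2, seed = 7)
  expect_equal(nrow(g$chromosomes), 3)
  expect_equal(g$chromosomes$length_cm, rep(5e6 * 4 / 1e6, 3))
  for (cn in g$chromosomes$chrom) {
    s <- g$scaffolds[g$scaffolds$chrom == cn, ]
    s <- s[order(s$start_bp), ]
    expect_equal(s$start_bp[1], 1)
    expect_equal(s$start_bp[-1], head(s$end_bp, -1) + 1)
    expect_equal(tail(s$end_bp, 1),
                 g$chromosomes$length_bp[g$chromosomes$chrom == cn])
  }
  expect_length(g$chimeras, 2)
  for (cid in g$chimeras) {
    parts <- g$scaffolds[g$scaffolds$scaffold_id == cid, ]
    expect_equal(nrow(parts), 2)
    expect_equal(length(unique(parts$chrom)), 2)
    spans <- parts[order(parts$scaff_start), ]
    expect_equal(spans$scaff_start[2], spans$scaff_end[1] + 1)
  }
  # seeded determinism
  g2 <- simulate_genome(n_chrom = 3, chrom_len_bp = 5e6, cm_per_mb = 4,
                        n_scaffolds = 12, n_chimeras = 2, seed = 7)
  expect_identical(g, g2)
  expect_error(simulate_genome(n_chrom = 1, chrom_len_bp = -5))
  g0 <- simulate_genome(n_chrom = 2, n_scaffolds = 6, n_chimeras = 0,
                        seed = 1)
  expect_equal(anyDuplicated(g0$scaffolds$scaffold_id), 0)
})

test_that("residual heterozygosity follows the Mendelian halving recursion", {
  g <- simulate_genome(n_chrom = 2, chrom_len_bp = 1e7, cm_per_mb = 4,
                       n_scaffolds = 4, seed = 5)
  pos <- seq(1, 1e7, length.out = 300)
  for (gen in c(4, 8)) {
    tr <- simulate_cross(g, n_lines = 150, n_generations = gen, seed = gen)
    het <- vapply(tr$lines, function(l)
      mean(c(true_genotype_at(tr, l, "chr01", pos),
             true_genotype_at(tr, l, "chr02", pos)) == "H"), numeric(1))
    expected <- 0.5^(gen - 1)
    se <- sd(het) / sqrt(length(het))
    expect_lt(abs(mean(het) - expected), 3 * se + 1e-12)
  }
})

test_that("per-locus genotype frequencies are balanced", {
  g <- simulate_genome(n_chrom = 1, chrom_len_bp = 1e7, cm_per_mb = 4,
                       n_scaffolds = 2, seed = 2)
  tr <- simulate_cross(g, n_lines = 400, n_generations = 8, seed = 3)
  pos <- seq(1, 1e7, length.out = 50)
  gm <- vapply(tr$lines, function(l) true_genotype_at(tr, l, "chr01", pos),
               character(50))
  fa <- rowMeans(gm == "A"); fb <- rowMeans(gm == "B")
  se <- sqrt(0.5 * 0.5 / 400) * sqrt(2)
  expect_true(mean(abs(fa - fb)) < 3 * se)
})

test_that("observed marker noise matches its binomial rates", {
  g <- simulate_genome(n_chrom = 2, chrom_len_bp = 5e6, cm_per_mb = 4,
                       n_scaffolds = 10, seed = 11)
  tr <- simulate_cross(g, n_lines = 60, n_generations = 8, seed = 12)
  clean <- observe_markers(tr, markers_per_scaffold = 30, seed = 13)
  # noiseless observation equals the truth projection
  l <- tr$lines[7]
  idx <- which(clean$markers$true_chrom == "chr02")
  expect_identical(unname(clean$calls[l, idx]),
                   true_genotype_at(tr, l, "chr02",
                                    clean$markers$true_pos[idx]))
  # missingness ~ Binomial(n, rate)
  noisy <- observe_markers(tr, markers_per_scaffold = 30,
                           missing_rate = 0.3, seed = 13)
  n <- length(noisy$calls)
  miss <- mean(is.na(noisy$calls))
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # error rate ~ Binomial; same seed keeps the marker placement fixed
  err <- observe_markers(tr, markers_per_scaffold = 30,
                         error_rate = 0.01, seed = 13)
  mm <- mean(err$calls != clean$calls, na.rm = TRUE)
  expect_lt(abs(mm - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  expect_error(observe_markers(tr, missing_rate = 1.2))
})

test_that("phenotype simulation realizes the requested architecture", {
  g <- simulate_genome(n_chrom = 2, chrom_len_bp = 5e6, cm_per_mb = 4,
                       n_scaffolds = 4, seed = 21)
  tr <- simulate_cross(g, n_lines = 430, n_generations = 8, seed = 22)
  # h2 -> 1: between-homozygote-class difference -> 2a
  sp <- qtl_spec(data.frame(trait = "T", chrom = "chr01", pos_bp = 2.5e6,
                            additive = 5), h2 = 1, env_effect_sd = 0,
                 n_env = 1, n_reps = 1)
  ph <- simulate_phenotypes(tr, sp, seed = 23)
  y <- line_means(ph, "T")
  gg <- vapply(names(y), function(l)
    true_genotype_at(tr, l, "chr01", 2.5e6), character(1))
  expect_equal(mean(y[gg == "A"]) - mean(y[gg == "B"]), 10,
               tolerance = 1e-9)
  # a = 5, residual sd = 1 -> marker R2 ~ 25/26
  sp2 <- qtl_spec(data.frame(trait = "T", chrom = "chr01", pos_bp = 2.5e6,
                             additive = 5), h2 = 25 / 26, env_effect_sd = 0,
                  n_env = 1, n_reps = 1)
  ph2 <- simulate_phenotypes(tr, sp2, seed = 24)
  y2 <- line_means(ph2, "T")
  ok <- gg %in% c("A", "B")
  x <- ifelse(gg[ok] == "A", 1, -1)
  r2 <- summary(lm(y2[ok] ~ x))$r.squared
  expect_equal(r2, 25 / 26, tolerance = 0.02)
  # inconsistent spec rejected
  expect_error(qtl_spec(data.frame(trait = "T", chrom = "chr01",
                                   pos_bp = 1, additive = 1),
                        h2 = 1, env_effect_sd = 2))
  expect_error(simulate_phenotypes(tr, qtl_spec(
    data.frame(trait = "T", chrom = "chr09", pos_bp = 1, additive = 1))))
})
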