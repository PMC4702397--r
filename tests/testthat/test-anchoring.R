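test_that("pseudomolecule assembly and AGP round-trip are exact", {
  seqs <- Biostrings::DNAStringSet(c(
    s1 = paste(rep("ACGT", 250), collapse = ""),
    s2 = paste(rep("GGCA", 250), collapse = "")))
  pl <- data.frame(scaffold_id = c("s1", "s2"), source_id = c("s1", "s2"),
                   object = "Chr01", mean_cm = c(0, 10),
                   orientation = c("+", "-"), src_start = 1, src_end = 1000,
                   n_bins = 2, rank = 1:2, stringsAsFactors = FALSE)
  ps <- write_pseudomolecules(pl, seqs, gap_len = 100)
  expect_equal(unname(Biostrings::width(ps$seqs)), 2100)
  built <- as.character(ps$seqs[["Chr01"]])
  expect_equal(substr(built, 1, 1000), as.character(seqs[["s1"]]))
  expect_equal(substr(built, 1001, 1100), strrep("N", 100))
  expect_equal(substr(built, 1101, 2100),
               as.character(Biostrings::reverseComplement(seqs[["s2"]])))
  # AGP -> FASTA rebuild is byte-identical
  rebuilt <- agp_to_fasta(ps$agp, seqs)
  expect_identical(as.character(ps$seqs), as.character(rebuilt))
  # file round trip
  f <- tempfile(fileext = ".agp")
  write_agp(ps$agp, f)
  agp2 <- read_agp(f)
  expect_identical(as.character(agp_to_fasta(agp2, seqs)),
                   as.character(ps$seqs))
  # missing sequence is a hard error naming the scaffold
  expect_error(write_pseudomolecules(pl, seqs["s1"]), "s2")
})

test_that("anchoring recovers order, orientation and chimera junctions", {
  gn <- simulate_genome(n_chrom = 4, chrom_len_bp = 1e7, cm_per_mb = 4.25,
                        n_scaffolds = 24, n_chimeras = 2, seed = 21)
  tr <- simulate_cross(gn, n_lines = 300, n_generations = 8, seed = 22)
  gm <- observe_markers(tr, markers_per_scaffold = 30, seed = 23)
  slen <- scaffold_lengths(gn)
  res <- build_anchored_map(gm, slen)
  expect_equal(length(unique(res$map$table$group)), 4)
  # both simulated chimeras split, within one bracketing marker gap of
  # the true junction
  expect_setequal(res$splits$scaffold_id, gn$chimeras)
  for (cid in gn$chimeras) {
    parts <- gn$scaffolds[gn$scaffolds$scaffold_id == cid, ]
    true_j <- min(parts$scaff_end)
    est <- res$splits$split_bp[res$splits$scaffold_id == cid]
    mpos <- sort(gm$markers$pos[gm$markers$scaffold == cid])
    lo <- max(mpos[mpos <= true_j])
    hi <- min(mpos[mpos > true_j])
    expect_gte(est, lo)
    expect_lte(est, hi)
  }
  # order and orientation recovery per pseudomolecule
  pl <- res$placements
  for (ob in unique(pl$object)) {
    p <- pl[pl$object == ob, ]
    p <- p[order(p$rank), ]
    tp <- lapply(seq_len(nrow(p)), function(i)
      true_tiling_part(gn, p$source_id[i], p$src_start[i], p$src_end[i]))
    tchrom <- vapply(tp, function(z) z$chrom, character(1))
    tstart <- vapply(tp, function(z) z$start_bp, numeric(1))
    tori <- vapply(tp, function(z) z$orientation, character(1))
    expect_equal(length(unique(tchrom)), 1)
    phys <- order(tstart)
    fwd <- identical(phys, seq_len(nrow(p)))
    rev_ <- identical(phys, rev(seq_len(nrow(p))))
    expect_true(fwd || rev_)
    informative <- p$orientation != "?" & p$n_bins >= 2
    expected <- if (rev_) ifelse(tori == "+", "-", "+") else tori
    expect_equal(p$orientation[informative], expected[informative])
  }
  # single-bin scaffolds carry undetermined orientation
  expect_true(all(pl$orientation[pl$n_bins < 2] == "?"))
  # AGP/FASTA round trip on the full assembly
  seqs <- simulate_scaffold_seqs(gn, seed = 24)
  ps <- write_pseudomolecules(pl, seqs)
  expect_identical(as.character(agp_to_fasta(ps$agp, seqs)),
                   as.character(ps$seqs))
  widths <- Biostrings::width(ps$seqs)
  for (ob in names(widths)) {
    rows <- ps$agp[ps$agp$object == ob, ]
    lens <- ifelse(rows$component_type == "U",
                   as.numeric(rows$component_id),
                   as.numeric(rows$component_end) -
                     as.numeric(rows$component_beg) + 1)
    expect_equal(sum(lens), unname(widths[ob]))
  }
  expect_gt(anchored_fraction(pl, slen), 0.9)
})

test_that("non-chimeric scaffolds produce no split record", {
  gn <- simulate_genome(n_chrom = 2, chrom_len_bp = 8e6, cm_per_mb = 4.25,
                        n_scaffolds = 10, n_chimeras = 0, seed = 31)
  tr <- simulate_cross(gn, n_lines = 200, n_generations = 8, seed = 32)
  gm <- observe_markers(tr, markers_per_scaffold = 30, seed = 33)
  res <- build_anchored_map(gm, scaffold_lengths(gn))
  expect_true(is.null(res$splits) || nrow(res$splits) == 0)
  expect_equal(length(unique(res$map$table$group)), 2)
})
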