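# Configuration and end-to-end orchestration of the study pipeline:
# simulate -> genotype -> bin -> map (+ anchor) -> pseudomolecules ->
# final bin map -> QTL -> trait stats.  Every run writes a config
# snapshot and a hash manifest so identical configs reproduce identical
# outputs.

#' Default pipeline configuration
#'
#' Stage parameters default to the values used throughout the package
#' (sliding window 15/13, missingness filter 0.70, distortion alpha 0.01,
#' grouping LOD 4.0, 1000 permutations at alpha 0.05, QTL LOD floor 2.5,
#' AGP gap 100 bp) and the simulation defaults emulate the study design:
#' 13 chromosomes of 20 Mb at 4.25 cM/Mb tiled by 325 scaffolds (6
#' chimeric), 430 F8 RILs, ~30 SNPs per scaffold, and two trait groups
#' with additive QTL R2 spanning ~0.03-0.46 over 3 environments x 3
#' replicates.
#'
#' @param ... Overrides of any default (e.g. `n_lines = 100`).
#' @return A `ril_config` list.
#' @export
ril_config <- function(...) {
  cfg <- list(
    # simulation
    n_chrom = 13, chrom_len_bp = 2e7, cm_per_mb = 4.25,
    n_scaffolds = 325, n_chimeras = 6,
    n_lines = 430, n_generations = 8,
    markers_per_scaffold = 30, missing_rate = 0.25, error_rate = 0.005,
    parent_missing_rate = 0.02, parent_error_rate = 0.002,
    # traits: additive effects chosen so marginal line-mean R2 spans
    # ~0.03-0.46 (see the methods vignette)
    traits = list(
      PH = list(chrom = c("chr03", "chr04", "chr08"),
                pos_bp = c(1.5e7, 6e6, 1.1e7),
                additive = c(sqrt(3), sqrt(8), sqrt(23)),
                h2 = 0.054, grand_mean = 150),
      SCb = list(chrom = c("chr04", "chr11"),
                 pos_bp = c(8e6, 2e6),
                 additive = c(sqrt(39), sqrt(10)),
                 h2 = 0.096, grand_mean = 20)),
    n_env = 3, n_reps = 3, env_effect_sd = 2,
    # marker filters
    max_missing = 0.70, seg_alpha = 0.01,
    # binning
    window = 15, threshold = 13,
    # linkage & anchoring
    lod_group = 4.0, foreign_tol = 3, max_gap_cm = 15, gap_len = 100,
    # QTL
    n_perm = 1000, alpha = 0.05, lod_min = 2.5, lod_drop = 1.5,
    seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "ril_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param cfg A `ril_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) yaml::write_yaml(unclass(cfg), path)

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- ril_config()
  over <- yaml::read_yaml(path)
  cfg[names(over)] <- over
  cfg
}

.cfg_qtl_spec <- function(cfg, trait_name) {
  tcfg <- cfg$traits[[trait_name]]
  qtl_spec(data.frame(trait = trait_name, chrom = tcfg$chrom,
                      pos_bp = tcfg$pos_bp, additive = tcfg$additive,
                      stringsAsFactors = FALSE),
           h2 = tcfg$h2, n_env = cfg$n_env, n_reps = cfg$n_reps,
           env_effect_sd = cfg$env_effect_sd,
           grand_mean = tcfg$grand_mean)
}

#' Run the pipeline end to end
#'
#' Executes the stages in order (`simulate`, `genotype`, `bin`, `map`,
#' `anchor`, `qtl`, `stats`), writing each stage's outputs under
#' `out_dir` together with a config snapshot and an md5 manifest.  Later
#' stages consume the in-memory results of earlier ones; a subset of
#' stages can be run provided the preceding stages ran in the same call
#' (stage inputs are also re-loadable from the written files by the
#' command-line driver).
#'
#' @param cfg A `ril_config`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (default all).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and `manifest`.
#' @export
run_pipeline <- function(cfg = ril_config(), out_dir = "rilmap_run",
                         stages = c("simulate", "genotype", "bin", "map",
                                    "anchor", "qtl", "stats"),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  say <- function(...) if (!quiet) message(...)
  res <- list(config = cfg)

  if ("simulate" %in% stages) {
    say("simulate: genome, cross, markers, phenotypes")
    res$genome <- simulate_genome(cfg$n_chrom, cfg$chrom_len_bp,
                                  cfg$cm_per_mb, cfg$n_scaffolds,
                                  cfg$n_chimeras, seed = cfg$seed)
    res$truth <- simulate_cross(res$genome, cfg$n_lines, cfg$n_generations,
                                seed = cfg$seed + 1)
    res$gm_raw <- observe_markers(res$truth, cfg$markers_per_scaffold,
                                  cfg$missing_rate, cfg$error_rate,
                                  cfg$parent_missing_rate,
                                  cfg$parent_error_rate,
                                  seed = cfg$seed + 2)
    res$scaffold_seqs <- simulate_scaffold_seqs(res$genome,
                                                seed = cfg$seed + 3)
    res$pheno <- do.call(rbind, lapply(seq_along(cfg$traits), function(i)
      simulate_phenotypes(res$truth, .cfg_qtl_spec(cfg, names(cfg$traits)[i]),
                          seed = cfg$seed + 10 + i)))
    write_vcf(res$gm_raw, file.path(out_dir, "markers.vcf"))
    Biostrings::writeXStringSet(res$scaffold_seqs,
                                file.path(out_dir, "scaffolds.fasta"))
    write_phenotypes_csv(res$pheno, file.path(out_dir, "phenotypes.csv"))
    write_truth_json(res$truth, file.path(out_dir, "truth.json"))
  }

  if ("genotype" %in% stages) {
    say("genotype: code against parents and filter")
    res$gm_raw <- NULL                       # reloaded from the VCF
    vc <- read_genotype_vcf(file.path(out_dir, "markers.vcf"))
    coded <- code_genotypes(vc$parent_calls, vc$line_calls, vc$markers)
    flt <- filter_markers(coded, cfg$max_missing, cfg$seg_alpha)
    res$gm <- flt$matrix
    res$filter_report <- flt$report
    write_genotype_tsv(res$gm, file.path(out_dir, "genotypes.tsv"))
    utils::write.csv(flt$report, file.path(out_dir, "filter_report.csv"),
                     row.names = FALSE)
  }

  if ("bin" %in% stages) {
    say("bin: per-scaffold window calls and primary bins")
    res$blocks_primary <- call_blocks(res$gm, window = cfg$window,
                                      threshold = cfg$threshold)
    res$binmap_primary <- build_bins(res$blocks_primary)
    write_bins(res$binmap_primary, file.path(out_dir, "bins_primary.bed"),
               file.path(out_dir, "bins_primary_geno.tsv"))
  }

  if ("map" %in% stages) {
    say("map: grouping, ordering, chimera resolution")
    slen <- scaffold_lengths(res$genome)
    res$anchored <- build_anchored_map(res$gm, slen, cfg$window,
                                       cfg$threshold, cfg$lod_group,
                                       cfg$foreign_tol, cfg$max_gap_cm)
    write_map_tsv(res$anchored$map, file.path(out_dir, "primary_map.tsv"))
    if (!is.null(res$anchored$splits))
      utils::write.csv(res$anchored$splits,
                       file.path(out_dir, "scaffold_splits.csv"),
                       row.names = FALSE)
    # the primary-map two-point matrices and block/bin intermediates are
    # written to disk above and can be large; keep the memory footprint
    # of a full-scale run bounded
    res$anchored$map$tp <- NULL
    res$anchored$binmap <- NULL
    res$anchored$blocks <- NULL
    res$blocks_primary <- NULL
    gc(FALSE)
  }

  if ("anchor" %in% stages) {
    say("anchor: pseudomolecules, AGP, final bin map")
    pl <- res$anchored$placements
    utils::write.table(pl, file.path(out_dir, "placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ps <- write_pseudomolecules(pl, res$scaffold_seqs, cfg$gap_len)
    Biostrings::writeXStringSet(ps$seqs,
                                file.path(out_dir, "pseudomolecules.fasta"))
    write_agp(ps$agp, file.path(out_dir, "pseudomolecules.agp"))
    if (length(ps$unplaced))
      Biostrings::writeXStringSet(res$scaffold_seqs[ps$unplaced],
                                  file.path(out_dir, "unplaced.fasta"))
    ps$seqs <- NULL                          # written above
    res$pseudomolecules <- ps
    res$scaffold_seqs <- NULL
    gc(FALSE)
    # final bin map on pseudomolecule coordinates
    gmp <- project_markers(res$anchored$gm, pl, cfg$gap_len)
    keep <- !is.na(gmp$markers$chrom)
    gmp$markers <- gmp$markers[keep, , drop = FALSE]
    gmp$calls <- gmp$calls[, keep, drop = FALSE]
    if (!is.null(gmp$parent_calls))
      gmp$parent_calls <- gmp$parent_calls[, keep, drop = FALSE]
    res$blocks_final <- call_blocks(gmp, seq_col = "chrom",
                                    pos_col = "chrom_pos",
                                    window = cfg$window,
                                    threshold = cfg$threshold)
    res$binmap <- build_bins(res$blocks_final)
    res$map <- build_genetic_map(res$binmap, cfg$lod_group)
    write_bins(res$binmap, file.path(out_dir, "bins.bed"),
               file.path(out_dir, "bins_geno.tsv"))
    write_map_tsv(res$map, file.path(out_dir, "map.tsv"))
    anchored_bp <- sum(pl$src_end - pl$src_start + 1)
    res$map_summary <- map_summary(res$map, anchored_bp)
    jsonlite::write_json(res$map_summary[c("n_groups", "n_bins", "total_cm",
                                           "mean_interval_cm",
                                           "mean_group_length_cm",
                                           "frac_intervals_lt_6cm",
                                           "cm_per_mb")],
                         file.path(out_dir, "map_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$map$tp <- NULL                       # bins^2 matrices; map.tsv holds
    res$blocks_final <- NULL                 # the downstream-relevant state
    gc(FALSE)
  }

  if ("qtl" %in% stages) {
    say("qtl: scans, permutation thresholds, peak calling")
    envs <- sort(unique(res$pheno$env))
    qtls <- list(); profiles <- list()
    for (tr in unique(res$pheno$trait)) {
      thr <- permutation_threshold(res$binmap, res$map, res$pheno, tr,
                                   env = NULL, n_perm = cfg$n_perm,
                                   alpha = cfg$alpha, seed = cfg$seed + 20)
      prs <- lapply(envs, function(e)
        lod_scan(res$binmap, res$map, res$pheno, tr, e))
      profiles[[tr]] <- do.call(rbind, prs)
      qq <- call_qtls(prs, thr, cfg$lod_min, cfg$lod_drop, res$binmap)
      qq$threshold <- rep(as.numeric(thr), nrow(qq))
      qtls[[tr]] <- qq
    }
    res$qtls <- do.call(rbind, qtls)
    rownames(res$qtls) <- NULL
    utils::write.csv(res$qtls, file.path(out_dir, "qtls.csv"),
                     row.names = FALSE)
    utils::write.table(do.call(rbind, profiles),
                       file.path(out_dir, "lod_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("stats" %in% stages) {
    say("stats: trait summaries, correlations, transgressives")
    res$trait_summary <- trait_summary(res$pheno)
    res$correlations <- trait_correlations(res$pheno)
    res$transgressive <- transgressive_segregation(res$pheno)
    utils::write.csv(res$trait_summary,
                     file.path(out_dir, "trait_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$correlations,
                     file.path(out_dir, "trait_correlations.csv"))
    utils::write.csv(res$transgressive,
                     file.path(out_dir, "transgressive.csv"),
                     row.names = FALSE)
  }

  files <- setdiff(list.files(out_dir, full.names = TRUE), "manifest.csv")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}
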