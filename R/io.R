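# Readers and writers for the package's external formats: VCF and TSV
# genotypes, phenotype CSV, bin BED + genotype TSV, map TSV, placements
# TSV, truth JSON.

#' Write a coded genotype matrix as VCF
#'
#' Minimal VCF 4.2 with GT-only genotypes; parents are the first two
#' samples.  Coded calls map to `0/0` (parent A allele), `1/1`, `0/1` and
#' `./.`.
#'
#' @param gm A `genotype_matrix` with `parent_calls`.
#' @param path Output path.
#' @export
write_vcf <- function(gm, path) {
  mk <- gm$markers
  gt_of <- function(v) c(A = "0/0", B = "1/1", H = "0/1")[v]
  gt_lines <- t(matrix(gt_of(gm$calls), nrow = nrow(gm$calls)))
  gt <- cbind(gt_of(gm$parent_calls[1, ]), gt_of(gm$parent_calls[2, ]),
              gt_lines)                     # markers x samples
  gt[is.na(gt)] <- "./."
  samples <- c("P1", "P2", gm$lines)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  body <- cbind(mk$scaffold, as.character(mk$pos), mk$marker_id,
                mk$allele_a, mk$allele_b, ".", "PASS", ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read parent and line calls from a VCF
#'
#' Reads GT genotypes with [vcfR::read.vcfR()] and converts them to
#' single-nucleotide allele pairs (`"G/T"` style) suitable for
#' [code_genotypes()].
#'
#' @param path VCF path.
#' @param parent_ids Sample names of the two parents (default the first
#'   two samples).
#' @return List with `markers` (data.frame `marker_id`, `scaffold`, `pos`),
#'   `parent_calls` and `line_calls` matrices.
#' @export
read_genotype_vcf <- function(path, parent_ids = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(parent_ids)) parent_ids <- samples[1:2]
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  conv <- function(g) {
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    n1 <- ifelse(a1 == "0", ref, ifelse(a1 == "1", alt, NA))
    n2 <- ifelse(a2 == "0", ref, ifelse(a2 == "1", alt, NA))
    ifelse(is.na(n1) | is.na(n2), "./.", paste0(n1, "/", n2))
  }
  calls <- apply(gt, 2, conv)
  markers <- data.frame(marker_id = if (all(is.na(fix[, "ID"])))
    paste0(fix[, "CHROM"], "_", fix[, "POS"]) else fix[, "ID"],
    scaffold = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    stringsAsFactors = FALSE)
  list(markers = markers,
       parent_calls = calls[, parent_ids, drop = FALSE],
       line_calls = calls[, setdiff(samples, parent_ids), drop = FALSE])
}

#' Write a coded genotype matrix as TSV
#'
#' Lines x markers symbols A/B/H/-; marker metadata in a sidecar header
#' block is avoided -- a companion `<path>.markers.tsv` carries it.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(gm, path) {
  m <- gm$calls
  m[is.na(m)] <- "-"
  utils::write.table(data.frame(line_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$markers, paste0(path, ".markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write bin definitions as BED and bin genotypes as TSV
#'
#' BED is 0-based half-open; the genotype TSV holds lines x bins symbols
#' A/B/H/-.
#'
#' @param binmap A `bin_map`.
#' @param bed_path,geno_path Output paths.
#' @export
write_bins <- function(binmap, bed_path, geno_path) {
  bed <- data.frame(binmap$bins$seq_id, binmap$bins$start - 1,
                    binmap$bins$end, binmap$bins$bin_id)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- binmap$geno
  g[is.na(g)] <- "-"
  utils::write.table(data.frame(line_id = rownames(g), g,
                                check.names = FALSE),
                     geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a genetic map as TSV
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write phenotypes as CSV
#'
#' @param pheno Phenotype table.
#' @param path Output path.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
}

#' Read phenotypes from CSV
#'
#' @param path CSV with columns `line_id`, `env`, `rep`, `trait`,
#'   `value` and optional `is_parent`.
#' @return Phenotype data.frame.
#' @export
read_phenotypes_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "env", "rep", "trait", "value")
  if (!all(need %in% names(p)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  p
}

#' Serialize the simulation truth to JSON
#'
#' @param truth A `ril_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    chromosomes = truth$genome$chromosomes,
    scaffolds = truth$genome$scaffolds,
    chimeras = truth$genome$chimeras,
    generation = truth$generation,
    segments = truth_segments(truth)), path, digits = NA)
}
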