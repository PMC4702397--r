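# Coding of raw biallelic calls against the two parents, and the marker
# filters applied before linkage mapping.

#' Code raw allele calls against the two parents
#'
#' Converts allele-level genotype calls (single-nucleotide pairs such as
#' `"G/G"`, `"G/T"`, `"./."`) for two inbred parents and a set of RIL lines
#' into the A/B/H coding used throughout the package: `A` if the line
#' matches the parent-1 homozygote, `B` if it matches the parent-2
#' homozygote, `H` if it carries both parental alleles, `NA` otherwise.
#' Sites with more than two alleles across parents and lines are dropped
#' and listed in the `dropped` attribute.  Markers whose parents are not
#' both homozygous for different alleles are kept uncoded (all `NA` line
#' calls) so that [filter_markers()] can report them.
#'
#' @param parent_calls Matrix of calls, markers x 2 (columns parent 1 =
#'   A-type, parent 2 = B-type).
#' @param line_calls Matrix of calls, markers x lines.
#' @param markers Optional data.frame of marker metadata with at least
#'   `marker_id`, `scaffold`, `pos`; defaults are built from row names.
#' @return A `genotype_matrix` (see [observe_markers()]); attribute
#'   `dropped` holds a data.frame of removed multi-allelic markers.
#' @export
code_genotypes <- function(parent_calls, line_calls, markers = NULL) {
  stopifnot(is.matrix(parent_calls), ncol(parent_calls) == 2,
            is.matrix(line_calls), nrow(line_calls) == nrow(parent_calls))
  n_mk <- nrow(parent_calls)
  if (is.null(markers)) {
    ids <- rownames(parent_calls)
    if (is.null(ids)) ids <- sprintf("mk%06d", seq_len(n_mk))
    markers <- data.frame(marker_id = ids, scaffold = "unknown",
                          pos = seq_len(n_mk), stringsAsFactors = FALSE)
  }

  split2 <- function(x) {
    x[x %in% c("./.", ".", "", NA)] <- NA_character_
    list(a1 = substr(x, 1, 1), a2 = substr(x, 3, 3))
  }
  p1 <- split2(parent_calls[, 1]); p2 <- split2(parent_calls[, 2])

  # multi-allelic screen across parents and lines
  alleles_per_marker <- function(m) {
    s <- split2(m)
    cbind(s$a1, s$a2)
  }
  all_al <- cbind(p1$a1, p1$a2, p2$a1, p2$a2,
                  alleles_per_marker(line_calls))
  n_alleles <- apply(all_al, 1, function(z) length(unique(z[!is.na(z) & z != "."])))
  multi <- n_alleles > 2
  dropped <- data.frame(marker_id = as.character(markers$marker_id[multi]),
                        reason = rep("multi-allelic", sum(multi)),
                        stringsAsFactors = FALSE)

  p1_hom <- !is.na(p1$a1) & p1$a1 == p1$a2
  p2_hom <- !is.na(p2$a1) & p2$a1 == p2$a2
  codable <- p1_hom & p2_hom & p1$a1 != p2$a1 & !multi

  allele_a <- ifelse(p1_hom, p1$a1, NA_character_)
  allele_b <- ifelse(p2_hom, p2$a1, NA_character_)

  keep <- !multi
  l1 <- split2(line_calls); a1 <- l1$a1; a2 <- l1$a2
  aa <- matrix(allele_a, nrow = n_mk, ncol = ncol(line_calls))
  bb <- matrix(allele_b, nrow = n_mk, ncol = ncol(line_calls))
  coded <- matrix(NA_character_, nrow = n_mk, ncol = ncol(line_calls))
  ok <- matrix(codable, nrow = n_mk, ncol = ncol(line_calls))
  coded[ok & a1 == aa & a2 == aa] <- "A"
  coded[ok & a1 == bb & a2 == bb] <- "B"
  coded[ok & ((a1 == aa & a2 == bb) | (a1 == bb & a2 == aa))] <- "H"

  pc <- matrix(NA_character_, nrow = 2, ncol = n_mk,
               dimnames = list(c("P1", "P2"), markers$marker_id))
  code_parent <- function(s) {
    out <- rep(NA_character_, n_mk)
    hom <- !is.na(s$a1) & s$a1 == s$a2
    out[hom & s$a1 == allele_a] <- "A"
    out[hom & s$a1 == allele_b] <- "B"
    het <- !is.na(s$a1) & !is.na(s$a2) & s$a1 != s$a2
    out[het] <- "H"
    out
  }
  pc[1, ] <- code_parent(p1)
  pc[2, ] <- code_parent(p2)

  mk <- markers[keep, , drop = FALSE]
  mk$allele_a <- allele_a[keep]
  mk$allele_b <- allele_b[keep]
  lines <- colnames(line_calls)
  if (is.null(lines)) lines <- sprintf("L%04d", seq_len(ncol(line_calls)))
  calls <- t(coded[keep, , drop = FALSE])
  dimnames(calls) <- list(lines, mk$marker_id)

  structure(list(markers = mk, lines = lines, calls = calls,
                 parent_calls = pc[, keep, drop = FALSE]),
            class = "genotype_matrix", dropped = dropped)
}

#' Filter coded markers before linkage mapping
#'
#' Removes markers that (i) are not homozygous for different alleles in the
#' two parents, (ii) have a missing-data proportion above `max_missing`
#' among the RIL lines, or (iii) show significant segregation distortion in
#' a 1-d.f. chi-square test of the A:B homozygote counts against the 1:1
#' RIL expectation (heterozygous and missing calls are excluded from the
#' test; no Yates correction).
#'
#' @param gm A `genotype_matrix` with `parent_calls`.
#' @param max_missing Maximum tolerated missing fraction (default 0.70).
#' @param seg_alpha Significance level of the distortion test
#'   (default 0.01); markers with P below it are removed.
#' @return List with `matrix` (the filtered `genotype_matrix`) and
#'   `report`, a per-marker data.frame of the decision
#'   (`marker_id`, `removed`, `reason`, `missing_frac`, `chisq`, `p`).
#' @export
filter_markers <- function(gm, max_missing = 0.70, seg_alpha = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$parent_calls)) stop("parent calls required for filtering")
  calls <- gm$calls
  n_mk <- ncol(calls)

  p1 <- gm$parent_calls[1, ]
  p2 <- gm$parent_calls[2, ]
  parent_ok <- !is.na(p1) & !is.na(p2) & p1 != "H" & p2 != "H" & p1 != p2

  miss <- colMeans(is.na(calls))
  nA <- colSums(calls == "A", na.rm = TRUE)
  nB <- colSums(calls == "B", na.rm = TRUE)
  tot <- nA + nB
  chisq <- ifelse(tot > 0, (nA - nB)^2 / tot, NA_real_)
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  reason <- rep(NA_character_, n_mk)
  reason[!parent_ok] <- "parent not homozygous"
  reason[is.na(reason) & miss > max_missing] <- "missingness"
  reason[is.na(reason) & (is.na(pval) | pval < seg_alpha)] <- "distortion"
  removed <- !is.na(reason)

  report <- data.frame(marker_id = gm$markers$marker_id,
                       removed = removed, reason = reason,
                       missing_frac = miss, chisq = chisq, p = pval,
                       stringsAsFactors = FALSE)
  if (all(removed)) stop("all markers removed by filtering")

  keep <- !removed
  out <- gm
  out$markers <- gm$markers[keep, , drop = FALSE]
  out$calls <- gm$calls[, keep, drop = FALSE]
  out$parent_calls <- gm$parent_calls[, keep, drop = FALSE]
  rownames(out$markers) <- NULL
  list(matrix = out, report = report)
}

#' Thin markers per scaffold
#'
#' Optional reduction to at most `max_per_scaffold` markers per scaffold,
#' taken evenly from the head, middle and end (off by default in the
#' pipeline; the bin stage supersedes it).
#'
#' @param gm A `genotype_matrix`.
#' @param max_per_scaffold Maximum markers retained per scaffold.
#' @return The thinned `genotype_matrix`.
#' @export
thin_markers <- function(gm, max_per_scaffold = 30) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- unlist(lapply(split(seq_len(nrow(gm$markers)), gm$markers$scaffold),
                        function(idx) {
    if (length(idx) <= max_per_scaffold) return(idx)
    idx[unique(round(seq(1, length(idx), length.out = max_per_scaffold)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- gm
  out$markers <- gm$markers[keep, , drop = FALSE]
  out$calls <- gm$calls[, keep, drop = FALSE]
  if (!is.null(gm$parent_calls))
    out$parent_calls <- gm$parent_calls[, keep, drop = FALSE]
  rownames(out$markers) <- NULL
  out
}
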