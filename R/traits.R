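# Descriptive genetics of the phenotype tables: variability, broad-sense
# heritability, trait correlations and transgressive segregation.

#' Per-trait summary: range, mean, CV and broad-sense heritability
#'
#' CV is the coefficient of variation (sd/mean) of the RIL line means.
#' Broad-sense heritability on a line-mean basis is estimated from the
#' expected mean squares of the two-way line x environment ANOVA with
#' replicates: `H2 = s2_G / (s2_G + s2_GE/E + s2_e/(E R))` where
#' `s2_e = MS_error`, `s2_GE = (MS_GE - MS_error)/R` and
#' `s2_G = (MS_G - MS_GE)/(E R)`; negative component estimates are
#' clamped to zero (flagged in the `clamped` column).  With a single
#' environment H2 is reported `NA`.
#'
#' @param pheno Phenotype table (`line_id`, `env`, `rep`, `trait`,
#'   `value`, optional `is_parent`).
#' @return data.frame per trait: `trait`, `n_lines`, `min`, `max`,
#'   `mean`, `cv`, `h2`, `clamped`.
#' @export
trait_summary <- function(pheno) {
  if (!is.null(pheno$is_parent)) pheno <- pheno[!pheno$is_parent, ]
  out <- lapply(unique(pheno$trait), function(tr) {
    p <- pheno[pheno$trait == tr & is.finite(pheno$value), ]
    lm_ <- tapply(p$value, p$line_id, mean)
    cv <- stats::sd(lm_) / mean(lm_)
    E <- length(unique(p$env))
    R <- max(tapply(p$rep, interaction(p$line_id, p$env), length),
             na.rm = TRUE)
    h2 <- NA_real_; clamped <- FALSE
    if (E >= 2) {
      fit <- stats::aov(value ~ line_id + env + line_id:env, data = p)
      ms <- summary(fit)[[1]][, "Mean Sq"]
      terms <- rownames(summary(fit)[[1]])
      ms_g <- ms[grep("^line_id *$", terms)]
      ms_ge <- ms[grep("line_id:env", terms)]
      ms_e <- ms[grep("Residuals", terms)]
      if (length(ms_e) == 0 || is.na(ms_e)) ms_e <- 0
      s2_e <- ms_e
      s2_ge <- max((ms_ge - ms_e) / R, 0)
      s2_g <- max((ms_g - ms_ge) / (E * R), 0)
      clamped <- (ms_ge - ms_e) / R < 0 || (ms_g - ms_ge) / (E * R) < 0
      denom <- s2_g + s2_ge / E + s2_e / (E * R)
      h2 <- if (denom > 0) s2_g / denom else 0
    }
    data.frame(trait = tr, n_lines = length(lm_), min = min(lm_),
               max = max(lm_), mean = mean(lm_), cv = cv, h2 = h2,
               clamped = clamped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between trait/environment line means
#'
#' @param pheno Phenotype table.
#' @param by_env If TRUE (default) each trait x environment combination is
#'   a column; otherwise across-environment line means per trait.
#' @return Symmetric correlation matrix (pairwise-complete lines); entries
#'   with fewer than 3 paired lines are `NA`.
#' @export
trait_correlations <- function(pheno, by_env = TRUE) {
  if (!is.null(pheno$is_parent)) pheno <- pheno[!pheno$is_parent, ]
  key <- if (by_env) paste(pheno$trait, pheno$env, sep = ".") else
    pheno$trait
  lm_ <- tapply(pheno$value, list(pheno$line_id, key), mean)
  cm <- suppressWarnings(stats::cor(lm_, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(lm_))
  cm[npair < 3] <- NA_real_
  diag(cm) <- 1
  cm
}

#' Transgressive segregation counts
#'
#' Counts RIL lines whose mean lies strictly above the larger parent mean
#' or strictly below the smaller parent mean (lines equal to a parent
#' value are not counted).
#'
#' @param pheno Phenotype table with parents flagged by `is_parent` or
#'   identifiable by `parent_ids`.
#' @param parent_ids Length-2 character vector of parent line ids
#'   (defaults to the flagged parents).
#' @return data.frame per trait: `trait`, `parent_lo`, `parent_hi`,
#'   `n_above`, `n_below`; traits without both parent values are skipped
#'   with a message.
#' @export
transgressive_segregation <- function(pheno, parent_ids = NULL) {
  if (is.null(parent_ids)) {
    if (is.null(pheno$is_parent)) stop("no parent flags or ids supplied")
    parent_ids <- unique(pheno$line_id[pheno$is_parent])
  }
  stopifnot(length(parent_ids) == 2)
  out <- list()
  for (tr in unique(pheno$trait)) {
    p <- pheno[pheno$trait == tr, ]
    lm_ <- tapply(p$value, p$line_id, mean)
    pv <- lm_[parent_ids]
    if (anyNA(pv)) {
      message("trait ", tr, ": missing parent value, skipped")
      next
    }
    ril <- lm_[!(names(lm_) %in% parent_ids)]
    out[[tr]] <- data.frame(trait = tr, parent_lo = min(pv),
                            parent_hi = max(pv),
                            n_above = sum(ril > max(pv)),
                            n_below = sum(ril < min(pv)),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(trait = character(0),
                                      parent_lo = numeric(0),
                                      parent_hi = numeric(0),
                                      n_above = integer(0),
                                      n_below = integer(0))
  rownames(res) <- NULL
  res
}
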