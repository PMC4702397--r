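# Single-trait QTL scanning on bin markers: Haley-Knott regression at the
# bins (which are recombination-free within the population, so the
# likelihood is flat inside a bin), composite interval mapping with
# forward-selected cofactors, genome-wide permutation thresholds, and peak
# calling/naming.

#' Phenotype line means
#'
#' Averages plot values over replicates (and environments when
#' `env = NULL`), excluding parents.
#'
#' @param pheno Phenotype data.frame from [simulate_phenotypes()] or read
#'   from CSV (`line_id`, `env`, `rep`, `trait`, `value`, optional
#'   `is_parent`).
#' @param trait Trait name.
#' @param env Environment label, or `NULL` for the across-environment
#'   mean.
#' @return Named numeric vector of line means.
#' @export
line_means <- function(pheno, trait, env = NULL) {
  p <- pheno[pheno$trait == trait, ]
  if (!is.null(p$is_parent)) p <- p[!p$is_parent, ]
  if (!is.null(env)) p <- p[p$env == env, ]
  tapply(p$value, p$line_id, mean)
}

# vectorized Haley-Knott core: X lines x bins coded +1/-1/0 (0 = excluded),
# Y lines x k response columns (no NA).  Returns list of bins x k matrices.
.hk_core <- function(X, Y) {
  M <- (X != 0) * 1
  n <- colSums(M)
  Sx <- colSums(X)
  Sy <- crossprod(M, Y)                      # bins x k
  Syy <- crossprod(M, Y^2)
  Sxy <- crossprod(X, Y)
  det <- n^2 - Sx^2
  rss0 <- Syy - Sy^2 / n
  b1 <- (n * Sxy - Sx * Sy) / det
  b0 <- (Sy - b1 * Sx) / n
  rss1 <- Syy - b0 * Sy - b1 * Sxy
  bad <- det <= 0 | n < 2                    # monomorphic bins
  rss1 <- pmax(rss1, rss0 * 1e-12)           # guard perfect fits
  lod <- (n / 2) * log10(rss0 / rss1)
  r2 <- 1 - rss1 / rss0
  lod[bad, ] <- NA_real_
  b1[bad, ] <- NA_real_
  r2[bad, ] <- NA_real_
  list(lod = lod, additive = b1, r2 = r2, n = n, monomorphic = bad)
}

.scan_inputs <- function(binmap, map, y) {
  lines <- intersect(rownames(binmap$geno), names(y))
  if (length(lines) < 30)
    stop("at least 30 lines with genotype and phenotype required")
  tab <- map$table
  g <- binmap$geno[lines, tab$bin_id, drop = FALSE]
  X <- matrix(0, nrow(g), ncol(g), dimnames = dimnames(g))
  X[g == "A"] <- 1
  X[g == "B"] <- -1
  list(X = X, y = y[lines], tab = tab, lines = lines)
}

#' Haley-Knott LOD scan at bin markers
#'
#' At each bin, fits `y = mu + a x` with genotype score `x` (+1 for the
#' parent-A homozygote, -1 for parent-B; heterozygous and missing calls
#' are excluded at that position).  LOD is `(n/2) log10(RSS0/RSS1)`; the
#' additive effect is half the difference between the homozygote class
#' means (positive when the parent-A allele increases the trait); R2 is
#' `1 - RSS1/RSS0`.  Monomorphic bins are skipped and listed in the
#' `skipped` attribute.
#'
#' @param binmap A `bin_map`.
#' @param map A `genetic_map` over the same bins.
#' @param pheno Phenotype table (see [line_means()]).
#' @param trait Trait name.
#' @param env Environment label or `NULL`.
#' @return A `lod_profile` data.frame: `trait`, `env`, `group`, `pos_cm`,
#'   `bin_id`, `lod`, `additive`, `r2`, `n`.
#' @export
lod_scan <- function(binmap, map, pheno, trait, env = NULL) {
  y <- line_means(pheno, trait, env)
  si <- .scan_inputs(binmap, map, y)
  hk <- .hk_core(si$X, matrix(si$y, ncol = 1))
  out <- data.frame(trait = trait, env = if (is.null(env)) "all" else env,
                    group = si$tab$group, pos_cm = si$tab$pos_cm,
                    bin_id = si$tab$bin_id,
                    lod = hk$lod[, 1], additive = hk$additive[, 1],
                    r2 = hk$r2[, 1], n = hk$n,
                    stringsAsFactors = FALSE)
  keep <- !hk$monomorphic
  attr(out, "skipped") <- si$tab$bin_id[!keep]
  out <- out[keep, ]
  rownames(out) <- NULL
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Composite interval mapping scan
#'
#' Cofactor bins are chosen by forward selection on the line means (entry
#' P < `entry_p`, at most `n_cofactors`; candidates nearly collinear with
#' a selected cofactor are pruned).  At each test position, cofactors
#' within `window_cm` on the same group are dropped and the position is
#' tested by the F-change LOD of adding its genotype to the cofactor
#' model.  With `n_cofactors = 0` this reduces to [lod_scan()].
#'
#' @inheritParams lod_scan
#' @param n_cofactors Maximum number of cofactors (default 5).
#' @param window_cm Exclusion window around the test position (default
#'   10 cM).
#' @param entry_p Forward-selection entry P-value (default 0.01).
#' @return A `lod_profile` data.frame with attribute `cofactors`.
#' @export
cim_scan <- function(binmap, map, pheno, trait, env = NULL,
                     n_cofactors = 5, window_cm = 10, entry_p = 0.01) {
  y <- line_means(pheno, trait, env)
  si <- .scan_inputs(binmap, map, y)
  X <- si$X; yv <- si$y; tab <- si$tab
  X[X == 0] <- NA

  # forward selection on complete-case correlation screening
  cof <- integer(0)
  if (n_cofactors > 0) {
    repeat {
      best_p <- Inf; best_j <- NA_integer_; best_rss <- NA
      base <- cbind(1, X[, cof, drop = FALSE])
      for (j in seq_len(ncol(X))) {
        if (j %in% cof) next
        if (length(cof) &&
            any(abs(suppressWarnings(stats::cor(X[, j], X[, cof],
                use = "pairwise.complete.obs"))) > 0.95, na.rm = TRUE))
          next                               # collinear candidate pruned
        d <- cbind(base, X[, j])
        cc <- stats::complete.cases(d)
        if (sum(cc) < 30) next
        f0 <- stats::lm.fit(d[cc, -ncol(d), drop = FALSE], yv[cc])
        f1 <- stats::lm.fit(d[cc, , drop = FALSE], yv[cc])
        rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
        df2 <- sum(cc) - ncol(d)
        fstat <- (rss0 - rss1) / (rss1 / df2)
        pv <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
        if (!is.na(pv) && pv < best_p) { best_p <- pv; best_j <- j }
      }
      if (is.na(best_j) || best_p >= entry_p || length(cof) >= n_cofactors)
        break
      cof <- c(cof, best_j)
    }
  }

  lod <- additive <- r2 <- nn <- rep(NA_real_, ncol(X))
  for (j in seq_len(ncol(X))) {
    keepc <- cof[!(tab$group[cof] == tab$group[j] &
                     abs(tab$pos_cm[cof] - tab$pos_cm[j]) < window_cm)]
    d <- cbind(1, X[, keepc, drop = FALSE], X[, j])
    cc <- stats::complete.cases(d)
    if (sum(cc) < 30) next
    xj <- X[cc, j]
    if (length(unique(xj)) < 2) next
    f0 <- stats::lm.fit(d[cc, -ncol(d), drop = FALSE], yv[cc])
    f1 <- stats::lm.fit(d[cc, , drop = FALSE], yv[cc])
    rss0 <- sum(f0$residuals^2); rss1 <- max(sum(f1$residuals^2),
                                             sum(f0$residuals^2) * 1e-12)
    n <- sum(cc)
    lod[j] <- (n / 2) * log10(rss0 / rss1)
    additive[j] <- f1$coefficients[ncol(d)]
    r2[j] <- 1 - rss1 / rss0
    nn[j] <- n
  }
  out <- data.frame(trait = trait, env = if (is.null(env)) "all" else env,
                    group = tab$group, pos_cm = tab$pos_cm,
                    bin_id = tab$bin_id, lod = lod, additive = additive,
                    r2 = r2, n = nn, stringsAsFactors = FALSE)
  attr(out, "cofactors") <- tab$bin_id[cof]
  out <- out[!is.na(out$lod), ]
  rownames(out) <- NULL
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype line means `n_perm` times against the fixed
#' genotypes, scans each permutation, and returns the
#' `ceil((1-alpha) n_perm)`-th order statistic of the genome-wide maximum
#' LOD.
#'
#' @inheritParams lod_scan
#' @param n_perm Number of permutations (default 1000; below 100 the
#'   quantile is unstable and a warning is issued).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed.
#' @return Threshold LOD (numeric) with attribute `max_lods`.
#' @export
permutation_threshold <- function(binmap, map, pheno, trait, env = NULL,
                                  n_perm = 1000, alpha = 0.05, seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations: unstable quantile")
  y <- line_means(pheno, trait, env)
  si <- .scan_inputs(binmap, map, y)
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(si$y), numeric(length(si$y)))
  hk <- .hk_core(si$X, Y)
  max_lods <- apply(hk$lod, 2, max, na.rm = TRUE)
  k <- min(n_perm, ceiling((1 - alpha) * n_perm))
  thr <- sort(max_lods)[max(k, 1)]
  attr(thr, "max_lods") <- max_lods
  thr
}

.group_number <- function(group) {
  n <- suppressWarnings(as.integer(sub("[^0-9]*", "", group)))
  ifelse(is.na(n), seq_along(group), n)
}

#' Call QTL peaks from one or more LOD profiles
#'
#' Peaks are local maxima of contiguous runs with
#' `lod >= max(threshold, lod_min)`.  The support interval extends from
#' the peak while `lod >= peak - lod_drop`; flanking bins are the bins
#' bracketing the peak bin; the physical span is the distance between the
#' outer boundaries of the flanking bins.  Peaks co-detected in several
#' environments are merged by overlapping support intervals and reported
#' with per-environment flags.  Names follow `q<Trait>-<group>.<index>`
#' with the index increasing along the group.
#'
#' @param profiles A `lod_profile` or list of them (one per environment).
#' @param threshold Permutation threshold LOD (may be a single value or
#'   one per profile).
#' @param lod_min Fixed LOD floor (default 2.5).
#' @param lod_drop Support-interval LOD drop (default 1.5).
#' @param binmap Optional `bin_map` supplying bin physical coordinates for
#'   the span in kb.
#' @return data.frame of QTL peaks (possibly empty): `name`, `trait`,
#'   `group`, `pos_cm`, `bin_id`, `lod`, `additive`, `r2`,
#'   `flank_left`, `flank_right`, `span_kb`, `ci_lo`, `ci_hi`, `envs`,
#'   `n_envs`.
#' @export
call_qtls <- function(profiles, threshold, lod_min = 2.5, lod_drop = 1.5,
                      binmap = NULL) {
  if (inherits(profiles, "lod_profile")) profiles <- list(profiles)
  threshold <- rep_len(threshold, length(profiles))

  peaks <- list()
  for (e in seq_along(profiles)) {
    pr <- profiles[[e]]
    thr <- max(threshold[e], lod_min)
    for (g in unique(pr$group)) {
      pg <- pr[pr$group == g, ]
      pg <- pg[order(pg$pos_cm), ]
      above <- !is.na(pg$lod) & pg$lod >= thr
      if (!any(above)) next
      # one peak per contiguous above-threshold run; linked QTLs whose
      # valley stays above the threshold merge here (separating them is
      # what the cofactor scan is for)
      runs <- rle(above)
      idx_end <- cumsum(runs$lengths)
      idx_start <- c(1, utils::head(idx_end, -1) + 1)
      pks <- vapply(which(runs$values), function(k) {
        seg <- idx_start[k]:idx_end[k]
        seg[which.max(pg$lod[seg])]
      }, integer(1))
      for (pk in pks) {
        lo <- pk; hi <- pk
        while (lo > 1 && !is.na(pg$lod[lo - 1]) &&
               pg$lod[lo - 1] >= pg$lod[pk] - lod_drop) lo <- lo - 1
        while (hi < nrow(pg) && !is.na(pg$lod[hi + 1]) &&
               pg$lod[hi + 1] >= pg$lod[pk] - lod_drop) hi <- hi + 1
        fl <- if (pk > 1) pg$bin_id[pk - 1] else pg$bin_id[pk]
        fr <- if (pk < nrow(pg)) pg$bin_id[pk + 1] else pg$bin_id[pk]
        span_kb <- NA_real_
        if (!is.null(binmap)) {
          bl <- binmap$bins[match(fl, binmap$bins$bin_id), ]
          br <- binmap$bins[match(fr, binmap$bins$bin_id), ]
          if (identical(bl$seq_id, br$seq_id))
            span_kb <- (max(bl$end, br$end) - min(bl$start, br$start) + 1) / 1000
        }
        peaks[[length(peaks) + 1]] <- data.frame(
          trait = pg$trait[1], env = pg$env[1], group = g,
          pos_cm = pg$pos_cm[pk], bin_id = pg$bin_id[pk],
          lod = pg$lod[pk], additive = pg$additive[pk], r2 = pg$r2[pk],
          flank_left = fl, flank_right = fr, span_kb = span_kb,
          ci_lo = pg$pos_cm[lo], ci_hi = pg$pos_cm[hi],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(peaks))
    return(data.frame(name = character(0), trait = character(0),
                      group = character(0), pos_cm = numeric(0),
                      bin_id = character(0), lod = numeric(0),
                      additive = numeric(0), r2 = numeric(0),
                      flank_left = character(0), flank_right = character(0),
                      span_kb = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), envs = character(0),
                      n_envs = integer(0), stringsAsFactors = FALSE))
  pk <- do.call(rbind, peaks)

  # merge across environments by overlapping support intervals per group
  pk <- pk[order(pk$group, pk$pos_cm), ]
  merged <- list()
  for (g in unique(pk$group)) {
    pg <- pk[pk$group == g, ]
    cl <- integer(nrow(pg)); cl[1] <- 1
    if (nrow(pg) > 1) for (i in 2:nrow(pg)) {
      prev <- which(cl == cl[i - 1])
      cl[i] <- if (pg$ci_lo[i] <= max(pg$ci_hi[prev])) cl[i - 1] else
        cl[i - 1] + 1
    }
    for (c in unique(cl)) {
      rows <- pg[cl == c, ]
      best <- rows[which.max(rows$lod), ]
      best$envs <- paste(sort(unique(rows$env)), collapse = ",")
      best$n_envs <- length(unique(rows$env))
      merged[[length(merged) + 1]] <- best
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(.group_number(out$group), out$pos_cm), ]
  out$name <- sprintf("q%s-%d.%d", out$trait, .group_number(out$group),
                      stats::ave(seq_len(nrow(out)), out$group,
                                 FUN = seq_along))
  out$env <- NULL
  rownames(out) <- NULL
  out[, c("name", setdiff(names(out), "name"))]
}
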