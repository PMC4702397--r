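# Two-point linkage estimation between bins, grouping at a LOD threshold,
# ordering by seriation, and Kosambi map distances.

.bin_scores <- function(binmap) {
  g <- binmap$geno
  x <- matrix(0, nrow = nrow(g), ncol = ncol(g), dimnames = dimnames(g))
  x[g == "A"] <- 1
  x[g == "B"] <- -1                           # H and missing both drop out
  x
}

#' Two-point recombination estimates between all bin pairs
#'
#' For every pair of bins, lines that are homozygous (A or B) at both are
#' informative; heterozygous and missing calls are excluded pairwise.  The
#' observed RIL recombinant fraction is `R = recombinants / informative`;
#' the two-point LOD against independence is
#' `n_p log10(2(1-R)) + n_r log10(2R)` (terms with zero counts contribute
#' zero, and R is capped at 0.5 in the likelihood); the meiotic fraction is
#' recovered with the Haldane-Waddington inversion `r = R/(2(1-R))`.
#'
#' @param binmap A `bin_map`.
#' @return A `two_point` object: list of bins x bins matrices `R`, `lod`,
#'   `n_inf`, `r`, plus the `bins` table.  Pairs with no informative lines
#'   have `NA` estimates.
#' @export
pairwise_rf <- function(binmap) {
  stopifnot(inherits(binmap, "bin_map"))
  if (ncol(binmap$geno) < 2) stop("at least 2 bins required")
  x <- .bin_scores(binmap)
  m <- (x != 0) * 1
  n_inf <- crossprod(m)
  n_rec <- (n_inf - crossprod(x)) / 2
  R <- n_rec / n_inf                         # NaN where n_inf == 0
  R[n_inf == 0] <- NA_real_
  # lod = n_p log10(2(1-R)) + n_r log10(2R), zero-count terms contribute 0
  Rcap <- pmin(R, 0.5)
  lod <- (n_inf - n_rec) * log10(2 * (1 - Rcap))
  lod[is.na(lod)] <- 0
  t2 <- n_rec * log10(2 * Rcap)
  t2[n_rec == 0] <- 0
  lod <- pmax(lod + t2, 0)
  lod[n_inf == 0] <- NA_real_
  rm(t2, Rcap, x, m)
  r <- ril_rf_shrink(R)
  diag(lod) <- 0
  structure(list(R = R, lod = lod, n_inf = n_inf, r = r,
                 bins = binmap$bins),
            class = "two_point")
}

#' Group bins into linkage groups
#'
#' Single-linkage transitive closure over bin pairs with `lod >= lod_min`
#' and an observed recombinant fraction significantly below independence.
#' With thousands of bin markers there are millions of between-group
#' pairs, so a raw `R < 0.5` edge rule admits expected-by-chance
#' borderline links that can glue two chromosomes; an edge therefore also
#' requires `R` below a Bonferroni-scaled cap,
#' `0.5 - z sqrt(0.25/n)` with `z = qnorm(1 - alpha / n_pairs)`.
#' Genuine chains are unaffected (adjacent bins recombine in a handful of
#' lines at most).  Groups are numbered by descending bin count, ties
#' broken by the smallest member bin; singletons are reported as
#' unplaced.
#'
#' @param tp A `two_point` object.
#' @param lod_min Grouping LOD threshold (default 4.0).
#' @param alpha Family-wise rate of chance linkage edges (default 0.05).
#' @return List with `groups` (named list of bin-id vectors, names
#'   `LG01`, ...) and `unplaced` (bin ids).
#' @export
group_bins <- function(tp, lod_min = 4.0, alpha = 0.05) {
  stopifnot(inherits(tp, "two_point"))
  n <- nrow(tp$lod)
  z <- stats::qnorm(1 - alpha / max(n * (n - 1) / 2, 1))
  r_cap <- pmin(0.5 - z * sqrt(0.25 / pmax(tp$n_inf, 1)), 0.5 - 1e-9)
  adj <- !is.na(tp$lod) & tp$lod >= lod_min & !is.na(tp$R) & tp$R < r_cap
  diag(adj) <- FALSE
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    js <- which(adj[i, (i + 1):n]) + i
    for (j in js) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- colnames(tp$lod)
  if (is.null(ids)) ids <- tp$bins$bin_id
  members <- split(seq_len(n), comp)
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, min, integer(1)))
  members <- members[ord]
  grouped <- members[lengths(members) >= 2]
  unplaced <- unlist(members[lengths(members) < 2], use.names = FALSE)
  groups <- lapply(grouped, function(ix) ids[ix])
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  list(groups = groups, unplaced = ids[unplaced])
}

.path_cost <- function(ordr, r) sum(r[cbind(ordr[-length(ordr)], ordr[-1])])

#' Order the bins of one linkage group
#'
#' Deterministic seriation minimizing the sum of adjacent meiotic
#' recombination fractions.  The initial order is the first principal
#' coordinate of the recombination-fraction matrix (classical scaling via
#' a deterministic power iteration); it is refined by 2-opt segment
#' reversals (first improvement, repeated until no reversal lowers the
#' objective).  For groups larger than `full_2opt_max` bins the reversal
#' search is restricted to segments spanning at most 40 positions, which
#' is where residual inversions of a near-Robinson ordering live.  The
#' overall orientation is arbitrary and is canonicalized so that the bin
#' with the smallest id lies in the first half.
#'
#' @param bin_ids Bin ids forming one group.
#' @param tp A `two_point` object.
#' @param full_2opt_max Group size up to which all reversals are searched
#'   (default 600).
#' @return Character vector of ordered bin ids.
#' @export
order_group <- function(bin_ids, tp, full_2opt_max = 600) {
  stopifnot(inherits(tp, "two_point"))
  k <- length(bin_ids)
  if (k <= 2) return(sort(bin_ids))
  r <- tp$r[bin_ids, bin_ids]
  r[is.na(r)] <- 0.5
  diag(r) <- 0

  # first principal coordinate: B = -J r^2 J / 2, deterministic power
  # iteration from a fixed start
  d2 <- r^2
  rm_ <- rowMeans(d2); gm_ <- mean(d2)
  center <- function(v) v - mean(v)
  bmul <- function(v) {
    w <- as.vector(d2 %*% v)
    -0.5 * center(w - rm_ * sum(v))
  }
  v <- center(seq_len(k))
  v <- v / sqrt(sum(v^2))
  for (it in 1:60) {
    w <- bmul(v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    if (sum(abs(w - v)) < 1e-10) { v <- w; break }
    v <- w
  }
  path <- order(v)
  diag(r) <- 0

  # refinement: 2-opt segment reversals plus Or-opt relocation of short
  # segments (a reversal cannot move a displaced bin across the path; a
  # relocation can), iterated until neither improves
  span <- if (k <= full_2opt_max) k else 40L
  d_at <- function(i, j) if (i < 1 || j > k) 0 else r[path[i], path[j]]
  passes <- 0
  repeat {
    improved <- FALSE
    passes <- passes + 1
    for (i in 1:(k - 1)) {
      jmax <- min(k, i + span)
      for (j in (i + 1):jmax) {
        if (i == 1 && j == k) next
        left <- if (i > 1) r[path[i - 1], path[j]] - r[path[i - 1], path[i]] else 0
        right <- if (j < k) r[path[i], path[j + 1]] - r[path[j], path[j + 1]] else 0
        if (left + right < -1e-12) {
          path[i:j] <- rev(path[i:j])
          improved <- TRUE
        }
      }
    }
    # Or-opt: move the segment [i, i+len-1] to sit after position p
    for (len in 1:3) {
      i <- 1
      while (i <= k - len + 1) {
        j <- i + len - 1
        gain_out <- d_at(i - 1, i) + d_at(j, j + 1) - d_at(i - 1, j + 1)
        if (gain_out > 1e-12) {
          seg <- path[i:j]
          rest <- path[-(i:j)]
          m <- length(rest)
          ins_cost <- vapply(0:m, function(p) {
            a <- if (p >= 1) r[rest[p], seg[1]] else 0
            b <- if (p < m) r[seg[len], rest[p + 1]] else 0
            base <- if (p >= 1 && p < m) r[rest[p], rest[p + 1]] else 0
            a + b - base
          }, numeric(1))
          best <- which.min(ins_cost) - 1L
          if (ins_cost[best + 1L] < gain_out - 1e-12) {
            path <- append(rest, seg, after = best)
            improved <- TRUE
            i <- max(i - 1, 1)
            next
          }
        }
        i <- i + 1
      }
    }
    if (!improved || passes >= 30) break
  }

  ids <- bin_ids[path]
  anchor <- which(ids == min(bin_ids))
  if (anchor > (k + 1) / 2) ids <- rev(ids)
  ids
}

#' Kosambi map positions along an ordered group
#'
#' Adjacent meiotic fractions are converted to cM with the Kosambi mapping
#' function and accumulated from 0.
#'
#' @param ordered_ids Ordered bin ids of one group.
#' @param tp A `two_point` object.
#' @return data.frame `bin_id`, `pos_cm`.
#' @export
genetic_distances <- function(ordered_ids, tp) {
  stopifnot(inherits(tp, "two_point"))
  k <- length(ordered_ids)
  if (k == 1) return(data.frame(bin_id = ordered_ids, pos_cm = 0,
                                stringsAsFactors = FALSE))
  radj <- tp$r[cbind(ordered_ids[-k], ordered_ids[-1])]
  if (anyNA(radj) || any(radj >= 0.5))
    stop("adjacent recombination fraction >= 0.5; ordering is inconsistent")
  data.frame(bin_id = ordered_ids,
             pos_cm = cumsum(c(0, kosambi_d(radj))),
             stringsAsFactors = FALSE)
}

#' Build a genetic map from a bin map
#'
#' Convenience wrapper: two-point estimation, grouping at `lod_min`,
#' per-group ordering and Kosambi distances.
#'
#' @param binmap A `bin_map`.
#' @param lod_min Grouping LOD threshold (default 4.0).
#' @param allow_weak_adjacencies If TRUE, adjacent fractions at or above
#'   0.5 are capped just below 0.5 instead of raising an error.  Used
#'   internally while conflicting (chimeric) scaffolds are still being
#'   resolved; a final map should be built with the default FALSE so that
#'   inconsistent orders surface.
#' @param bin_max_missing Bins whose heterozygous-plus-missing fraction
#'   exceeds this are left unplaced (default 0.70) -- the missing-data
#'   filter applied to the bin markers, mirroring the marker-level filter
#'   (H is treated as missing by the two-point estimates, so such bins
#'   carry almost no mapping information and only destabilize ordering).
#' @return A `genetic_map`: list with `table` (data.frame `group`,
#'   `bin_id`, `pos_cm`, `seq_id`, `start`, `end`), `unplaced` bin ids and
#'   `tp`, the `two_point` object.
#' @export
build_genetic_map <- function(binmap, lod_min = 4.0,
                              allow_weak_adjacencies = FALSE,
                              bin_max_missing = 0.70) {
  uninf <- colMeans(is.na(binmap$geno) | binmap$geno == "H")
  dropped <- colnames(binmap$geno)[uninf > bin_max_missing]
  if (length(dropped)) {
    keep <- uninf <= bin_max_missing
    binmap$geno <- binmap$geno[, keep, drop = FALSE]
    binmap$bins <- binmap$bins[keep, , drop = FALSE]
  }
  tp <- pairwise_rf(binmap)
  if (allow_weak_adjacencies) {
    tp$r <- pmin(tp$r, 0.5 - 1e-6)
    tp$r[is.na(tp$r)] <- 0.5 - 1e-6
  }
  grp <- group_bins(tp, lod_min = lod_min)
  tabs <- lapply(names(grp$groups), function(gn) {
    ordr <- order_group(grp$groups[[gn]], tp)
    gd <- genetic_distances(ordr, tp)
    gd$group <- gn
    gd
  })
  tab <- do.call(rbind, tabs)
  bi <- match(tab$bin_id, binmap$bins$bin_id)
  tab$seq_id <- binmap$bins$seq_id[bi]
  tab$start <- binmap$bins$start[bi]
  tab$end <- binmap$bins$end[bi]
  tab <- tab[, c("group", "bin_id", "pos_cm", "seq_id", "start", "end")]
  structure(list(table = tab, unplaced = c(grp$unplaced, dropped),
                 tp = tp),
            class = "genetic_map")
}

#' Interval arithmetic of a genetic map
#'
#' The summary arithmetic used by [map_summary()], exposed for desk checks
#' against published totals: with `n_bins` bins in `n_groups` groups there
#' are `n_bins - n_groups` adjacent intervals, so the mean adjacent
#' interval is `total_cm / (n_bins - n_groups)` and the mean group length
#' is `total_cm / n_groups`.
#'
#' @param n_bins,n_groups,total_cm Map totals.
#' @return List `mean_interval_cm`, `mean_group_length_cm`, `n_intervals`.
#' @export
map_interval_stats <- function(n_bins, n_groups, total_cm) {
  stopifnot(n_bins >= n_groups, n_groups >= 1)
  n_int <- n_bins - n_groups
  list(mean_interval_cm = if (n_int > 0) total_cm / n_int else NA_real_,
       mean_group_length_cm = total_cm / n_groups,
       n_intervals = n_int)
}

#' Summarize a genetic map
#'
#' @param map A `genetic_map`.
#' @param anchored_length_bp Optional physical length anchored to the map,
#'   for the genome-wide recombination rate in cM/Mb.
#' @return List with totals, per-group table, mean adjacent interval,
#'   fraction of adjacent intervals shorter than 6 cM, and `cm_per_mb`.
#' @export
map_summary <- function(map, anchored_length_bp = NA_real_) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  per_group <- do.call(rbind, lapply(split(tab, tab$group), function(g)
    data.frame(group = g$group[1], n_bins = nrow(g),
               length_cm = max(g$pos_cm), stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  total_cm <- sum(per_group$length_cm)
  n_bins <- nrow(tab)
  n_groups <- nrow(per_group)
  ints <- unlist(lapply(split(tab$pos_cm, tab$group), diff), use.names = FALSE)
  st <- map_interval_stats(n_bins, n_groups, total_cm)
  list(n_groups = n_groups, n_bins = n_bins, total_cm = total_cm,
       per_group = per_group,
       mean_interval_cm = st$mean_interval_cm,
       mean_group_length_cm = st$mean_group_length_cm,
       frac_intervals_lt_6cm = if (length(ints)) mean(ints < 6) else NA_real_,
       cm_per_mb = if (is.na(anchored_length_bp)) NA_real_ else
         total_cm / (anchored_length_bp / 1e6))
}
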