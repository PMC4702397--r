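# Sliding-window genotype smoothing, recombination-breakpoint detection and
# construction of the population bin map.

#' Sliding-window genotype calls for one line on one sequence
#'
#' Scans the ordered genotype calls of a single line with a window of
#' `window` informative (non-missing) calls and step 1.  A window is called
#' `A` if it contains at least `threshold` A calls, `B` if at least
#' `threshold` B calls, and `H` otherwise.  Missing calls are skipped, so
#' every window holds exactly `window` informative calls; heterozygous
#' calls are informative and count towards neither homozygote.  Each window
#' call is assigned to the window's center marker.
#'
#' @param calls Character vector over `A`/`B`/`H`/`NA`, in physical order.
#' @param pos Numeric marker positions (bp), same length as `calls`.
#' @param window Window size in informative calls (default 15).
#' @param threshold Homozygote call threshold (default 13).
#' @return data.frame with one row per window: `center_idx` (index into
#'   `calls`), `center_pos` and `genotype`.  If fewer than `window`
#'   informative calls are available the sequence is un-callable: an empty
#'   data.frame with attribute `uncallable = TRUE` is returned.
#' @export
smooth_line <- function(calls, pos, window = 15, threshold = 13) {
  stopifnot(length(calls) == length(pos), window >= 1,
            threshold >= window / 2, threshold <= window)
  w <- .win_calls(calls, pos, window, threshold)
  if (is.null(w)) {
    empty <- data.frame(center_idx = integer(0), center_pos = numeric(0),
                        genotype = character(0), stringsAsFactors = FALSE)
    attr(empty, "uncallable") <- TRUE
    return(empty)
  }
  data.frame(center_idx = w$center_idx, center_pos = w$center_pos,
             genotype = w$geno, stringsAsFactors = FALSE)
}

# window-call core: returns NULL when un-callable
.win_calls <- function(calls, pos, window, threshold) {
  ii <- which(!is.na(calls))
  m <- length(ii)
  if (m < window) return(NULL)
  x <- calls[ii]
  csA <- cumsum(x == "A"); csB <- cumsum(x == "B")
  n_win <- m - window + 1
  i <- seq_len(n_win)
  cA <- csA[i + window - 1] - c(0, csA)[i]
  cB <- csB[i + window - 1] - c(0, csB)[i]
  geno <- ifelse(cA >= threshold, "A", ifelse(cB >= threshold, "B", "H"))
  center <- ii[i + (window - 1L) %/% 2L]
  list(center_idx = center, center_pos = pos[center], geno = geno,
       inf_idx = ii, inf_calls = x)
}

# run-level engine shared by detect_breakpoints() and call_blocks():
# wedge collapse, same-flank H dissolution, terminal refinement, and
# breakpoint placement.  Returns list(geno, bp, lg, rg).
.blocks_core <- function(w, calls, pos, extent, window, threshold) {
  r <- rle(w$geno)
  geno <- r$values
  run_end <- cumsum(r$lengths)
  run_start <- c(1, utils::head(run_end, -1) + 1)
  # A clean crossover produces 2*threshold-window-1 H windows; up to
  # window-threshold invisible stray het calls in the transition can add
  # one window each, giving the bound threshold-1.  A genuine het segment
  # visible to the rule (>= window-threshold+1 H calls) always produces
  # at least threshold H windows, strictly above the bound.
  wedge_max <- threshold - 1

  # interior H runs: a run short enough to be a single-crossover wedge is
  # collapsed to a breakpoint when its flanks are opposite homozygotes, or
  # dissolved into its flanks when they carry the same genotype (a 2-error
  # artifact; any het segment visible to the window rule spans more
  # windows than the wedge bound)
  i <- 2
  while (i <= length(geno) - 1) {
    len_i <- run_end[i] - run_start[i] + 1
    if (geno[i] == "H" && len_i <= wedge_max &&
        geno[i - 1] != "H" && geno[i + 1] != "H") {
      if (geno[i - 1] == geno[i + 1]) {       # dissolve, merge flanks
        run_end[i - 1] <- run_end[i + 1]
        geno <- geno[-c(i, i + 1)]
        run_start <- run_start[-c(i, i + 1)]
        run_end <- run_end[-(i:(i + 1))]
        i <- max(i - 1, 2)
      } else {                                # crossover wedge
        geno <- geno[-i]
        run_start <- run_start[-i]
        run_end <- run_end[-i]
      }
    } else i <- i + 1
  }

  bp_at <- rep(NA_real_, length(geno))        # breakpoint before run j

  if (!is.null(calls)) {
    vi <- w$inf_idx
    v <- w$inf_calls
    # restrict the scan to the terminal H run's own window span
    lim_head <- if (length(geno) > 1)
      min(length(v), run_end[1] + window - 1) else length(v)
    ref <- .refine_terminal(v[seq_len(lim_head)], geno)
    if (!is.null(ref$lead)) {
      t <- ref$lead$t
      bpp <- (pos[vi[t]] + pos[vi[t + 1]]) / 2
      if (ref$lead$mode == "drop") {
        geno <- geno[-1]; run_start <- run_start[-1]; run_end <- run_end[-1]
        bp_at <- bp_at[-1]
      } else if (ref$lead$mode == "insert") {
        geno <- c(ref$lead$x, geno)
        run_start <- c(run_start[1], run_start)
        run_end <- c(run_start[1], run_end)
        bp_at <- c(NA_real_, bpp, bp_at[-1])
      } else {                               # replace
        geno[1] <- ref$lead$x
        if (length(geno) > 1) bp_at[2] <- bpp
      }
    }
    nr <- length(geno)
    lim_tail <- if (nr > 1) min(length(v), length(v) - run_start[nr] + 1) else
      length(v)
    refT <- .refine_terminal(rev(v)[seq_len(lim_tail)], rev(geno))
    if (!is.null(refT$lead)) {
      t <- length(v) - refT$lead$t + 1        # first marker of tail block
      bpp <- (pos[vi[t - 1]] + pos[vi[t]]) / 2
      n <- length(geno)
      if (refT$lead$mode == "drop") {
        geno <- geno[-n]; run_start <- run_start[-n]; run_end <- run_end[-n]
        bp_at <- bp_at[-n]
      } else if (refT$lead$mode == "insert") {
        geno <- c(geno, refT$lead$x)
        run_start <- c(run_start, run_end[n])
        run_end <- c(run_end, run_end[n])
        bp_at <- c(bp_at, bpp)
      } else {
        geno[n] <- refT$lead$x
        if (n > 1) bp_at[n] <- bpp
      }
    }
    if (length(geno) == 1 && geno[1] == "H") {
      two <- .refine_whole_h(v)
      if (!is.null(two)) {
        bpp <- (pos[vi[two$t]] + pos[vi[two$t + 1]]) / 2
        geno <- c(two$x, two$y)
        run_start <- c(run_start[1], run_start[1])
        run_end <- c(run_end[1], run_end[1])
        bp_at <- c(NA_real_, bpp)
      }
    }
  }

  nb <- length(geno)
  bps <- numeric(0); lg <- character(0); rg <- character(0)
  if (nb > 1) {
    bps <- bp_at[-1]
    vi <- w$inf_idx; v <- w$inf_calls
    for (j in which(is.na(bps))) {
      # the breakpoint sits at the midpoint between the last SNP
      # supporting the left block and the first SNP supporting the right
      # block, searched within the transition zone spanned by the two
      # flanking windows (marker-level, so coincident crossovers of
      # different lines yield identical positions)
      bpp <- NA_real_
      if (!is.null(v)) {
        zone_lo <- run_end[j]
        zone_hi <- min(run_start[j + 1] + window - 1, length(v))
        t <- .bp_gap(v, zone_lo:zone_hi, geno[j], geno[j + 1])
        if (!is.na(t)) bpp <- (pos[vi[t]] + pos[vi[t + 1]]) / 2
      }
      if (is.na(bpp))
        bpp <- (w$center_pos[run_end[j]] + w$center_pos[run_start[j + 1]]) / 2
      bps[j] <- bpp
    }
    bps <- cummax(bps)                        # guard pathological inversions
    lg <- geno[-nb]; rg <- geno[-1]
  }
  list(geno = geno, bps = bps, lg = lg, rg = rg)
}

#' Combine window calls into blocks and locate breakpoints
#'
#' Maximal runs of identical window genotype become blocks; the breakpoint
#' between two consecutive blocks is placed at the midpoint between the
#' center of the last window supporting the left block and the center of
#' the first window supporting the right block.
#'
#' A clean homozygous crossover necessarily produces a short run of H
#' windows under the window rule (windows straddling the exchange contain
#' 3-12 calls of each parent), at most `threshold - 1` windows even when
#' stray invisible het calls sit in the transition, whereas any
#' heterozygous segment visible to the rule (at least
#' `window - threshold + 1` informative markers) produces at least
#' `threshold`; H runs at or below the bound are therefore collapsed into
#' a single A/B breakpoint when flanked by opposite homozygotes, and
#' dissolved into their flanks when both flanks carry the same genotype
#' (isolated genotyping-error artifacts).
#'
#' @param sm Window calls from [smooth_line()].
#' @param line_id,seq_id Identifiers stored in the output.
#' @param extent Length-2 numeric, first and last marker position of the
#'   sequence; defaults to the span of the window centers.
#' @param window,threshold The smoothing parameters (used for the wedge
#'   bound).
#' @param calls,pos The raw calls and positions given to [smooth_line()];
#'   when supplied, terminal H runs are refined at marker level (see
#'   Details).
#' @details A genotype change within `window` informative markers of a
#'   sequence end cannot be called by the window rule (no window on the
#'   far side can reach `threshold` calls), which would silently discard
#'   terminal recombination -- and, on chimeric scaffolds, whole misjoined
#'   tails.  When the raw calls are supplied, a terminal H run whose
#'   underlying calls show a clean leading (or trailing) run of at least 3
#'   homozygous calls of the opposite parent is re-called as a terminal
#'   homozygous block, with the breakpoint at the midpoint of the flanking
#'   informative markers.  Tails containing three or more interior
#'   heterozygous calls are left as H (a visible het segment, not an end
#'   artifact).
#' @return data.frame of blocks (`line_id`, `seq_id`, `start`, `end`,
#'   `genotype`) with attribute `breakpoints`: data.frame (`line_id`,
#'   `seq_id`, `pos`, `left_geno`, `right_geno`).
#' @export
detect_breakpoints <- function(sm, line_id = "line", seq_id = "seq",
                               extent = NULL, window = 15, threshold = 13,
                               calls = NULL, pos = NULL) {
  bp_empty <- data.frame(line_id = character(0), seq_id = character(0),
                         pos = numeric(0), left_geno = character(0),
                         right_geno = character(0), stringsAsFactors = FALSE)
  if (nrow(sm) == 0) {
    out <- data.frame(line_id = character(0), seq_id = character(0),
                      start = numeric(0), end = numeric(0),
                      genotype = character(0), stringsAsFactors = FALSE)
    attr(out, "breakpoints") <- bp_empty
    return(out)
  }
  if (is.null(extent)) extent <- range(sm$center_pos)
  w <- list(center_idx = sm$center_idx, center_pos = sm$center_pos,
            geno = sm$genotype)
  if (!is.null(calls)) {
    ii <- which(!is.na(calls))
    w$inf_idx <- ii
    w$inf_calls <- calls[ii]
  }
  core <- .blocks_core(w, calls, pos, extent, window, threshold)
  bps <- core$bps
  out <- data.frame(line_id = line_id, seq_id = seq_id,
                    start = c(extent[1], floor(bps) + 1),
                    end = c(floor(bps), extent[2]),
                    genotype = core$geno, stringsAsFactors = FALSE)
  attr(out, "breakpoints") <- if (length(bps))
    data.frame(line_id = line_id, seq_id = seq_id, pos = bps,
               left_geno = core$lg, right_geno = core$rg,
               stringsAsFactors = FALSE)
    else bp_empty
  out
}

# marker-level breakpoint gap between two blocks: the first supported
# call of the right block's class within the transition zone, preceded by
# the last call of the left class -- the leftmost minimal-misclassification
# changepoint, deterministic across lines sharing a crossover gap.  When
# a block carries no call of its own class in the zone (a sub-threshold
# homozygote stretch expressed as a heterozygous block, or vice versa),
# the search falls back to the first sustained departure from the left
# class / last departure from the right class.  Returns the informative
# index t such that the breakpoint lies between calls t and t+1, or NA.
.bp_gap <- function(v, zone, gl, gr) {
  confirmed <- function(idx, not_class) {
    # a sustained departure: of the up-to-3 calls after the candidate, at
    # least 2 also leave the left class (so a sub-threshold stray run
    # cannot masquerade as the junction)
    vapply(idx, function(s) {
      if (s >= length(v)) return(TRUE)
      nx <- v[seq(s + 1, min(s + 3, length(v)))]
      sum(nx != not_class) >= min(2, length(nx))
    }, logical(1))
  }
  s_cand <- zone[v[zone] == gr]
  if (length(s_cand) > 1) {
    ok <- confirmed(s_cand, not_class = gl)
    if (any(ok)) s_cand <- s_cand[ok]
  }
  if (!length(s_cand)) {
    s_cand <- zone[v[zone] != gl]
    if (length(s_cand) > 1) {
      ok <- confirmed(s_cand, not_class = gl)
      if (any(ok)) s_cand <- s_cand[ok]
    }
  }
  if (!length(s_cand)) return(NA_integer_)
  s <- min(s_cand)
  t_cand <- zone[v[zone] == gl]
  t_cand <- t_cand[t_cand < s]
  if (!length(t_cand)) {
    t_cand <- zone[v[zone] != gr]
    t_cand <- t_cand[t_cand < s]
  }
  if (!length(t_cand)) return(NA_integer_)
  max(t_cand)
}

# leading-end refinement of an H window run: v = informative calls, geno =
# current run genotypes.  Returns list() or list(lead = list(x, t, mode)):
# x = terminal genotype, t = last informative index of the terminal block,
# mode = "replace" (H run becomes the terminal homozygous block),
# "insert" (terminal block prepended, H run kept: an interior
# opposite-parent stretch caused the H windows) or "drop" (the leading
# calls simply extend the adjacent block).
.refine_terminal <- function(v, geno, min_run = 3) {
  if (length(geno) < 2 || geno[1] != "H" || geno[2] == "H") return(list())
  g_next <- geno[2]
  x <- v[v != "H"][1]
  if (is.na(x)) return(list())
  if (match(TRUE, v != "H") - 1 > 2) return(list())  # genuine het head
  # maximal leading run of x, tolerating at most 2 consecutive H calls,
  # stopping at the other homozygote
  t <- 0; n_x <- 0; i <- 1; consec_h <- 0
  while (i <= length(v) && (v[i] == x || (v[i] == "H" && consec_h < 2))) {
    if (v[i] == x) { t <- i; n_x <- n_x + 1; consec_h <- 0 }
    else consec_h <- consec_h + 1
    i <- i + 1
  }
  if (n_x < min_run || t >= length(v)) return(list())
  after <- v[seq_len(length(v)) > t]
  h_gap <- match(TRUE, after != "H", nomatch = length(after) + 1) - 1
  if (x == g_next) {
    # H windows despite matching terminal calls: an interior
    # opposite-parent stretch caused them -> keep the H run and prepend
    # the terminal block; otherwise the leading calls merely extend the
    # adjacent block
    opp <- setdiff(c("A", "B"), x)
    r_after <- rle(after)
    opp_run <- suppressWarnings(max(r_after$lengths[r_after$values == opp]))
    if (is.finite(opp_run) && opp_run >= min_run)
      return(list(lead = list(x = x, t = t, mode = "insert")))
    if (h_gap <= 2) return(list(lead = list(x = x, t = t, mode = "drop")))
    return(list())
  }
  # no visible het segment between the leading run and the next block
  if (h_gap > 2) return(list())
  list(lead = list(x = x, t = t, mode = "replace"))
}

# all-H smoothed sequence: accept a clean "X then Y" structure with
# homozygous tails of >= min_run calls each and no visible interior het
.refine_whole_h <- function(v, min_run = 3) {
  hom <- v != "H"
  if (!any(hom)) return(NULL)
  x <- v[hom][1]; y <- rev(v[hom])[1]
  if (x == y) return(NULL)
  if (match(TRUE, hom) - 1 > 2 || match(TRUE, rev(hom)) - 1 > 2)
    return(NULL)                             # genuine het tails
  t <- 0; n_x <- 0; i <- 1; ch <- 0
  while (i <= length(v) && (v[i] == x || (v[i] == "H" && ch < 2))) {
    if (v[i] == x) { t <- i; n_x <- n_x + 1; ch <- 0 } else ch <- ch + 1
    i <- i + 1
  }
  s <- length(v) + 1; n_y <- 0; j <- length(v); ch <- 0
  while (j >= 1 && (v[j] == y || (v[j] == "H" && ch < 2))) {
    if (v[j] == y) { s <- j; n_y <- n_y + 1; ch <- 0 } else ch <- ch + 1
    j <- j - 1
  }
  if (n_x < min_run || n_y < min_run || s <= t) return(NULL)
  if (sum(v[t:s] == "H") > 2) return(NULL)
  list(x = x, y = y, t = t)
}

#' Block calls for all lines of a genotype matrix
#'
#' Runs the window smoothing and breakpoint detection for every line on
#' every sequence (scaffold or pseudomolecule) of a coded genotype matrix.
#'
#' @param gm A `genotype_matrix`.
#' @param seq_col,pos_col Names of the marker-metadata columns giving the
#'   sequence id and position to scan along (defaults `"scaffold"`,
#'   `"pos"`).
#' @param window,threshold Smoothing parameters.
#' @return A `block_calls` object: data.frame of blocks with attributes
#'   `breakpoints` (all lines), `extents` (per-sequence marker span) and
#'   `uncallable` (data.frame of line/sequence pairs with too few
#'   informative calls).
#' @export
call_blocks <- function(gm, seq_col = "scaffold", pos_col = "pos",
                        window = 15, threshold = 13) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  seqs <- unique(mk[[seq_col]])
  acc <- list(line = list(), seq = list(), start = list(), end = list(),
              geno = list())
  bacc <- list(line = list(), seq = list(), pos = list(), lg = list(),
               rg = list())
  unc_line <- character(0); unc_seq <- character(0)
  ext_seq <- character(0); ext_lo <- numeric(0); ext_hi <- numeric(0)
  k <- 0; bk <- 0
  for (s in seqs) {
    idx <- which(mk[[seq_col]] == s)
    idx <- idx[order(mk[[pos_col]][idx])]
    pos <- mk[[pos_col]][idx]
    lo <- pos[1]; hi <- pos[length(pos)]
    ext_seq <- c(ext_seq, s); ext_lo <- c(ext_lo, lo); ext_hi <- c(ext_hi, hi)
    for (l in gm$lines) {
      calls <- gm$calls[l, idx]
      w <- .win_calls(calls, pos, window, threshold)
      if (is.null(w)) {
        unc_line <- c(unc_line, l); unc_seq <- c(unc_seq, s)
        next
      }
      core <- .blocks_core(w, calls, pos, c(lo, hi), window, threshold)
      k <- k + 1
      acc$line[[k]] <- rep(l, length(core$geno))
      acc$seq[[k]] <- rep(s, length(core$geno))
      acc$start[[k]] <- c(lo, floor(core$bps) + 1)
      acc$end[[k]] <- c(floor(core$bps), hi)
      acc$geno[[k]] <- core$geno
      if (length(core$bps)) {
        bk <- bk + 1
        bacc$line[[bk]] <- rep(l, length(core$bps))
        bacc$seq[[bk]] <- rep(s, length(core$bps))
        bacc$pos[[bk]] <- core$bps
        bacc$lg[[bk]] <- core$lg
        bacc$rg[[bk]] <- core$rg
      }
    }
  }
  out <- data.frame(line_id = unlist(acc$line), seq_id = unlist(acc$seq),
                    start = unlist(acc$start), end = unlist(acc$end),
                    genotype = unlist(acc$geno), stringsAsFactors = FALSE)
  attr(out, "breakpoints") <- data.frame(
    line_id = as.character(unlist(bacc$line)),
    seq_id = as.character(unlist(bacc$seq)),
    pos = as.numeric(unlist(bacc$pos)),
    left_geno = as.character(unlist(bacc$lg)),
    right_geno = as.character(unlist(bacc$rg)), stringsAsFactors = FALSE)
  attr(out, "extents") <- data.frame(seq_id = ext_seq, start = ext_lo,
                                     end = ext_hi, stringsAsFactors = FALSE)
  attr(out, "uncallable") <- data.frame(line_id = unc_line,
                                        seq_id = unc_seq,
                                        stringsAsFactors = FALSE)
  class(out) <- c("block_calls", "data.frame")
  out
}

#' Build the population bin map
#'
#' Bin boundaries on each sequence are the sorted union of all lines'
#' breakpoints; bins are the intervals between consecutive boundaries,
#' tiling the marker-covered extent, so the number of bins per sequence is
#' the number of distinct breakpoints plus one.  Each line's bin genotype
#' is the genotype of its covering block (`NA` where the line was
#' un-callable on the sequence).
#'
#' @param blocks A `block_calls` object from [call_blocks()].
#' @return A `bin_map`: list with `bins` (data.frame `bin_id`, `seq_id`,
#'   `start`, `end`) and `geno` (lines x bins character matrix over
#'   A/B/H/NA).
#' @export
build_bins <- function(blocks) {
  stopifnot(inherits(blocks, "block_calls"))
  bps <- attr(blocks, "breakpoints")
  extents <- attr(blocks, "extents")
  lines <- unique(blocks$line_id)
  if (length(lines) < 2) stop("block calls for at least 2 lines required")

  bins <- list()
  for (s in extents$seq_id) {
    ext <- extents[extents$seq_id == s, ]
    cuts <- sort(unique(floor(bps$pos[bps$seq_id == s])))
    cuts <- cuts[cuts >= ext$start & cuts < ext$end]
    start <- c(ext$start, cuts + 1)
    end <- c(cuts, ext$end)
    bins[[s]] <- data.frame(
      bin_id = sprintf("%s_bin%d", s, seq_along(start)),
      seq_id = s, start = start, end = end, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins)
  rownames(bins) <- NULL

  geno <- matrix(NA_character_, nrow = length(lines), ncol = nrow(bins),
                 dimnames = list(lines, bins$bin_id))
  mid <- (bins$start + bins$end) / 2
  bin_by_seq <- split(seq_len(nrow(bins)), bins$seq_id)
  blk_by_seq <- split(seq_len(nrow(blocks)), blocks$seq_id)
  for (s in names(bin_by_seq)) {
    bidx <- bin_by_seq[[s]]
    rows <- blk_by_seq[[s]]
    if (is.null(rows)) next
    by_line <- split(rows, blocks$line_id[rows])
    for (l in names(by_line)) {
      rr <- by_line[[l]]
      st <- blocks$start[rr]; en <- blocks$end[rr]; gg <- blocks$genotype[rr]
      j <- findInterval(mid[bidx], st)
      g <- ifelse(j >= 1 & mid[bidx] <= en[pmax(j, 1)], gg[pmax(j, 1)],
                  NA_character_)
      geno[l, bidx] <- g
    }
  }
  structure(list(bins = bins, geno = geno), class = "bin_map")
}

#' Verify that no line recombines inside any bin
#'
#' Re-scans a bin map against the block calls it was built from and checks
#' that no line has a breakpoint strictly inside a bin.
#'
#' @param binmap A `bin_map`.
#' @param blocks The `block_calls` it was built from.
#' @return TRUE invisibly; stops with a message on violation.
#' @export
check_bins <- function(binmap, blocks) {
  bps <- attr(blocks, "breakpoints")
  bins <- binmap$bins
  for (s in unique(bins$seq_id)) {
    p <- unique(floor(bps$pos[bps$seq_id == s]))
    b <- bins[bins$seq_id == s, ]
    p <- p[p >= min(b$start) & p < max(b$end)]
    # every breakpoint must coincide with a bin boundary (the end of the
    # bin to its left); otherwise it falls strictly inside a bin
    if (!all(p %in% b$end)) stop("breakpoint strictly inside a bin on ", s)
  }
  invisible(TRUE)
}
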