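# Genetic-map-guided scaffold anchoring: conflict detection, chimeric
# scaffold splitting, placement/orientation, and pseudomolecule
# construction (AGP + FASTA).
#
# A chimeric scaffold does not always surface as "bins in two groups":
# windows smoothed across the misjoin create mosaic bins that can bridge
# the two chromosomes into a single linkage group.  Conflicts are
# therefore detected on the ordered map as scaffolds whose bins are
# dispersed into two runs separated by foreign bins, split at a
# marker-level changepoint, and the markers are re-binned and re-mapped --
# the iterative regroup/reorder/split workflow driven by
# [build_anchored_map()].

#' Detect scaffolds in conflict with the ordered map
#'
#' A scaffold conflicts with the map when its bins fall in more than one
#' linkage group; when they straddle a weak junction, i.e. an adjacent
#' map interval longer than `max_gap_cm` (a chimera can glue two
#' chromosomes into one apparent group through mosaic bins smoothed across
#' the misjoin -- the glue shows up as an implausibly long adjacent
#' interval); or when, within one map segment, they form two or more runs
#' separated by more than `foreign_tol` foreign bins (the scaffold is
#' "dispersed" along the map).
#'
#' @param map A `genetic_map` built on per-scaffold bins.
#' @param foreign_tol Number of interleaved foreign bins tolerated before
#'   two runs are declared (default 3).
#' @param max_gap_cm Adjacent intervals longer than this split a group
#'   into segments for straddle detection (default 15 cM; in a dense bin
#'   map genuine adjacent intervals are almost all below 6 cM).
#' @return data.frame of the conflicted scaffolds' bins with a `dest`
#'   column labelling the destination run of each bin, or `NULL` when no
#'   conflict exists.
#' @export
detect_scaffold_conflicts <- function(map, foreign_tol = 3, max_gap_cm = 15) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  tab <- tab[order(tab$group, tab$pos_cm), ]
  tab$rank_in_group <- unlist(lapply(split(tab$group, tab$group), seq_along),
                              use.names = FALSE)
  # segment each group at weak junctions
  seg <- unlist(lapply(split(tab$pos_cm, tab$group), function(p)
    cumsum(c(0, diff(p) > max_gap_cm))), use.names = FALSE)
  tab$segment <- paste0(tab$group, ".s", seg)
  conf <- list()
  for (s in unique(tab$seq_id)) {
    tt <- tab[tab$seq_id == s, ]
    tt <- tt[order(tt$start), ]
    if (length(unique(tt$group)) > 1) {
      tt$dest <- tt$group
      conf[[s]] <- tt
      next
    }
    if (length(unique(tt$segment)) > 1) {
      tt$dest <- tt$segment
      conf[[s]] <- tt
      next
    }
    if (nrow(tt) < 2) next
    rk <- sort(tt$rank_in_group)
    if (any(diff(rk) - 1 > foreign_tol)) {
      # label runs along the scaffold by rank clusters
      cl <- cumsum(c(0, diff(sort(tt$rank_in_group)) - 1 > foreign_tol))
      tt$dest <- paste0(tt$group, ".r", cl[rank(tt$rank_in_group)])
      conf[[s]] <- tt
    }
  }
  if (!length(conf)) return(NULL)
  out <- do.call(rbind, conf)
  rownames(out) <- NULL
  out
}

#' Split chimeric scaffolds at a marker-level changepoint
#'
#' For each conflicted scaffold, the raw marker calls are re-analysed at
#' marker level (the bins near a misjoin are mosaics of the two sides and
#' cannot localize it).  Per-line consensus genotypes of the first and
#' last `n_end` markers represent the scaffold's two ends; every marker is
#' classified to the end it matches better, and the split point is the
#' single changepoint minimizing misclassifications -- the midpoint
#' between the last marker of the left part and the first marker of the
#' right part.  A scaffold is split only when the two ends are genuinely
#' discordant (pairwise mismatch of the end consensi at least
#' `min_end_disc`) and the two-part structure is clean (misfit at the
#' changepoint at most 20 %); scaffolds with more than two destinations,
#' or without a clean two-part structure, are unresolvable (only two-part
#' splits are attempted) and are left unplaced.
#'
#' @param conflicts Conflict table from [detect_scaffold_conflicts()].
#' @param gm The `genotype_matrix` the bins were built from (raw marker
#'   calls and scaffold-local positions).
#' @param binmap The `bin_map` holding the bin genotypes (retained for
#'   destination bookkeeping).
#' @param n_end Markers in each end consensus (default 5).
#' @param min_end_disc Minimum end-to-end mismatch fraction for a split
#'   (default 0.2); ends of a contiguous scaffold are tightly linked and
#'   fall well below it.
#' @return List with `splits` (data.frame `scaffold_id`, `split_bp`,
#'   `left_dest`, `right_dest`, `reason`) and `unresolved` (scaffold ids).
#' @export
split_chimeras <- function(conflicts, gm, binmap, n_end = 5,
                           min_end_disc = 0.2) {
  empty <- data.frame(scaffold_id = character(0), split_bp = numeric(0),
                      left_dest = character(0), right_dest = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (is.null(conflicts) || nrow(conflicts) == 0)
    return(list(splits = empty, unresolved = character(0),
                drop_markers = character(0)))
  splits <- list(); unresolved <- character(0); drop_ids <- character(0)

  consensus <- function(calls) {             # per-line majority of A/B
    apply(calls, 1, function(z) {
      z <- z[!is.na(z) & z != "H"]
      if (!length(z)) return(NA_character_)
      names(which.max(table(z)))
    })
  }
  mism <- function(a, b) {
    ok <- !is.na(a) & !is.na(b) & a != "H" & b != "H"
    if (sum(ok) < 10) return(NA_real_)
    mean(a[ok] != b[ok])
  }

  for (s in unique(conflicts$seq_id)) {
    tt <- conflicts[conflicts$seq_id == s, ]
    tt <- tt[order(tt$start), ]
    dests <- unique(tt$dest)
    mi <- which(gm$markers$scaffold == s)
    mi <- mi[order(gm$markers$pos[mi])]
    pos <- gm$markers$pos[mi]
    calls <- gm$calls[, mi, drop = FALSE]
    n <- length(mi)
    if (n < 2 * n_end) {
      unresolved <- c(unresolved, s)
      next
    }
    gl <- consensus(calls[, seq_len(n_end), drop = FALSE])
    gr <- consensus(calls[, (n - n_end + 1):n, drop = FALSE])
    disc <- mism(gl, gr)
    if (is.na(disc) || disc < min_end_disc) {
      unresolved <- c(unresolved, s)
      next
    }
    rl <- apply(calls, 2, mism, b = gl)
    rr <- apply(calls, 2, mism, b = gr)
    side <- sign(rl - rr)                     # <0: left, >0: right
    side[is.na(side)] <- 0
    # cost[c] = (#right-looking in 1..c) + (#left-looking in c+1..n)
    cost <- vapply(seq_len(n - 1), function(c)
      sum(side[seq_len(c)] > 0) + sum(side[(c + 1):n] < 0), numeric(1))
    cstar <- which.min(cost)
    if (cost[cstar] / n > 0.2) {             # no clean two-part structure
      unresolved <- c(unresolved, s)
      next
    }
    split_bp <- floor((pos[cstar] + pos[cstar + 1]) / 2)
    # markers whose side classification disagrees with the split are of
    # ambiguous provenance; carrying them into a part would seed mosaic
    # bins on the pseudomolecule, so they are dropped
    mis <- c(which(side[seq_len(cstar)] > 0),
             cstar + which(side[(cstar + 1):n] < 0))
    if (length(mis))
      drop_ids <- c(drop_ids, gm$markers$marker_id[mi[mis]])
    reason <- if (length(unique(tt$group)) > 1) "conflicting groups" else
      "conflicting positions"
    dest_of <- function(lo, hi) {
      d <- tt$dest[tt$start <= hi & tt$end >= lo]
      if (!length(d)) NA_character_ else names(which.max(table(d)))
    }
    splits[[s]] <- data.frame(scaffold_id = s, split_bp = split_bp,
                              left_dest = dest_of(-Inf, split_bp),
                              right_dest = dest_of(split_bp + 1, Inf),
                              reason = reason, stringsAsFactors = FALSE)
  }
  sp <- do.call(rbind, splits)
  if (is.null(sp)) sp <- empty else rownames(sp) <- NULL
  list(splits = sp, unresolved = unresolved, drop_markers = drop_ids)
}

#' Apply scaffold splits to a genotype matrix
#'
#' Markers of each split scaffold are reassigned to `<scaffold>.1` (local
#' position at or below the split) or `<scaffold>.2`, keeping their
#' original scaffold-local positions so that split-part coordinates remain
#' source coordinates.
#'
#' @param gm A `genotype_matrix`.
#' @param splits Split table from [split_chimeras()].
#' @param drop_markers Marker ids of ambiguous provenance to remove (the
#'   `drop_markers` element of [split_chimeras()]).
#' @return The modified `genotype_matrix`.
#' @export
split_scaffold_markers <- function(gm, splits, drop_markers = NULL) {
  if (is.null(splits) || nrow(splits) == 0) return(gm)
  mk <- gm$markers
  for (i in seq_len(nrow(splits))) {
    s <- splits$scaffold_id[i]
    j <- mk$scaffold == s
    mk$scaffold[j] <- ifelse(mk$pos[j] <= splits$split_bp[i],
                             paste0(s, ".1"), paste0(s, ".2"))
  }
  gm$markers <- mk
  if (length(drop_markers)) {
    keep <- !(gm$markers$marker_id %in% drop_markers)
    gm$markers <- gm$markers[keep, , drop = FALSE]
    gm$calls <- gm$calls[, keep, drop = FALSE]
    if (!is.null(gm$parent_calls))
      gm$parent_calls <- gm$parent_calls[, keep, drop = FALSE]
  }
  gm
}

#' Scaffold-part table
#'
#' Builds the part table (`part_id`, `source_id`, `src_start`, `src_end`)
#' mapping possibly-split scaffold parts back to source-scaffold spans.
#'
#' @param scaffold_len Named vector of source scaffold lengths.
#' @param splits Accumulated split table (may be empty/NULL).
#' @return data.frame of parts.
#' @export
scaffold_parts <- function(scaffold_len, splits = NULL) {
  parts <- data.frame(part_id = names(scaffold_len),
                      source_id = names(scaffold_len),
                      src_start = 1, src_end = as.numeric(scaffold_len),
                      stringsAsFactors = FALSE)
  if (!is.null(splits) && nrow(splits) > 0) {
    for (i in seq_len(nrow(splits))) {
      s <- splits$scaffold_id[i]
      len <- scaffold_len[[s]]
      parts <- parts[parts$part_id != s, ]
      parts <- rbind(parts,
        data.frame(part_id = paste0(s, c(".1", ".2")), source_id = s,
                   src_start = c(1, splits$split_bp[i] + 1),
                   src_end = c(splits$split_bp[i], len),
                   stringsAsFactors = FALSE))
    }
  }
  rownames(parts) <- NULL
  parts
}

#' Anchor scaffolds along linkage groups
#'
#' Each scaffold (part) is assigned to the linkage group holding its bins,
#' ranked by the mean genetic position of those bins (ties broken by
#' scaffold id), and oriented by the sign of the rank correlation between
#' scaffold-local bin position and genetic position: `+` increasing, `-`
#' decreasing, `?` undetermined (fewer than two distinct genetic
#' positions).  Scaffolds still spanning two or more groups are returned
#' as conflicts, not placed.
#'
#' @param map A `genetic_map` whose `seq_id`s are scaffold part ids.
#' @param parts Part table from [scaffold_parts()].
#' @return List with `placements` (data.frame `scaffold_id`, `source_id`,
#'   `object`, `mean_cm`, `orientation`, `src_start`, `src_end`, `n_bins`,
#'   `rank`) and `conflicts` (bins of multi-group scaffolds, or NULL).
#' @export
anchor_scaffolds <- function(map, parts) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  out <- list(); conf <- list()
  for (s in unique(tab$seq_id)) {
    tt <- tab[tab$seq_id == s, ]
    if (length(unique(tt$group)) > 1) {
      conf[[s]] <- tt
      next
    }
    p <- parts[parts$part_id == s, ]
    if (nrow(p) != 1) stop("unknown scaffold part ", s)
    out[[s]] <- .place_scaffold(s, p$source_id, tt, p$src_start, p$src_end)
  }
  placements <- .rank_placements(do.call(rbind, out))
  conflicts <- do.call(rbind, conf)
  if (!is.null(conflicts)) rownames(conflicts) <- NULL
  list(placements = placements, conflicts = conflicts)
}

.place_scaffold <- function(part_id, source_id, tt, lo, hi) {
  mid <- (tt$start + tt$end) / 2
  ori <- "?"
  if (length(unique(tt$pos_cm)) >= 2 && length(unique(mid)) >= 2) {
    rho <- suppressWarnings(stats::cor(mid, tt$pos_cm, method = "spearman"))
    if (!is.na(rho) && rho > 0) ori <- "+"
    if (!is.na(rho) && rho < 0) ori <- "-"
  }
  data.frame(scaffold_id = part_id, source_id = source_id,
             object = sub("^LG", "Chr", tt$group[1]),
             mean_cm = mean(tt$pos_cm),
             orientation = ori, src_start = lo, src_end = hi,
             n_bins = nrow(tt), stringsAsFactors = FALSE)
}

.rank_placements <- function(placements) {
  if (is.null(placements) || nrow(placements) == 0) return(placements)
  placements <- placements[order(placements$object, placements$mean_cm,
                                 placements$scaffold_id), ]
  placements$rank <- unlist(lapply(split(seq_len(nrow(placements)),
                                         placements$object), seq_along),
                            use.names = FALSE)
  rownames(placements) <- NULL
  placements
}

#' Build an anchored genetic map with iterative chimera splitting
#'
#' Runs the full map-and-anchor cycle: per-scaffold binning, two-point
#' grouping and ordering, detection of scaffolds dispersed along the map,
#' marker-level splitting of those scaffolds, re-binning and re-mapping,
#' repeated until no conflict remains (or `max_iter` is reached), then
#' final scaffold placement.
#'
#' @param gm A filtered, coded `genotype_matrix` with scaffold metadata.
#' @param scaffold_len Named vector of source scaffold lengths (bp).
#' @param window,threshold Sliding-window parameters (defaults 15, 13).
#' @param lod_min Grouping LOD threshold (default 4.0).
#' @param foreign_tol,max_gap_cm Conflict-detection tolerances (see
#'   [detect_scaffold_conflicts()]).
#' @param max_iter Maximum split iterations (default 2: one detection and
#'   split pass, one rebuild).
#' @return List with `map` (final `genetic_map`), `binmap`, `blocks`,
#'   `placements`, `splits` (accumulated), `parts`, `unresolved` and the
#'   final `gm` (with split scaffold ids).
#' @export
build_anchored_map <- function(gm, scaffold_len, window = 15, threshold = 13,
                               lod_min = 4.0, foreign_tol = 3,
                               max_gap_cm = 15, max_iter = 2) {
  all_splits <- NULL
  map <- NULL
  for (it in seq_len(max_iter)) {
    map <- NULL                              # free bins^2 matrices before
    gc(FALSE)                                # the rebuild
    blocks <- call_blocks(gm, seq_col = "scaffold", pos_col = "pos",
                          window = window, threshold = threshold)
    binmap <- build_bins(blocks)
    map <- build_genetic_map(binmap, lod_min = lod_min,
                             allow_weak_adjacencies = TRUE)
    conflicts <- detect_scaffold_conflicts(map, foreign_tol = foreign_tol,
                                           max_gap_cm = max_gap_cm)
    if (is.null(conflicts) || it == max_iter) break
    sp <- split_chimeras(conflicts, gm, binmap)
    if (nrow(sp$splits) == 0) break
    # splits recorded against source scaffolds; a part split again is not
    # expected under two-part chimeras and is left to the next iteration
    all_splits <- rbind(all_splits, sp$splits)
    gm <- split_scaffold_markers(gm, sp$splits, sp$drop_markers)
  }
  map <- build_genetic_map(binmap, lod_min = lod_min)
  parts <- scaffold_parts(scaffold_len, all_splits)
  anc <- anchor_scaffolds(map, parts)
  unresolved <- if (is.null(anc$conflicts)) character(0) else
    unique(anc$conflicts$seq_id)
  list(map = map, binmap = binmap, blocks = blocks,
       placements = anc$placements, splits = all_splits, parts = parts,
       unresolved = unresolved, gm = gm)
}

#' Anchored fraction of the assembly
#'
#' @param placements Placement table.
#' @param scaffold_len Named vector of all source scaffold lengths.
#' @return Fraction of total assembly bp anchored.
#' @export
anchored_fraction <- function(placements, scaffold_len) {
  sum(placements$src_end - placements$src_start + 1) / sum(scaffold_len)
}

#' Build pseudomolecules from placements
#'
#' Components are joined in rank order with `gap_len` `N` bases between
#' them (AGP U-type scaffold gaps, linkage yes, evidence map); minus
#' components are reverse-complemented; `?` components are treated as `+`
#' in the sequence but keep `?` in the AGP orientation column.  Split
#' parts are extracted from the source scaffold by their source span.
#'
#' @param placements Placement table from [anchor_scaffolds()].
#' @param scaffold_seqs A [Biostrings::DNAStringSet] of source scaffold
#'   sequences, named by scaffold id.
#' @param gap_len Gap length between components (default 100).
#' @return List with `seqs` (pseudomolecule `DNAStringSet`), `agp`
#'   (data.frame, AGP v2.1 columns) and `unplaced` (source scaffold ids
#'   with no placed part).
#' @export
write_pseudomolecules <- function(placements, scaffold_seqs, gap_len = 100) {
  stopifnot(is.data.frame(placements))
  objs <- sort(unique(placements$object))
  seqs <- character(length(objs)); names(seqs) <- objs
  agp <- list()
  for (ob in objs) {
    pl <- placements[placements$object == ob, ]
    pl <- pl[order(pl$rank), ]
    pieces <- character(0)
    pos <- 0; pn <- 0
    for (i in seq_len(nrow(pl))) {
      src <- pl$source_id[i]
      if (!src %in% names(scaffold_seqs))
        stop("sequence missing for scaffold ", src)
      comp <- Biostrings::subseq(scaffold_seqs[[src]], pl$src_start[i],
                                 pl$src_end[i])
      if (pl$orientation[i] == "-")
        comp <- Biostrings::reverseComplement(comp)
      if (i > 1) {
        pn <- pn + 1
        agp[[length(agp) + 1]] <- data.frame(
          object = ob, object_beg = pos + 1, object_end = pos + gap_len,
          part_number = pn, component_type = "U", component_id = gap_len,
          component_beg = "scaffold", component_end = "yes",
          orientation = "map", stringsAsFactors = FALSE)
        pos <- pos + gap_len
        pieces <- c(pieces, strrep("N", gap_len))
      }
      pn <- pn + 1
      w <- length(comp)
      agp[[length(agp) + 1]] <- data.frame(
        object = ob, object_beg = pos + 1, object_end = pos + w,
        part_number = pn, component_type = "W",
        component_id = pl$scaffold_id[i],
        component_beg = as.character(pl$src_start[i]),
        component_end = as.character(pl$src_end[i]),
        orientation = pl$orientation[i],
        stringsAsFactors = FALSE)
      pos <- pos + w
      pieces <- c(pieces, as.character(comp))
    }
    seqs[ob] <- paste(pieces, collapse = "")
  }
  agp <- do.call(rbind, agp)
  unplaced <- setdiff(names(scaffold_seqs), placements$source_id)
  list(seqs = Biostrings::DNAStringSet(seqs), agp = agp,
       unplaced = unplaced)
}

#' Rebuild pseudomolecule sequences from an AGP table
#'
#' Independent reconstruction used for round-trip checks: walks the AGP
#' components, extracting and orienting source-scaffold spans and
#' inserting `N` gaps.  Split-part component ids (`<scaffold>.<part>`) are
#' resolved against the parent scaffold via the component span, and `?`
#' orientations are treated as `+`.
#'
#' @param agp AGP data.frame from [write_pseudomolecules()] or
#'   [read_agp()].
#' @param scaffold_seqs `DNAStringSet` of source scaffold sequences.
#' @return A `DNAStringSet` of pseudomolecules.
#' @export
agp_to_fasta <- function(agp, scaffold_seqs) {
  objs <- unique(agp$object)
  out <- character(length(objs)); names(out) <- objs
  for (ob in objs) {
    rows <- agp[agp$object == ob, ]
    rows <- rows[order(rows$part_number), ]
    parts <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (rows$component_type[i] == "U") {
        parts[i] <- strrep("N", as.integer(rows$component_id[i]))
      } else {
        src <- sub("\\.[0-9]+$", "", rows$component_id[i])
        if (!src %in% names(scaffold_seqs)) src <- rows$component_id[i]
        comp <- Biostrings::subseq(scaffold_seqs[[src]],
                                   as.integer(rows$component_beg[i]),
                                   as.integer(rows$component_end[i]))
        if (rows$orientation[i] == "-")
          comp <- Biostrings::reverseComplement(comp)
        parts[i] <- as.character(comp)
      }
    }
    out[ob] <- paste(parts, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

#' Write an AGP v2.1 file
#'
#' @param agp AGP data.frame (9 columns, 1-based inclusive).
#' @param path Output path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file path.
#' @return AGP data.frame with the column names used by
#'   [write_pseudomolecules()].
#' @export
read_agp <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")
  df
}

#' Project markers onto pseudomolecule coordinates
#'
#' Computes, for every marker placed on an anchored scaffold part, its
#' pseudomolecule id and 1-based position implied by the placements and
#' gap length -- the coordinate system on which the final bin map is
#' built.
#'
#' @param gm A `genotype_matrix` (scaffold ids may be split part ids).
#' @param placements Placement table.
#' @param gap_len Gap length used between components (default 100).
#' @return `gm` with `chrom`/`chrom_pos` columns added to `markers`;
#'   markers on unplaced scaffolds get `NA`.
#' @export
project_markers <- function(gm, placements, gap_len = 100) {
  mk <- gm$markers
  mk$chrom <- NA_character_
  mk$chrom_pos <- NA_real_
  for (ob in unique(placements$object)) {
    pl <- placements[placements$object == ob, ]
    pl <- pl[order(pl$rank), ]
    offset <- 0
    for (i in seq_len(nrow(pl))) {
      w <- pl$src_end[i] - pl$src_start[i] + 1
      j <- which(mk$scaffold == pl$scaffold_id[i])
      if (length(j)) {
        local <- mk$pos[j] - pl$src_start[i] + 1   # 1..w within the part
        ppos <- if (pl$orientation[i] == "-") offset + (w - local + 1) else
          offset + local
        mk$chrom[j] <- ob
        mk$chrom_pos[j] <- ppos
      }
      offset <- offset + w + gap_len
    }
  }
  gm$markers <- mk
  gm
}
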