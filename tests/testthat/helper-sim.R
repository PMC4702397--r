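# Shared fixtures and truth-side oracles for the test suite.

# small bin_map from a genotype matrix of coded calls (lines x bins)
toy_binmap <- function(g, seq_id = "s") {
  structure(list(
    bins = data.frame(bin_id = colnames(g), seq_id = seq_id,
                      start = seq_len(ncol(g)) * 1000 - 999,
                      end = seq_len(ncol(g)) * 1000,
                      stringsAsFactors = FALSE),
    geno = g), class = "bin_map")
}

# phenotype table from a vector of line means (one env, one rep)
toy_pheno <- function(y, trait = "T", env = "E1") {
  data.frame(line_id = names(y), env = env, rep = 1, trait = trait,
             value = as.numeric(y), is_parent = FALSE,
             stringsAsFactors = FALSE)
}

# Truth-side oracle for breakpoint recovery on noiseless data.  Projects a
# line's true genotype to the marker sites and derives the breakpoints the
# window rule can resolve, directly from counting arguments (never by
# running the smoother):
#   - runs shorter than window-threshold+1 = 3 markers cannot move any
#     window call: invisible, absorbed;
#   - a homozygous run of 3..12 markers cannot reach the 13-call
#     homozygote threshold: it is expressed as heterozygous and fuses
#     with adjacent het runs -- except at a sequence end next to the
#     opposite homozygote, where the marker-level terminal refinement
#     recovers it;
#   - each surviving transition is placed at the midpoint between the
#     last call of the left class and the first call of the right class.
oracle_line_breakpoints <- function(truth, line, chrom, pos,
                                    window = 15, threshold = 13) {
  min_run <- window - threshold + 1
  g <- true_genotype_at(truth, line, chrom, pos)
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  geno <- r$values

  drop_run <- function(j) {
    geno <<- geno[-j]; starts <<- starts[-j]; ends <<- ends[-j]
    protected <<- protected[-j]
    if (j > 1 && j <= length(geno) && geno[j - 1] == geno[j]) {
      ends[j - 1] <<- ends[j]
      geno <<- geno[-j]; starts <<- starts[-j]; ends <<- ends[-j]
      protected <<- protected[-j]
    }
  }
  protected <- rep(FALSE, length(geno))

  # invisible runs first
  repeat {
    len <- ends - starts + 1
    j <- which(len < min_run)
    if (!length(j)) break
    if (length(geno) == 1) return(numeric(0))
    drop_run(j[1])
  }
  # terminal sub-threshold homozygote next to the opposite homozygote is
  # recoverable at marker level
  n <- length(geno)
  if (n >= 2) for (j in unique(c(1, n))) {
    nb <- if (j == 1) 2 else n - 1
    if (geno[j] %in% c("A", "B") && (ends[j] - starts[j] + 1) < threshold &&
        geno[nb] %in% c("A", "B") && geno[nb] != geno[j])
      protected[j] <- TRUE
  }
  # sub-threshold homozygotes are expressed as het
  repeat {
    len <- ends - starts + 1
    j <- which(geno %in% c("A", "B") & len < threshold & !protected)
    if (!length(j)) break
    geno[j[1]] <- "H"
    # merge adjacent equal runs
    k <- 1
    while (k < length(geno)) {
      if (geno[k] == geno[k + 1]) {
        ends[k] <- ends[k + 1]
        geno <- geno[-(k + 1)]; starts <- starts[-(k + 1)]
        ends <- ends[-(k + 1)]; protected <- protected[-(k + 1)]
      } else k <- k + 1
    }
  }
  if (length(geno) < 2) return(numeric(0))

  # transition positions: first right-class call in the right run, then
  # the last left-class call the window rule still associates with the
  # left block.  A homozygous left block supports calls arbitrarily close
  # to its last window; a heterozygous left block's last H-classified
  # window starts only window-threshold calls before s, so an actual H
  # call further back than that is outside the transition and the
  # boundary falls to the call just before s (the end of an absorbed
  # sub-threshold homozygote stretch).
  out <- numeric(length(geno) - 1)
  for (j in seq_len(length(geno) - 1)) {
    span_r <- starts[j + 1]:ends[j + 1]
    s <- span_r[g[span_r] == geno[j + 1]][1]
    if (is.na(s)) s <- starts[j + 1]
    if (geno[j] %in% c("A", "B")) {
      span_l <- starts[j]:(s - 1)
      tl <- span_l[g[span_l] == geno[j]]
      t <- if (length(tl)) max(tl) else s - 1
    } else {
      near <- max(starts[j], s - (window - threshold)):(s - 1)
      hh <- near[g[near] == "H"]
      t <- if (length(hh)) max(hh) else s - 1
    }
    out[j] <- (pos[t] + pos[t + 1]) / 2
  }
  out
}

# order-consistency check: within one linkage group, every bin pair with
# at least min_rec observed recombinant lines must be ordered like the
# true physical positions (up to global reversal).  Zero-recombinant
# pairs are unordered at the data's resolution; with genotyping error,
# 1-2 apparent recombinants cannot be told from error, so noisy-data
# checks use min_rec = 3 (the same evidential threshold as the window
# rule's visibility bound)
order_consistent <- function(tab_group, tp, min_rec = 1) {
  ids <- tab_group$bin_id
  n <- length(ids)
  if (n < 3) return(TRUE)
  R <- tp$R[ids, ids]
  nrec <- R * tp$n_inf[ids, ids]
  informative <- !is.na(nrec) & nrec >= min_rec
  o <- outer(seq_len(n), seq_len(n), "-")
  t <- outer(tab_group$start, tab_group$start, "-")
  s <- sign(o[informative]) * sign(t[informative])
  all(s >= 0) || all(s <= 0)
}

# true tiling record of a (possibly split) scaffold part, by best overlap
true_tiling_part <- function(genome, source_id, lo, hi) {
  tl <- genome$scaffolds[genome$scaffolds$scaffold_id == source_id, ]
  ov <- pmin(hi, tl$scaff_end) - pmax(lo, tl$scaff_start) + 1
  tl[which.max(ov), ]
}
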