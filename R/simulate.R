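# Forward simulation of a biparental single-seed-descent RIL study:
# genome + scaffold tiling (with optional chimeric scaffolds), the cross,
# marker observation with noise, and multi-environment phenotypes.
# Every object carries enough truth for downstream recovery tests.

#' Simulate a genome with a scaffold tiling
#'
#' Builds the assembly context for a mapping study: `n_chrom` chromosomes of
#' given physical length, each tiled by scaffolds with random breakpoints and
#' random orientations.  Optionally, pairs of scaffold segments from two
#' different chromosomes are fused into chimeric scaffolds (emulating
#' misjoins from paired-end links) whose identity is recorded so that
#' downstream splitting can be checked against the truth.
#'
#' @param n_chrom Number of chromosomes (default 13).
#' @param chrom_len_bp Physical chromosome length(s) in bp; recycled to
#'   `n_chrom`.
#' @param cm_per_mb Recombination rate; genetic length of each chromosome is
#'   `chrom_len_bp * cm_per_mb / 1e6` cM (default 4.25 cM/Mb).
#' @param n_scaffolds Total number of scaffold segments tiling the genome
#'   (before chimera fusion); at least `n_chrom`.
#' @param n_chimeras Number of chimeric scaffolds to create by fusing two
#'   segments from different chromosomes.  Must be `< n_scaffolds / 2`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An object of class `ril_genome`: list with `chromosomes`
#'   (data.frame `chrom`, `length_bp`, `length_cm`), `scaffolds` (tiling
#'   records: `scaffold_id`, `chrom`, `start_bp`, `end_bp`, `orientation`,
#'   `scaff_start`, `scaff_end`, `scaff_len`) and `chimeras` (character
#'   vector of chimeric scaffold ids).  Chimeric scaffolds have exactly two
#'   tiling records with disjoint scaffold-local spans covering the scaffold.
#' @export
simulate_genome <- function(n_chrom = 13, chrom_len_bp = 2e7,
                            cm_per_mb = 4.25, n_scaffolds = 10 * n_chrom,
                            n_chimeras = 0, seed = 1) {
  stopifnot(n_chrom >= 1, n_scaffolds >= n_chrom)
  chrom_len_bp <- rep_len(chrom_len_bp, n_chrom)
  if (any(chrom_len_bp <= 0)) stop("chromosome lengths must be positive")
  if (cm_per_mb <= 0) stop("cm_per_mb must be positive")
  if (n_chimeras >= n_scaffolds / 2)
    stop("n_chimeras must be smaller than n_scaffolds / 2")
  set.seed(seed)

  chroms <- data.frame(
    chrom = sprintf("chr%02d", seq_len(n_chrom)),
    length_bp = as.numeric(chrom_len_bp),
    length_cm = chrom_len_bp * cm_per_mb / 1e6,
    stringsAsFactors = FALSE
  )

  # distribute scaffold counts proportional to physical length, >= 1 each
  extra <- n_scaffolds - n_chrom
  per_chrom <- rep(1L, n_chrom)
  if (extra > 0) {
    add <- table(factor(sample.int(n_chrom, extra, replace = TRUE,
                                   prob = chrom_len_bp), levels = seq_len(n_chrom)))
    per_chrom <- per_chrom + as.integer(add)
  }

  tiling <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    k <- per_chrom[i]
    w <- stats::rgamma(k, shape = 4)          # moderate size variation
    ends <- round(cumsum(w) / sum(w) * chrom_len_bp[i])
    ends[k] <- chrom_len_bp[i]
    starts <- c(1, utils::head(ends, -1) + 1)
    keep <- ends >= starts                     # guard against zero-length
    starts <- starts[keep]; ends <- ends[keep]
    tiling[[i]] <- data.frame(
      chrom = chroms$chrom[i],
      start_bp = starts, end_bp = ends,
      orientation = sample(c("+", "-"), length(starts), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  tiling <- do.call(rbind, tiling)
  n_seg <- nrow(tiling)
  seg_len <- tiling$end_bp - tiling$start_bp + 1

  # fuse n_chimeras pairs of segments from different chromosomes
  chim_ids <- character(0)
  scaffold_id <- character(n_seg)
  scaff_start <- rep(1, n_seg)
  scaff_end <- seg_len
  part <- rep(1L, n_seg)
  if (n_chimeras > 0) {
    pool <- seq_len(n_seg)
    pairs <- matrix(NA_integer_, nrow = n_chimeras, ncol = 2)
    for (p in seq_len(n_chimeras)) {
      a <- sample(pool, 1)
      bpool <- pool[tiling$chrom[pool] != tiling$chrom[a] & pool != a]
      if (length(bpool) == 0) stop("cannot place chimera across chromosomes")
      b <- if (length(bpool) == 1) bpool else sample(bpool, 1)
      pairs[p, ] <- c(a, b)
      pool <- setdiff(pool, c(a, b))
    }
    for (p in seq_len(n_chimeras)) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      scaff_start[b] <- seg_len[a] + 1
      scaff_end[b] <- seg_len[a] + seg_len[b]
      part[b] <- 2L
    }
    # ids assigned after fusion so each scaffold gets one id
    grp <- seq_len(n_seg)
    for (p in seq_len(n_chimeras)) grp[pairs[p, 2]] <- pairs[p, 1]
  } else {
    grp <- seq_len(n_seg)
  }
  uid <- match(grp, unique(grp))
  scaffold_id <- sprintf("scaffold%04d", uid)
  if (n_chimeras > 0) chim_ids <- unique(scaffold_id[part == 2L])

  scaffolds <- data.frame(
    scaffold_id = scaffold_id,
    chrom = tiling$chrom,
    start_bp = tiling$start_bp,
    end_bp = tiling$end_bp,
    orientation = tiling$orientation,
    scaff_start = scaff_start,
    scaff_end = scaff_end,
    stringsAsFactors = FALSE
  )
  scaffolds <- scaffolds[order(scaffolds$chrom, scaffolds$start_bp), ]
  rownames(scaffolds) <- NULL

  structure(list(chromosomes = chroms, scaffolds = scaffolds,
                 chimeras = chim_ids),
            class = "ril_genome")
}

#' Scaffold lengths of a simulated genome
#'
#' @param genome A `ril_genome`.
#' @return Named numeric vector of scaffold lengths in bp (chimeric
#'   scaffolds are the sum of their two parts).
#' @export
scaffold_lengths <- function(genome) {
  sc <- genome$scaffolds
  len <- tapply(sc$scaff_end, sc$scaffold_id, max)
  out <- as.numeric(len)
  names(out) <- names(len)
  out
}

#' Simulate scaffold sequences
#'
#' Random uniform-composition DNA for each scaffold of a simulated genome,
#' for exercising pseudomolecule construction.  Sequence content carries no
#' signal; only lengths and identities matter.
#'
#' @param genome A `ril_genome`.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named by scaffold id.
#' @export
simulate_scaffold_seqs <- function(genome, seed = 1) {
  set.seed(seed)
  len <- scaffold_lengths(genome)
  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(len)))
}

## internal haplotype machinery ------------------------------------------
## a haplotype on one chromosome is list(end = numeric seg end positions
## (last == L), orig = integer +1 (parent A) / -1 (parent B))

.meiosis <- function(h1, h2, L_bp, L_morgan) {
  n_co <- stats::rpois(1, L_morgan)
  start <- sample(c(1L, 2L), 1)
  if (n_co == 0) return(if (start == 1L) h1 else h2)
  xpos <- sort(stats::runif(n_co, 0, L_bp))
  bounds <- c(xpos, L_bp)
  haps <- list(h1, h2)
  cur <- start
  end <- numeric(0); orig <- integer(0)
  lo <- 0
  for (i in seq_along(bounds)) {
    hi <- bounds[i]
    h <- haps[[cur]]
    j1 <- which(h$end > lo)[1]
    j2 <- which(h$end >= hi)[1]
    if (j1 <= j2) {
      e <- h$end[j1:j2]; o <- h$orig[j1:j2]
      e[length(e)] <- hi
      end <- c(end, e); orig <- c(orig, o)
    }
    lo <- hi
    cur <- 3L - cur
  }
  keep <- c(diff(end) > 0, TRUE)            # drop zero-length pieces
  end <- end[keep]; orig <- orig[keep]
  if (length(orig) > 1) {                    # merge equal neighbours
    same <- c(orig[-1] == orig[-length(orig)], FALSE)
    end <- end[!same]; orig <- orig[!same]
  }
  list(end = end, orig = orig)
}

.diplo_genotype <- function(h1, h2) {
  ends <- sort(unique(c(h1$end, h2$end)))
  o1 <- h1$orig[findInterval(ends, h1$end, left.open = TRUE) + 1]
  o2 <- h2$orig[findInterval(ends, h2$end, left.open = TRUE) + 1]
  g <- ifelse(o1 == o2, o1, 0L)              # +1 = A, -1 = B, 0 = H
  if (length(g) > 1) {
    same <- c(g[-1] == g[-length(g)], FALSE)
    ends <- ends[!same]; g <- g[!same]
  }
  list(end = ends, geno = as.integer(g))
}

#' Simulate a RIL population by single-seed descent
#'
#' Starting from the F1 of two fully homozygous parents, each line is
#' advanced by selfing with single-seed descent for `n_generations - 1`
#' rounds of meiosis.  Crossovers follow a no-interference count process:
#' per meiosis the crossover count on a chromosome is Poisson with mean
#' equal to its genetic length in Morgans, positions uniform.  At F8 the
#' expected residual heterozygosity is (1/2)^7 of the genome.
#'
#' @param genome A `ril_genome` from [simulate_genome()].
#' @param n_lines Number of RILs (default 430).
#' @param n_generations Filial generation number (default 8, i.e. F8).
#' @param seed Integer seed.
#' @return An object of class `ril_truth`: list with `genome`, `lines`,
#'   `generation` and `seg`, a per-line list of per-chromosome genotype
#'   segments (`end` positions and integer `geno` +1/0/-1 for A/H/B).
#'   Use [truth_segments()] for a tidy data.frame view.
#' @export
simulate_cross <- function(genome, n_lines = 430, n_generations = 8,
                           seed = 1) {
  stopifnot(inherits(genome, "ril_genome"))
  if (n_lines <= 0) stop("n_lines must be positive")
  if (n_generations < 2) stop("n_generations must be >= 2")
  set.seed(seed)
  ch <- genome$chromosomes
  n_chrom <- nrow(ch)
  lines <- sprintf("RIL%04d", seq_len(n_lines))

  seg <- vector("list", n_lines)
  for (l in seq_len(n_lines)) {
    per_chrom <- vector("list", n_chrom)
    for (c in seq_len(n_chrom)) {
      L_bp <- ch$length_bp[c]
      L_m <- ch$length_cm[c] / 100
      h1 <- list(end = L_bp, orig = 1L)      # F1: one A and one B haplotype
      h2 <- list(end = L_bp, orig = -1L)
      for (g in seq_len(n_generations - 1)) {
        g1 <- .meiosis(h1, h2, L_bp, L_m)
        g2 <- .meiosis(h1, h2, L_bp, L_m)
        h1 <- g1; h2 <- g2
      }
      per_chrom[[c]] <- .diplo_genotype(h1, h2)
    }
    names(per_chrom) <- ch$chrom
    seg[[l]] <- per_chrom
  }
  names(seg) <- lines
  structure(list(genome = genome, lines = lines,
                 generation = n_generations, seg = seg),
            class = "ril_truth")
}

#' Tidy view of true genotype segments
#'
#' @param truth A `ril_truth`.
#' @return data.frame with `line_id`, `chrom`, `start_bp`, `end_bp`,
#'   `genotype` (A/H/B) and `heterozygous` flag.
#' @export
truth_segments <- function(truth) {
  stopifnot(inherits(truth, "ril_truth"))
  out <- lapply(truth$lines, function(l) {
    per <- truth$seg[[l]]
    do.call(rbind, lapply(names(per), function(cn) {
      s <- per[[cn]]
      data.frame(line_id = l, chrom = cn,
                 start_bp = c(1, utils::head(s$end, -1) + 1),
                 end_bp = s$end,
                 genotype = c("B", "H", "A")[s$geno + 2L],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out$heterozygous <- out$genotype == "H"
  rownames(out) <- NULL
  out
}

#' True genotypes of one line at given chromosome positions
#'
#' @param truth A `ril_truth`.
#' @param line_id Line identifier.
#' @param chrom Chromosome id.
#' @param pos Positions in bp.
#' @return Character vector over A/H/B.
#' @export
true_genotype_at <- function(truth, line_id, chrom, pos) {
  s <- truth$seg[[line_id]][[chrom]]
  if (is.null(s)) stop("unknown line or chromosome")
  g <- s$geno[findInterval(pos, s$end, left.open = TRUE) + 1]
  c("B", "H", "A")[g + 2L]
}

#' Observe SNP markers on a simulated population
#'
#' Places `markers_per_scaffold` biallelic SNPs uniformly on each scaffold,
#' projects every line's true genotype to the marker sites, then corrupts
#' the calls: with probability `error_rate` a call is replaced by one of the
#' two other states (other homozygote or heterozygote, equally likely) and
#' with probability `missing_rate` it is set missing.  Parent calls (all-A
#' and all-B) receive the same noise.  Marker metadata carries the scaffold
#' id and scaffold-local position, plus `true_chrom`/`true_pos` truth
#' columns used only by recovery tests.
#'
#' @param truth A `ril_truth`.
#' @param markers_per_scaffold Number of SNPs per scaffold (default 30).
#' @param missing_rate,error_rate Per-call rates in `[0, 1)` for the RIL
#'   lines.
#' @param parent_missing_rate,parent_error_rate Rates for the parent
#'   calls; parents are typically sequenced much deeper than the
#'   population, so the defaults are low.
#' @param seed Integer seed.
#' @return A `genotype_matrix`: list with `markers` (data.frame), `lines`,
#'   `calls` (lines x markers character matrix over A/B/H/NA) and
#'   `parent_calls` (2 x markers, rows P1/P2).
#' @export
observe_markers <- function(truth, markers_per_scaffold = 30,
                            missing_rate = 0, error_rate = 0,
                            parent_missing_rate = 0.02,
                            parent_error_rate = 0.002, seed = 1) {
  stopifnot(inherits(truth, "ril_truth"))
  rates <- c(missing_rate, error_rate, parent_missing_rate,
             parent_error_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("missing_rate and error_rate must lie in [0, 1)")
  set.seed(seed)
  sc <- truth$genome$scaffolds

  # sample scaffold-local marker positions per tiling part, proportional to
  # part length so density is uniform along the scaffold
  slen <- scaffold_lengths(truth$genome)
  mk <- lapply(seq_len(nrow(sc)), function(i) {
    part_len <- sc$scaff_end[i] - sc$scaff_start[i] + 1
    n <- max(1L, round(markers_per_scaffold * part_len / slen[[sc$scaffold_id[i]]]))
    lp <- sort(sample.int(part_len, min(n, part_len)))
    local <- sc$scaff_start[i] + lp - 1
    chrom_pos <- if (sc$orientation[i] == "+")
      sc$start_bp[i] + lp - 1 else sc$end_bp[i] - lp + 1
    data.frame(scaffold = sc$scaffold_id[i], pos = local,
               true_chrom = sc$chrom[i], true_pos = chrom_pos,
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, mk)
  mk <- mk[order(mk$scaffold, mk$pos), ]
  rownames(mk) <- NULL
  mk$marker_id <- paste0(mk$scaffold, "_", mk$pos)
  nt <- c("A", "C", "G", "T")
  ia <- sample.int(4, nrow(mk), replace = TRUE)
  ib <- ((ia - 1L + sample.int(3, nrow(mk), replace = TRUE)) %% 4L) + 1L
  mk$allele_a <- nt[ia]
  mk$allele_b <- nt[ib]
  mk <- mk[, c("marker_id", "scaffold", "pos", "allele_a", "allele_b",
               "true_chrom", "true_pos")]

  n_mk <- nrow(mk)
  lines <- truth$lines
  calls <- matrix(NA_character_, nrow = length(lines), ncol = n_mk,
                  dimnames = list(lines, mk$marker_id))
  for (l in seq_along(lines)) {
    g <- character(n_mk)
    for (cn in unique(mk$true_chrom)) {
      idx <- which(mk$true_chrom == cn)
      g[idx] <- true_genotype_at(truth, lines[l], cn, mk$true_pos[idx])
    }
    calls[l, ] <- g
  }
  parent_calls <- matrix(c(rep("A", n_mk), rep("B", n_mk)), nrow = 2,
                         byrow = TRUE, dimnames = list(c("P1", "P2"),
                                                       mk$marker_id))

  corrupt <- function(m, err, mis) {
    n <- length(m)
    if (err > 0) {
      flip <- which(stats::runif(n) < err)
      if (length(flip)) {
        states <- c("A", "B", "H")
        for (i in flip) {
          m[i] <- sample(setdiff(states, m[i]), 1)
        }
      }
    }
    if (mis > 0) m[stats::runif(n) < mis] <- NA_character_
    m
  }
  calls[] <- corrupt(calls, error_rate, missing_rate)
  parent_calls[] <- corrupt(parent_calls, parent_error_rate,
                            parent_missing_rate)

  structure(list(markers = mk, lines = lines, calls = calls,
                 parent_calls = parent_calls),
            class = "genotype_matrix")
}

#' Specify quantitative trait loci for phenotype simulation
#'
#' @param qtls data.frame with columns `trait`, `chrom`, `pos_bp`,
#'   `additive` (effect in trait units; positive means the parent-A allele
#'   increases the trait).
#' @param h2 Plot-level narrow-sense heritability of the simulated genetic
#'   signal, in `[0, 1]` (environment main effects are treated as block
#'   effects and excluded from the ratio).
#' @param n_env,n_reps Number of environments and replicate plots per
#'   environment (defaults 3 and 3, a randomized-complete-block layout).
#' @param env_effect_sd SD of the per-environment additive shift, trait
#'   units.
#' @param grand_mean Trait grand mean(s); named by trait or recycled.
#' @param null_sd Residual SD used when a trait has no genetic variance
#'   (h2 undefined); default 1 trait unit.
#' @return A `qtl_spec` object.
#' @export
qtl_spec <- function(qtls, h2 = 0.8, n_env = 3, n_reps = 3,
                     env_effect_sd = 1, grand_mean = 100, null_sd = 1) {
  stopifnot(is.data.frame(qtls),
            all(c("trait", "chrom", "pos_bp", "additive") %in% names(qtls)))
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (h2 == 1 && env_effect_sd > 0)
    stop("h2 = 1 is inconsistent with a nonzero env_effect_sd")
  structure(list(qtls = qtls, h2 = h2, n_env = n_env, n_reps = n_reps,
                 env_effect_sd = env_effect_sd, grand_mean = grand_mean,
                 null_sd = null_sd),
            class = "qtl_spec")
}

#' Simulate multi-environment phenotypes
#'
#' Each plot value is grand mean + sum of additive QTL contributions
#' (genotype score x = +1/-1 by parental origin, 0 if heterozygous) + a
#' per-environment shift + Gaussian plot residual.  The residual SD is set
#' from the realized genetic variance so that plot-level
#' genetic/(genetic+residual) variance equals `h2`.  Parents are simulated
#' alongside the RILs (all-A and all-B genotypes) and flagged.
#'
#' @param truth A `ril_truth`.
#' @param spec A `qtl_spec`.
#' @param seed Integer seed.
#' @return data.frame `line_id`, `env`, `rep`, `trait`, `value`,
#'   `is_parent`, with attribute `qtl_truth`: the QTL table augmented with
#'   per-trait residual SDs and realized marginal R2 at plot and line-mean
#'   level.
#' @export
simulate_phenotypes <- function(truth, spec, seed = 1) {
  stopifnot(inherits(truth, "ril_truth"), inherits(spec, "qtl_spec"))
  q <- spec$qtls
  ch <- truth$genome$chromosomes
  bad <- !(q$chrom %in% ch$chrom) |
    q$pos_bp < 1 | q$pos_bp > ch$length_bp[match(q$chrom, ch$chrom)]
  if (any(bad)) stop("QTL positions must lie on simulated chromosomes")
  set.seed(seed)

  lines <- truth$lines
  n <- length(lines)
  envs <- sprintf("E%d", seq_len(spec$n_env))
  traits <- unique(q$trait)
  gm <- spec$grand_mean
  if (is.null(names(gm))) gm <- setNames(rep_len(gm, length(traits)), traits)

  # QTL genotype scores per line (+1/-1/0), truth projection
  xs <- matrix(0, nrow = n, ncol = nrow(q))
  for (j in seq_len(nrow(q))) {
    gj <- vapply(lines, function(l)
      true_genotype_at(truth, l, q$chrom[j], q$pos_bp[j]), character(1))
    xs[, j] <- c(A = 1, H = 0, B = -1)[gj]
  }

  env_shift <- stats::rnorm(spec$n_env, 0, spec$env_effect_sd)
  out <- list()
  qtruth <- q
  qtruth$resid_sd <- NA_real_
  qtruth$r2_plot <- NA_real_
  qtruth$r2_linemean <- NA_real_
  for (tr in traits) {
    jj <- which(q$trait == tr)
    g <- as.vector(xs[, jj, drop = FALSE] %*% q$additive[jj])
    vg <- stats::var(g)
    sd_e <- if (vg > 0 && spec$h2 > 0) {
      if (spec$h2 == 1) 0 else sqrt(vg * (1 - spec$h2) / spec$h2)
    } else spec$null_sd
    E <- spec$n_env; R <- spec$n_reps
    v_plot <- vg + sd_e^2
    v_lm <- vg + sd_e^2 / (E * R)
    qtruth$resid_sd[jj] <- sd_e
    qtruth$r2_plot[jj] <- q$additive[jj]^2 / v_plot
    qtruth$r2_linemean[jj] <- q$additive[jj]^2 / v_lm
    # parents: all-A scores +1, all-B scores -1
    gp <- c(sum(q$additive[jj]), -sum(q$additive[jj]))
    for (e in seq_len(E)) for (r in seq_len(R)) {
      val <- gm[[tr]] + g + env_shift[e] + stats::rnorm(n, 0, sd_e)
      pval <- gm[[tr]] + gp + env_shift[e] + stats::rnorm(2, 0, sd_e)
      out[[length(out) + 1]] <- data.frame(
        line_id = c(lines, "P1", "P2"), env = envs[e], rep = r, trait = tr,
        value = c(val, pval), is_parent = c(rep(FALSE, n), TRUE, TRUE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "qtl_truth") <- qtruth
  res
}
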