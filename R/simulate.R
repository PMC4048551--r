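#' Simulation configuration
#'
#' Conditions for the built-in admixture simulator. Defaults describe a
#' SNP-array-like design over a mid-size genome: 10 chromosomes of 100 cM
#' carrying 300 evenly spaced loci each, donor populations diverged at
#' F = 0.2 (of the order of the taurine-indicine differentiation on
#' ascertained array SNPs), a single admixture pulse contributing
#' m = 0.33 of ancestry B (the introgressed proportion reported for
#' recent hybrid and western-African cattle breeds) g = 25 generations
#' ago, a diploid population of N = 1000 for forward simulation, samples
#' of 50 individuals, and an ascertainment floor of combined minor allele
#' frequency 0.1 (SNP chips target common variants).
#'
#' @param n_loci loci per chromosome.
#' @param n_chrom number of (autosomal) chromosomes.
#' @param chrom_length_cm genetic map length per chromosome, cM.
#' @param F drift/divergence parameter of the Balding-Nichols model, in
#'   (0, 1\].
#' @param m admixture proportion of ancestry B in \[0, 1\].
#' @param g generations since the admixture pulse (>= 1).
#' @param N diploid population size for forward-in-time mode.
#' @param n_sample individuals sampled from the admixed population.
#' @param maf_min combined minor-allele-frequency ascertainment floor.
#' @param cm_per_mb physical-to-genetic scaling for emitted bp positions.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 300, n_chrom = 10, chrom_length_cm = 100,
                       F = 0.2, m = 0.33, g = 25, N = 1000, n_sample = 50,
                       maf_min = 0.1, cm_per_mb = 1, seed = 1) {
  stopifnot(n_loci >= 1, n_chrom >= 1, chrom_length_cm > 0,
            F > 0, F <= 1, m >= 0, m <= 1, g >= 1, N >= 1, n_sample >= 1,
            maf_min >= 0, maf_min < 0.5)
  if (n_sample > N) stop("sim_config: n_sample cannot exceed N")
  structure(list(n_loci = n_loci, n_chrom = n_chrom,
                 chrom_length_cm = chrom_length_cm, F = F, m = m, g = g,
                 N = N, n_sample = n_sample, maf_min = maf_min,
                 cm_per_mb = cm_per_mb, seed = seed),
            class = "sim_config")
}

#' Marker map for a simulation
#'
#' Loci are evenly spaced in genetic distance along each chromosome, with
#' physical positions derived at `cm_per_mb`.
#'
#' @param cfg a [sim_config()].
#' @return a [marker_map()] with `n_chrom * n_loci` markers.
#' @export
sim_marker_map <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chrom), function(ch) {
    cm <- seq(0, cfg$chrom_length_cm, length.out = cfg$n_loci)
    data.frame(chrom = as.character(ch),
               name = sprintf("c%d_m%d", ch, seq_len(cfg$n_loci)),
               pos_bp = round(cm * 1e6 / cfg$cm_per_mb),
               pos_cm = cm, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, maps)
  marker_map(all$chrom, all$name, all$pos_bp, all$pos_cm)
}

#' Simulate two divergent donor panels
#'
#' Per locus, an ancestral frequency p0 ~ Uniform(0.05, 0.95) drifts
#' independently into populations A and B under the Balding-Nichols model
#' with parameter F: population frequencies are Beta(p0 (1-F)/F,
#' (1-p0)(1-F)/F) (at F = 1 each population is fixed for an allele drawn
#' with probability p0). Haplotype alleles are sampled independently per
#' locus from the population frequency. Loci whose combined sample minor
#' allele frequency falls below `maf_min` are redrawn, mimicking SNP-chip
#' ascertainment toward common variants; panels therefore carry no
#' within-population linkage disequilibrium.
#'
#' @param cfg a [sim_config()].
#' @param n_A,n_B haplotypes per panel (each panel's individuals are
#'   `A<k>`/`B<k>` with two haplotypes each; odd counts leave a trailing
#'   single haplotype).
#' @param map optional [marker_map()] (defaults to [sim_marker_map()]).
#' @param max_redraws redraw rounds before giving up on ascertainment.
#' @return list with `panels` (a [donor_panels()]), `freqs` (data.frame
#'   `p0`, `freq_A`, `freq_B` per marker) and `map`.
#' @export
sim_divergent_panels <- function(cfg, n_A = 50, n_B = 50, map = NULL,
                                 max_redraws = 1000) {
  set.seed(cfg$seed)
  if (is.null(map)) map <- sim_marker_map(cfg)
  L <- nrow(map)
  pA <- pB <- p0 <- numeric(L)
  hapA <- matrix(NA_integer_, n_A, L)
  hapB <- matrix(NA_integer_, n_B, L)
  todo <- seq_len(L)
  for (round in seq_len(max_redraws)) {
    k <- length(todo)
    if (!k) break
    q0 <- stats::runif(k, 0.05, 0.95)
    if (cfg$F >= 1) {
      qA <- as.numeric(stats::runif(k) < q0)
      qB <- as.numeric(stats::runif(k) < q0)
    } else {
      s <- (1 - cfg$F) / cfg$F
      qA <- stats::rbeta(k, q0 * s, (1 - q0) * s)
      qB <- stats::rbeta(k, q0 * s, (1 - q0) * s)
    }
    hA <- matrix(stats::rbinom(n_A * k, 1, rep(qA, each = n_A)), n_A, k)
    hB <- matrix(stats::rbinom(n_B * k, 1, rep(qB, each = n_B)), n_B, k)
    f <- (colSums(hA) + colSums(hB)) / (n_A + n_B)
    ok <- pmin(f, 1 - f) >= cfg$maf_min
    keep <- todo[ok]
    p0[keep] <- q0[ok]; pA[keep] <- qA[ok]; pB[keep] <- qB[ok]
    hapA[, keep] <- hA[, ok, drop = FALSE]
    hapB[, keep] <- hB[, ok, drop = FALSE]
    todo <- todo[!ok]
  }
  if (length(todo)) {
    stop("sim_divergent_panels: could not satisfy maf_min = ", cfg$maf_min,
         " for ", length(todo), " loci after ", max_redraws, " redraws")
  }
  ids_A <- hap_ids("A", n_A)
  ids_B <- hap_ids("B", n_B)
  panels <- donor_panels(
    haplotype_panel(hapA, ids_A, rep("panelA", n_A), map),
    haplotype_panel(hapB, ids_B, rep("panelB", n_B), map))
  list(panels = panels,
       freqs = data.frame(p0 = p0, freq_A = pA, freq_B = pB),
       map = map)
}

hap_ids <- function(prefix, n) {
  sprintf("%s%d_%d", prefix, (seq_len(n) + 1) %/% 2, (seq_len(n) + 1) %% 2)
}

# ---- tract machinery ---------------------------------------------------
# A haplotype-chromosome's ancestry is a step function stored as
# list(bk = interior breakpoints (cM, ascending), lab = labels per tract,
# length(bk) + 1 of them; labels 1 = A, 2 = B).

merge_tracts <- function(bk, lab) {
  if (length(lab) > 1) {
    same <- lab[-1] == lab[-length(lab)]
    if (any(same)) {
      bk <- bk[!same]
      lab <- lab[c(TRUE, !same)]
    }
  }
  list(bk = bk, lab = lab)
}

# Label at positions x (cM) of tract list h.
tract_label_at <- function(h, x) {
  h$lab[findInterval(x, h$bk) + 1]
}

# Recombine two parental haplotypes into a gamete over [0, L] cM.
recombine <- function(h1, h2, L) {
  n_x <- stats::rpois(1, L / 100)
  src <- if (stats::runif(1) < 0.5) list(h1, h2) else list(h2, h1)
  if (n_x == 0) return(src[[1]])
  cuts <- sort(stats::runif(n_x, 0, L))
  bounds <- c(0, cuts, L)
  bk <- numeric(0); lab <- integer(0)
  for (s in seq_len(n_x + 1)) {
    h <- src[[(s - 1) %% 2 + 1]]
    a <- bounds[s]; b <- bounds[s + 1]
    inner <- h$bk[h$bk > a & h$bk < b]
    labs <- tract_label_at(h, c(a, inner))
    bk <- c(bk, inner, b)
    lab <- c(lab, labs)
  }
  merge_tracts(bk[-length(bk)], lab)
}

#' Simulate an admixed cohort by forward Wright-Fisher
#'
#' Generation 0 holds N founder individuals, each a migrant from
#' population B with probability m (the admixture pulse), carrying two
#' single-tract haplotypes of its ancestry. Each
#' subsequent generation, every offspring draws two parents uniformly at
#' random and receives from each a gamete formed with
#' Poisson(length in Morgans) crossovers at uniform genetic positions.
#' After g generations, `n_sample` individuals are sampled and alleles
#' are emitted per marker from the tract-ancestry population frequency.
#' Drift is real in this mode: tracts may fix or be lost.
#'
#' @param cfg a [sim_config()].
#' @param freqs,map frequency table and map from
#'   [sim_divergent_panels()].
#' @return list with `panel` (a [haplotype_panel()] of 2 x n_sample
#'   haplotypes), `truth` (see [sim_truth()]) and `map`.
#' @export
sim_admixed_forward <- function(cfg, freqs, map) {
  set.seed(cfg$seed + 1L)
  L <- cfg$chrom_length_cm
  n_hap <- 2L * cfg$N
  founder_lab <- rep(ifelse(stats::runif(cfg$N) < cfg$m, 2L, 1L), each = 2)
  # pop[[chrom]][[hap]] ; haplotypes 2i-1, 2i belong to individual i
  pop <- lapply(seq_len(cfg$n_chrom), function(ch) {
    lapply(founder_lab, function(l) list(bk = numeric(0), lab = l))
  })
  for (gen in seq_len(cfg$g)) {
    mothers <- sample.int(cfg$N, cfg$N, replace = TRUE)
    fathers <- sample.int(cfg$N, cfg$N, replace = TRUE)
    pop <- lapply(pop, function(chrom_haps) {
      nxt <- vector("list", n_hap)
      for (i in seq_len(cfg$N)) {
        mo <- mothers[i]; fa <- fathers[i]
        nxt[[2L * i - 1L]] <- recombine(chrom_haps[[2L * mo - 1L]],
                                        chrom_haps[[2L * mo]], L)
        nxt[[2L * i]] <- recombine(chrom_haps[[2L * fa - 1L]],
                                   chrom_haps[[2L * fa]], L)
      }
      nxt
    })
  }
  take_ind <- sample.int(cfg$N, cfg$n_sample)
  take_hap <- as.vector(rbind(2L * take_ind - 1L, 2L * take_ind))
  tracts <- lapply(pop, function(chrom_haps) chrom_haps[take_hap])
  emit_cohort(cfg, freqs, map, tracts)
}

#' Simulate an admixed cohort by the pulse (Markovian) approximation
#'
#' For each haplotype-chromosome, tract breakpoints form a Poisson process
#' of rate g per Morgan and tract labels are i.i.d. B with probability m.
#' This is the large-N approximation to [sim_admixed_forward()] (valid
#' for g much smaller than N): it ignores drift in the admixture
#' proportion and correlations between haplotypes, in exchange for cost
#' independent of N and g.
#'
#' @inheritParams sim_admixed_forward
#' @return list with `panel`, `truth` and `map` (as in
#'   [sim_admixed_forward()]).
#' @export
sim_admixed_pulse <- function(cfg, freqs, map) {
  set.seed(cfg$seed + 1L)
  L <- cfg$chrom_length_cm
  n_hap <- 2L * cfg$n_sample
  n_bk_rec <- matrix(0L, n_hap, cfg$n_chrom)
  tracts <- lapply(seq_len(cfg$n_chrom), function(ch) {
    lapply(seq_len(n_hap), function(h) {
      n_bk <- stats::rpois(1, cfg$g * L / 100)
      n_bk_rec[h, ch] <<- n_bk
      bk <- sort(stats::runif(n_bk, 0, L))
      lab <- ifelse(stats::runif(n_bk + 1) < cfg$m, 2L, 1L)
      merge_tracts(bk, lab)
    })
  })
  out <- emit_cohort(cfg, freqs, map, tracts)
  # raw crossover counts per haplotype-chromosome (before merging tracts
  # of equal ancestry), for breakpoint-process diagnostics
  out$truth$n_breakpoints <- n_bk_rec
  out
}

# Shared back end: emit alleles and truth from per-chromosome tract lists.
emit_cohort <- function(cfg, freqs, map, tracts) {
  stopifnot(nrow(freqs) == nrow(map))
  n_hap <- length(tracts[[1]])
  ids <- sprintf("s%d_%d", rep(seq_len(n_hap %/% 2), each = 2), 0:1)
  alleles <- matrix(NA_integer_, n_hap, nrow(map))
  lab_mat <- matrix(1L, n_hap, nrow(map))
  tract_rows <- list()
  idx_by_chrom <- map_chrom_index(map)
  for (ch in seq_along(idx_by_chrom)) {
    idx <- idx_by_chrom[[ch]]
    mk_cm <- map$pos_cm[idx]
    for (h in seq_len(n_hap)) {
      tr <- tracts[[ch]][[h]]
      lab <- tract_label_at(tr, mk_cm)
      lab_mat[h, idx] <- lab
      f <- ifelse(lab == 1L, freqs$freq_A[idx], freqs$freq_B[idx])
      alleles[h, idx] <- stats::rbinom(length(idx), 1, f)
      bounds_cm <- c(0, tr$bk, cfg$chrom_length_cm)
      tract_rows[[length(tract_rows) + 1]] <- data.frame(
        haplotype_id = ids[h], chrom = map$chrom[idx[1]],
        start_bp = round(utils::head(bounds_cm, -1) * 1e6 / cfg$cm_per_mb),
        end_bp = round(utils::tail(bounds_cm, -1) * 1e6 / cfg$cm_per_mb),
        label = c("A", "B")[tr$lab], stringsAsFactors = FALSE)
    }
  }
  panel <- haplotype_panel(alleles, ids, rep("admixed", n_hap), map)
  truth <- sim_truth(lab_mat, ids, map, do.call(rbind, tract_rows))
  list(panel = panel, truth = truth, map = map)
}

#' Ground-truth container for simulated cohorts
#'
#' @param labels integer matrix haplotypes x markers, 1 = ancestry A,
#'   2 = ancestry B.
#' @param haplotype_ids haplotype identifiers.
#' @param map the [marker_map()].
#' @param tracts data.frame of true tract intervals (bp, 0-based
#'   half-open) per haplotype-chromosome.
#' @return a `sim_truth` list; `$painting` is the exact (0/1)
#'   [ancestry_painting()] implied by the true labels.
#' @export
sim_truth <- function(labels, haplotype_ids, map, tracts) {
  painting <- ancestry_painting((labels == 1L) * 1, haplotype_ids, map)
  structure(list(labels = labels, painting = painting, tracts = tracts),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d haplotypes x %d markers, %.1f%% ancestry B\n",
              nrow(x$labels), ncol(x$labels), 100 * mean(x$labels == 2L)))
  invisible(x)
}

#' Hudson-type Fst between the two donor panels
#'
#' Ratio-of-averages Hudson estimator from panel allele counts; used to
#' check that simulated divergence matches the requested F.
#'
#' @param panels a [donor_panels()].
#' @return scalar Fst estimate.
#' @export
panel_fst <- function(panels) {
  a <- panels$panel_A$alleles
  b <- panels$panel_B$alleles
  n1 <- nrow(a); n2 <- nrow(b)
  p1 <- colMeans(a); p2 <- colMeans(b)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
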