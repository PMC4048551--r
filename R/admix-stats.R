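#' Per-chromosome ancestry proportions
#'
#' For each individual and chromosome, the proportion of panel-A ancestry
#' computed from labelled block lengths: A bp / (A bp + B bp) per
#' haplotype, averaged over the individual's two haplotypes. Uncertain
#' intervals count in neither term. A haplotype-chromosome with no
#' labelled length yields `NA`.
#'
#' @param blocks a [block_set()] for a cohort, or an
#'   [ancestry_painting()] (thresholded via [call_blocks()] first).
#' @param groups optional named character vector mapping individual ids to
#'   group labels, attached to the result.
#' @param threshold block-calling threshold used when `blocks` is a
#'   painting.
#' @return a `chrom_ancestry` matrix individuals x chromosomes with the
#'   group labels in attribute `groups`.
#' @export
chromosome_ancestry_proportions <- function(blocks, groups = NULL,
                                            threshold = 0.75) {
  if (inherits(blocks, "ancestry_painting")) {
    blocks <- call_blocks(blocks, threshold = threshold)
  }
  stopifnot(inherits(blocks, "block_set"))
  ind <- hap_individual(blocks$haplotype_id)
  inds <- unique(ind)
  chroms <- unique(blocks$chrom)
  chroms <- chroms[order(chrom_rank(chroms))]
  len <- blocks$end_bp - blocks$start_bp
  m <- matrix(NA_real_, length(inds), length(chroms),
              dimnames = list(inds, chroms))
  for (i in seq_along(inds)) {
    sel <- ind == inds[i]
    for (j in seq_along(chroms)) {
      s <- sel & blocks$chrom == chroms[j]
      if (!any(s)) next
      hap_ratio <- vapply(unique(blocks$haplotype_id[s]), function(h) {
        hs <- s & blocks$haplotype_id == h
        a <- sum(len[hs & blocks$label == "A"])
        b <- sum(len[hs & blocks$label == "B"])
        if (a + b == 0) NA_real_ else a / (a + b)
      }, numeric(1))
      m[i, j] <- mean(hap_ratio)   # NA propagates: unlabelled haplotype
    }
  }
  structure(m, groups = groups, class = c("chrom_ancestry", "matrix"))
}

#' Bonferroni-corrected alpha for the chromosome-ancestry tests
#'
#' Splits a two-tailed familywise level into its one-tail half and divides
#' by the number of tests (chromosomes x groups). Also reports the value
#' rounded to one significant figure, the form used for display.
#'
#' @param familywise_two_tailed familywise two-tailed level (default 0.05).
#' @param n_chromosomes number of chromosomes tested (default 30: 29
#'   autosomes plus X).
#' @param n_groups number of groups tested (default 4).
#' @return list with `alpha` (exact) and `alpha_display` (1 significant
#'   figure).
#' @export
bonferroni_alpha <- function(familywise_two_tailed = 0.05,
                             n_chromosomes = 30, n_groups = 4) {
  stopifnot(familywise_two_tailed > 0, n_chromosomes >= 1, n_groups >= 1)
  a <- (familywise_two_tailed / 2) / (n_chromosomes * n_groups)
  list(alpha = a, alpha_display = signif(a, 1),
       n_tests = as.integer(n_chromosomes * n_groups))
}

#' Bootstrap test for chromosome-level ancestry deviations
#'
#' Under uniform admixture across chromosomes, any chromosome's across-
#' individual median ancestry should look like the median of n values
#' drawn from the group's pooled ancestry distribution. The pool collects
#' every (individual, chromosome) proportion in the group; each bootstrap
#' replicate draws n values (n = group size) with replacement and records
#' their median. A chromosome is significant when its observed median
#' falls below the alpha/2 or above the 1 - alpha/2 empirical quantile of
#' the replicate medians. The attained p is reported as the bound
#' (c + 1) / n_reps, where c counts replicates at least as extreme in the
#' nearer tail, so the resolution is 1/n_reps.
#'
#' @param m a `chrom_ancestry` matrix (see
#'   [chromosome_ancestry_proportions()]) restricted to, or subset by,
#'   one group.
#' @param group optional group label: rows whose `groups` attribute entry
#'   matches are used. Omit to use all rows.
#' @param n_reps bootstrap replicates (default 50000).
#' @param alpha corrected two-tailed level (default 0.0002; see
#'   [bonferroni_alpha()]).
#' @param seed integer seed for the replicate draws.
#' @return a `bootstrap_median_test` list: per-chromosome data.frame
#'   (`chrom`, `observed_median`, `range_lo`, `range_hi`, `p_bound`,
#'   `significant`, `direction`) plus `lower_cutoff`, `upper_cutoff`,
#'   `pool_median`, `alpha`, `n_reps`, `seed`.
#' @export
bootstrap_median_test <- function(m, group = NULL, n_reps = 50000,
                                  alpha = 0.0002, seed = 1) {
  m <- subset_group(m, group)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("bootstrap_median_test: need >= 2 individuals and >= 2 chromosomes")
  }
  if (anyNA(m)) stop("bootstrap_median_test: missing ancestry entries")
  if (n_reps < 1 / alpha) {
    stop("bootstrap_median_test: n_reps = ", n_reps,
         " cannot resolve quantiles at alpha = ", alpha,
         " (need >= ", ceiling(1 / alpha), ")")
  }
  pool <- sort(as.vector(m))   # canonical order: replicate draws depend
  n <- nrow(m)                 # only on the pooled multiset and the seed
  set.seed(seed)
  draws <- matrix(sample(pool, n * n_reps, replace = TRUE), nrow = n)
  meds <- apply(draws, 2, stats::median)
  cuts <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), type = 1,
                          names = FALSE)
  obs <- apply(m, 2, stats::median)
  c_low <- vapply(obs, function(o) sum(meds <= o), numeric(1))
  c_high <- vapply(obs, function(o) sum(meds >= o), numeric(1))
  nearer <- pmin(c_low, c_high)
  per_chrom <- data.frame(
    chrom = colnames(m), observed_median = unname(obs),
    range_lo = apply(m, 2, min), range_hi = apply(m, 2, max),
    p_bound = (nearer + 1) / n_reps,
    significant = obs < cuts[1] | obs > cuts[2],
    direction = ifelse(obs < cuts[1], "low",
                       ifelse(obs > cuts[2], "high", "-")),
    stringsAsFactors = FALSE)
  rownames(per_chrom) <- NULL
  structure(list(per_chrom = per_chrom, lower_cutoff = cuts[1],
                 upper_cutoff = cuts[2],
                 pool_median = stats::median(pool),
                 pool_range = range(pool), alpha = alpha,
                 n_reps = n_reps, seed = seed),
            class = "bootstrap_median_test")
}

#' @export
print.bootstrap_median_test <- function(x, ...) {
  cat(sprintf(
    "bootstrap_median_test: %d chromosomes, %d reps, alpha = %g\n",
    nrow(x$per_chrom), x$n_reps, x$alpha))
  cat(sprintf("  pool median %.3f, cutoffs [%.3f, %.3f]\n",
              x$pool_median, x$lower_cutoff, x$upper_cutoff))
  sig <- x$per_chrom[x$per_chrom$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant chromosomes:\n")
    print(sig, row.names = FALSE)
  } else cat("  no significant chromosome\n")
  invisible(x)
}

subset_group <- function(m, group) {
  if (is.null(group)) return(m)
  g <- attr(m, "groups")
  if (is.null(g)) stop("no group labels attached to ancestry matrix")
  keep <- rownames(m) %in% names(g)[g == group]
  if (!any(keep)) stop("no individuals in group ", group)
  m[keep, , drop = FALSE]
}

#' Permutation ANOVA for variability of ancestry across chromosomes
#'
#' Tests whether the spread of ancestry proportions differs among
#' chromosomes. Deviations d\[i, c\] = |value\[i, c\] - group median of
#' chromosome c| are compared across chromosomes by a one-way ANOVA F
#' (chromosomes as groups); because the deviations are not normal, the
#' null distribution of F is generated by permuting chromosome labels over
#' the pooled deviations. p = (#\{F_perm >= F_obs\} + 1) / (n_reps + 1).
#'
#' @inheritParams bootstrap_median_test
#' @param n_reps permutation replicates (default 5000).
#' @return list with `F_observed`, `p`, `n_reps`, `seed`.
#' @export
permutation_variability_test <- function(m, group = NULL, n_reps = 5000,
                                         seed = 1) {
  m <- subset_group(m, group)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("permutation_variability_test: need >= 2 individuals and >= 2 chromosomes")
  }
  med <- apply(m, 2, stats::median)
  d <- abs(sweep(m, 2, med))
  lab <- rep(seq_len(ncol(d)), each = nrow(d))
  pooled <- as.vector(d)
  if (all(pooled == pooled[1])) {
    warning("permutation_variability_test: zero variance in deviations")
    return(list(F_observed = 0, p = 1, n_reps = n_reps, seed = seed))
  }
  f_obs <- oneway_f(pooled, lab)
  set.seed(seed)
  f_perm <- replicate(n_reps, oneway_f(pooled[sample.int(length(pooled))],
                                       lab))
  p <- (sum(f_perm >= f_obs) + 1) / (n_reps + 1)
  list(F_observed = f_obs, p = p, n_reps = n_reps, seed = seed)
}

# One-way ANOVA F from sums of squares; Inf when within-group variance is
# zero but between-group variance is not (aov would return NaN there).
oneway_f <- function(x, g) {
  gm <- mean(x)
  means <- tapply(x, g, mean)
  counts <- tapply(x, g, length)
  ss_b <- sum(counts * (means - gm)^2)
  ss_w <- sum((x - means[as.character(g)])^2)
  df_b <- length(means) - 1
  df_w <- length(x) - length(means)
  if (ss_w == 0) {
    if (ss_b == 0) return(0)
    return(Inf)
  }
  (ss_b / df_b) / (ss_w / df_w)
}

#' Correlation and one-way ANOVA summaries
#'
#' Standard companions to the resampling tests: the Pearson correlation
#' between two per-individual quantities (e.g. admixture proportion vs
#' SBS) with its two-tailed t-approximation p, and a one-way ANOVA
#' comparing a quantity across groups.
#'
#' @param x,y equal-length numeric vectors (>= 3 points) for the
#'   correlation; `NULL` to skip.
#' @param groups named list of numeric vectors (>= 2 groups of >= 2) for
#'   the ANOVA; `NULL` to skip.
#' @return list with `r`, `r_p`, `F`, `F_p` (NA where skipped).
#' @export
summary_stats <- function(x = NULL, y = NULL, groups = NULL) {
  r <- r_p <- f <- f_p <- NA_real_
  if (!is.null(x)) {
    if (length(x) != length(y) || length(x) < 3) {
      stop("summary_stats: x and y must have equal length >= 3")
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      stop("summary_stats: zero variance, correlation undefined")
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  if (!is.null(groups)) {
    if (length(groups) < 2 || any(lengths(groups) < 2)) {
      stop("summary_stats: need >= 2 groups with >= 2 members each")
    }
    vals <- unlist(groups, use.names = FALSE)
    lab <- factor(rep(seq_along(groups), lengths(groups)))
    if (all(tapply(vals, lab, stats::var) == 0) &&
        length(unique(tapply(vals, lab, mean))) == 1) {
      f <- 0; f_p <- 1
    } else {
      ow <- stats::oneway.test(vals ~ lab, var.equal = TRUE)
      f <- unname(ow$statistic); f_p <- ow$p.value
    }
  }
  list(r = r, r_p = r_p, F = f, F_p = f_p)
}
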