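# Shared fixtures and independent oracles, built in code at test time.

# --- toy PLINK text pair -------------------------------------------------
write_toy_ped_map <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  map <- c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300")
  ped <- c("breedX ind1 0 0 0 -9 A A A G G G",
           "breedY ind2 0 0 0 -9 A G 0 0 A G")
  writeLines(map, file.path(dir, "toy.map"))
  writeLines(ped, file.path(dir, "toy.ped"))
  list(ped = file.path(dir, "toy.ped"), map = file.path(dir, "toy.map"))
}

# --- small haplotype TSV -------------------------------------------------
write_toy_hap_tsv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  lines <- c(paste(c("haplotype_id", "breed", paste0("m", 1:5)),
                   collapse = "\t"),
             paste(c("s1_0", "bA", 1, 0, 1, 1, 0), collapse = "\t"),
             paste(c("s1_1", "bA", 0, 0, ".", 1, 1), collapse = "\t"),
             paste(c("s2_0", "bB", 1, 1, 1, 0, 0), collapse = "\t"),
             paste(c("s2_1", "bB", 0, 1, 0, 0, 1), collapse = "\t"))
  mp <- sprintf("1\tm%d\t0\t%d", 1:5, (1:5) * 1000)
  writeLines(lines, file.path(dir, "haps.tsv"))
  writeLines(mp, file.path(dir, "haps.map"))
  list(tsv = file.path(dir, "haps.tsv"), map = file.path(dir, "haps.map"))
}

# genotype_table built directly from a calls matrix
make_gt <- function(calls, breed = rep("b1", nrow(calls)),
                    chrom = rep("1", ncol(calls)),
                    pos = seq_len(ncol(calls)) * 100) {
  map <- marker_map(chrom, paste0("m", seq_len(ncol(calls))), pos)
  genotype_table(calls, paste0("i", seq_len(nrow(calls))), breed, map)
}

# single-row painting over one chromosome with given positions (bp)
make_painting <- function(prob, pos, ids = "s1_0", chrom = "1") {
  prob <- rbind(prob)
  map <- marker_map(rep(chrom, length(pos)),
                    paste0(chrom, "_m", seq_along(pos)), pos)
  ancestry_painting(prob, ids, map)
}

# --- exhaustive path-enumeration oracle for the copying HMM --------------
# Sums the joint probability over every donor-path sequence; independent
# of the forward-backward implementation.
enum_panel_posterior <- function(target, donors_A, donors_B, cm, eps, rho) {
  donors <- rbind(donors_A, donors_B)
  K <- nrow(donors)
  nA <- nrow(donors_A)
  L <- length(target)
  pi0 <- c(rep(0.5 / nA, nA), rep(0.5 / (K - nA), K - nA))
  emit <- function(j, t) {
    if (is.na(target[t]) || is.na(donors[j, t])) return(1)
    if (donors[j, t] == target[t]) 1 - eps else eps
  }
  q <- 1 - exp(-rho * diff(cm))
  trans <- function(i, j, t) (if (i == j) (1 - q[t]) else 0) + q[t] / K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  w <- apply(paths, 1, function(s) {
    p <- pi0[s[1]] * emit(s[1], 1)
    for (t in 2:L) p <- p * trans(s[t - 1], s[t], t - 1) * emit(s[t], t)
    p
  })
  post_A <- vapply(seq_len(L), function(t) {
    sum(w[paths[, t] <= nA]) / sum(w)
  }, numeric(1))
  post_A
}

# empirical fraction of bootstrap replicate medians equal to `value`,
# regenerated with the scheme bootstrap_median_test uses (sorted pool)
replicate_medians_equal <- function(m, n_reps, seed, value) {
  pool <- sort(as.vector(m))
  set.seed(seed)
  meds <- apply(matrix(sample(pool, nrow(m) * n_reps, replace = TRUE),
                       nrow = nrow(m)), 2, stats::median)
  meds == value
}

# --- exact bootstrap-median distribution on a two-valued pool ------------
# P(median of n draws = each possible value), by binomial enumeration.
exact_median_dist_2val <- function(v1, v2, p1, n) {
  stopifnot(v1 < v2)
  k <- 0:n
  pk <- stats::dbinom(k, n, p1)    # draws equal to v1
  if (n %% 2 == 1) {
    need <- (n + 1) / 2
    c(v1 = sum(pk[k >= need]), mid = 0, v2 = sum(pk[k < need]))
  } else {
    lo <- n / 2 + 1
    c(v1 = sum(pk[k >= lo]), mid = pk[k == n / 2 + 0],
      v2 = sum(pk[k <= n / 2 - 1]))
  }
}
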