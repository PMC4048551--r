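anc_matrix <- function(m, groups = NULL) {
  structure(m, groups = groups, class = c("chrom_ancestry", "matrix"))
}

test_that("per-chromosome ancestry proportions come from labelled bp", {
  # hap1 A:[0,60)/B:[60,100), hap2 fully A -> (0.6 + 1.0)/2 = 0.8
  rows <- rbind(
    data.frame(haplotype_id = "s1_0", chrom = "1", start_bp = c(0, 60),
               end_bp = c(60, 100), label = c("A", "B")),
    data.frame(haplotype_id = "s1_1", chrom = "1", start_bp = 0,
               end_bp = 100, label = "A"),
    # saturation and symmetry cases on chromosome 2
    data.frame(haplotype_id = "s1_0", chrom = "2", start_bp = 0,
               end_bp = 50, label = "A"),
    data.frame(haplotype_id = "s1_1", chrom = "2", start_bp = 0,
               end_bp = 50, label = "B"))
  m <- chromosome_ancestry_proportions(block_set(rows))
  expect_equal(unname(m["s1", "1"]), 0.8)
  expect_equal(unname(m["s1", "2"]), 0.5)
  # uncertain bp excluded: fully-A haplotype with uncertain tail
  rows2 <- rbind(
    data.frame(haplotype_id = "s2_0", chrom = "1", start_bp = c(0, 80),
               end_bp = c(80, 100), label = c("A", "uncertain")),
    data.frame(haplotype_id = "s2_1", chrom = "1", start_bp = 0,
               end_bp = 100, label = "A"))
  m2 <- chromosome_ancestry_proportions(block_set(rows2))
  expect_equal(unname(m2["s2", "1"]), 1.0)
})

test_that("Bonferroni correction halves the level and divides by tests", {
  b <- bonferroni_alpha()
  expect_equal(b$alpha, 0.025 / 120)
  expect_equal(b$alpha_display, 0.0002)
  expect_equal(b$n_tests, 120)
  expect_equal(bonferroni_alpha(0.05, 1, 1)$alpha, 0.025)
  expect_equal(bonferroni_alpha(0.05, 10, 1)$alpha, 0.0025)
})

test_that("bootstrap cutoffs match exact enumeration on a 2-valued pool", {
  # 3 individuals x 2 chromosomes: values 0.2 (x3) and 0.8 (x3)
  m <- anc_matrix(matrix(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), 3, 2,
                         dimnames = list(paste0("i", 1:3), c("1", "2"))))
  n_reps <- 20000
  bt <- bootstrap_median_test(m, n_reps = n_reps, alpha = 0.05, seed = 4)
  # exact: median of 3 draws = 0.2 with prob 0.5 -> neither tail reaches
  # 0.025, so neither observed median (0.2 or 0.8) is significant
  expect_false(any(bt$per_chrom$significant))
  ex <- exact_median_dist_2val(0.2, 0.8, 0.5, 3)
  emp_low <- mean(replicate_medians_equal(m, n_reps, 4, 0.2))
  expect_lt(abs(emp_low - ex[["v1"]]), 3 / sqrt(n_reps))
  # p bound for each observed median is about 0.5, far from alpha
  expect_true(all(bt$per_chrom$p_bound > 0.4))
})

test_that("a constant pool flags nothing", {
  m <- anc_matrix(matrix(0.4, 5, 3, dimnames = list(paste0("i", 1:5),
                                                    c("1", "2", "3"))))
  bt <- bootstrap_median_test(m, n_reps = 1000, alpha = 0.01, seed = 1)
  expect_false(any(bt$per_chrom$significant))
  expect_equal(bt$lower_cutoff, 0.4)
  expect_equal(bt$upper_cutoff, 0.4)
})

test_that("bootstrap test is reproducible and individual-order invariant", {
  set.seed(10)
  m <- anc_matrix(matrix(runif(8 * 5), 8, 5,
                         dimnames = list(paste0("i", 1:8), paste0("c", 1:5))))
  b1 <- bootstrap_median_test(m, n_reps = 2000, alpha = 0.05, seed = 7)
  b2 <- bootstrap_median_test(m, n_reps = 2000, alpha = 0.05, seed = 7)
  expect_identical(b1, b2)
  mp <- m[sample(nrow(m)), , drop = FALSE]
  b3 <- bootstrap_median_test(anc_matrix(mp), n_reps = 2000, alpha = 0.05,
                              seed = 7)
  expect_equal(b3$per_chrom, b1$per_chrom)
})

test_that("bootstrap test rejects unresolvable alpha and p >= 1/n_reps", {
  m <- anc_matrix(matrix(runif(20), 4, 5,
                         dimnames = list(paste0("i", 1:4), paste0("c", 1:5))))
  expect_error(bootstrap_median_test(m, n_reps = 100, alpha = 0.0002),
               "resolve")
  bt <- bootstrap_median_test(m, n_reps = 5000, alpha = 0.05, seed = 2)
  expect_true(all(bt$per_chrom$p_bound >= 1 / 5000))
})

test_that("permutation ANOVA p matches complete enumeration on {0,0}/{1,1}", {
  m <- anc_matrix(matrix(c(0.5, 0.5, 0.0, 1.0), 2, 2,
                         dimnames = list(c("i1", "i2"), c("1", "2"))))
  # deviations: chrom1 {0,0}, chrom2 {0.5,0.5}: permuting the 4 pooled
  # deviations over two pairs keeps F infinite in 2 of the 6 distinct
  # assignments -> p = 1/3
  r <- permutation_variability_test(m, n_reps = 6000, seed = 3)
  expect_equal(r$F_observed, Inf)
  expect_equal(r$p, 1 / 3, tolerance = 0.05)
})

test_that("identical deviation multisets give F = 0 and p = 1", {
  m <- anc_matrix(matrix(c(0.2, 0.8, 0.2, 0.8), 2, 2,
                         dimnames = list(c("i1", "i2"), c("1", "2"))))
  r <- permutation_variability_test(m, n_reps = 200, seed = 1)
  expect_equal(r$F_observed, 0)
  expect_equal(r$p, 1)
})

test_that("permutation p is invariant under a common additive shift", {
  set.seed(8)
  base <- matrix(runif(6 * 4), 6, 4,
                 dimnames = list(paste0("i", 1:6), paste0("c", 1:4)))
  r1 <- permutation_variability_test(anc_matrix(base), n_reps = 500,
                                     seed = 9)
  r2 <- permutation_variability_test(anc_matrix(base + 0.17), n_reps = 500,
                                     seed = 9)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$F_observed, r2$F_observed)
})

test_that("permutation ANOVA holds its size under an exchangeable null", {
  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- anc_matrix(matrix(runif(10 * 6), 10, 6,
                           dimnames = list(paste0("i", 1:10),
                                           paste0("c", 1:6))))
    permutation_variability_test(m, n_reps = 400, seed = s)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("the internal F statistic agrees with oneway.test", {
  set.seed(12)
  x <- rnorm(30)
  g <- rep(1:3, each = 10)
  f_hand <- blockclock:::oneway_f(x, g)
  f_ref <- unname(oneway.test(x ~ factor(g), var.equal = TRUE)$statistic)
  expect_equal(f_hand, f_ref, tolerance = 1e-12)
})

test_that("summary statistics reproduce hand-computed values", {
  s <- summary_stats(x = 1:5, y = 2 * (1:5) + 1)
  expect_equal(s$r, 1)
  s2 <- summary_stats(x = c(1, 2, 3), y = c(2, 1, 3))
  expect_equal(s2$r, 0.5)
  g <- summary_stats(groups = list(a = c(1, 2), b = c(1, 2)))
  expect_equal(g$F, 0)
  expect_error(summary_stats(x = c(1, 1, 1), y = 1:3), "variance")
})
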