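test_that("divergence of simulated panels tracks the drift parameter F", {
  # near-zero drift: panels nearly identical
  cfg0 <- sim_config(n_loci = 2000, n_chrom = 1, F = 1e-4, seed = 2)
  d0 <- sim_divergent_panels(cfg0, 100, 100)
  expect_lt(panel_fst(d0$panels), 0.01)
  # full drift: every locus fixed within each population
  cfg1 <- sim_config(n_loci = 200, n_chrom = 1, F = 1, seed = 2)
  d1 <- sim_divergent_panels(cfg1, 20, 20)
  expect_true(all(colMeans(d1$panels$panel_A$alleles) %in% c(0, 1)))
  expect_true(all(colMeans(d1$panels$panel_B$alleles) %in% c(0, 1)))
  # intermediate drift: Hudson Fst near F across seeds
  fst <- vapply(1:3, function(s) {
    cfg <- sim_config(n_loci = 3000, n_chrom = 1, F = 0.2, seed = s)
    panel_fst(sim_divergent_panels(cfg, 100, 100)$panels)
  }, numeric(1))
  expect_true(all(fst > 0.15 & fst < 0.25))
})

test_that("ascertainment keeps the combined minor allele frequency up", {
  cfg <- sim_config(n_loci = 500, n_chrom = 1, F = 0.3, maf_min = 0.2,
                    seed = 6)
  d <- sim_divergent_panels(cfg, 40, 40)
  f <- (colSums(d$panels$panel_A$alleles) +
        colSums(d$panels$panel_B$alleles)) / 80
  expect_true(all(pmin(f, 1 - f) >= 0.2))
  # an unsatisfiable floor errors out
  cfg_bad <- sim_config(n_loci = 10, n_chrom = 1, F = 1, maf_min = 0.49,
                        seed = 1)
  expect_error(sim_divergent_panels(cfg_bad, 2, 2, max_redraws = 5),
               "maf_min")
})

test_that("pulse mode: degenerate proportions and breakpoint process", {
  cfg_m1 <- sim_config(n_loci = 20, n_chrom = 2, m = 1, g = 5,
                       n_sample = 5, seed = 3)
  d <- sim_divergent_panels(cfg_m1, 10, 10)
  a1 <- sim_admixed_pulse(cfg_m1, d$freqs, d$map)
  expect_true(all(a1$truth$labels == 2L))
  cfg_m0 <- sim_config(n_loci = 20, n_chrom = 2, m = 0, g = 5,
                       n_sample = 5, seed = 3)
  a0 <- sim_admixed_pulse(cfg_m0, d$freqs, d$map)
  expect_true(all(a0$truth$labels == 1L))

  # g = 1 on a 1 Morgan chromosome: zero-crossover fraction ~ e^(-1)
  cfg_g1 <- sim_config(n_loci = 2, n_chrom = 1, chrom_length_cm = 100,
                       g = 1, n_sample = 5000, N = 5000, seed = 4)
  dg <- sim_divergent_panels(cfg_g1, 4, 4)
  ag <- sim_admixed_pulse(cfg_g1, dg$freqs, dg$map)
  expect_equal(mean(ag$truth$n_breakpoints == 0), exp(-1), tolerance = 0.02)

  # breakpoint rate per Morgan close to g
  for (g in c(10, 100)) {
    cfgg <- sim_config(n_loci = 2, n_chrom = 1, chrom_length_cm = 100,
                       g = g, n_sample = 5000, N = 5000, seed = g)
    ag2 <- sim_admixed_pulse(cfgg, dg$freqs, dg$map)
    expect_equal(mean(ag2$truth$n_breakpoints), g, tolerance = 0.05)
  }
})

test_that("forward mode: pure pulses and single-tract F1 gametes", {
  cfg <- sim_config(n_loci = 50, n_chrom = 2, m = 0, g = 3, N = 30,
                    n_sample = 10, seed = 5)
  d <- sim_divergent_panels(cfg, 10, 10)
  a <- sim_admixed_forward(cfg, d$freqs, d$map)
  expect_true(all(a$truth$labels == 1L))
  # one generation after the pulse every chromosome is a single pure tract
  cfg1 <- sim_config(n_loci = 50, n_chrom = 2, m = 0.4, g = 1, N = 50,
                     n_sample = 20, seed = 6)
  a1 <- sim_admixed_forward(cfg1, d$freqs[seq_len(100), ], d$map)
  per_chrom_pure <- tapply(seq_len(nrow(a1$truth$tracts)),
                           paste(a1$truth$tracts$haplotype_id,
                                 a1$truth$tracts$chrom),
                           function(ii) length(ii) == 1)
  expect_true(all(per_chrom_pure))
})

test_that("minority genome fraction matches the pulse proportion m", {
  frac_p <- vapply(1:4, function(s) {
    cfg <- sim_config(n_loci = 50, n_chrom = 4, m = 0.33, g = 20,
                      n_sample = 40, seed = s)
    d <- sim_divergent_panels(cfg, 4, 4)
    mean(sim_admixed_pulse(cfg, d$freqs, d$map)$truth$labels == 2L)
  }, numeric(1))
  expect_lt(abs(mean(frac_p) - 0.33), 2 * stats::sd(frac_p) + 0.02)
  cfgf <- sim_config(n_loci = 50, n_chrom = 4, m = 0.33, g = 5, N = 200,
                     n_sample = 50, seed = 11)
  df <- sim_divergent_panels(cfgf, 4, 4)
  ff <- mean(sim_admixed_forward(cfgf, df$freqs, df$map)$truth$labels == 2L)
  expect_lt(abs(ff - 0.33), 0.15)  # drift at N=200 adds spread
})

test_that("minority tract length shrinks with generations since the pulse", {
  mean_minority_tract <- function(a) {
    tr <- a$truth$tracts
    mean((tr$end_bp - tr$start_bp)[tr$label == "B"])
  }
  lens <- vapply(c(5, 25, 100), function(g) {
    m <- vapply(1:3, function(s) {
      cfg <- sim_config(n_loci = 20, n_chrom = 1, m = 0.3, g = g, N = 300,
                        n_sample = 30, seed = 20 + s)
      d <- sim_divergent_panels(cfg, 2, 2)
      mean_minority_tract(sim_admixed_forward(cfg, d$freqs, d$map))
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(lens) < 0))
})

test_that("forward and pulse modes agree on tract scale for g << N", {
  mean_tract <- function(a) {
    tr <- a$truth$tracts
    mean(tr$end_bp - tr$start_bp)
  }
  res <- vapply(1:3, function(s) {
    cfg <- sim_config(n_loci = 20, n_chrom = 2, m = 0.3, g = 10, N = 400,
                      n_sample = 60, seed = 30 + s)
    d <- sim_divergent_panels(cfg, 2, 2)
    fw <- mean_tract(sim_admixed_forward(cfg, d$freqs, d$map))
    pu <- mean_tract(sim_admixed_pulse(cfg, d$freqs, d$map))
    c(fw, pu)
  }, numeric(2))
  expect_equal(mean(res[1, ]), mean(res[2, ]), tolerance = 0.15)
})

test_that("truth painting, labels and tracts are mutually consistent", {
  cfg <- sim_config(n_loci = 40, n_chrom = 2, m = 0.3, g = 15,
                    n_sample = 8, seed = 9)
  d <- sim_divergent_panels(cfg, 6, 6)
  a <- sim_admixed_pulse(cfg, d$freqs, d$map)
  expect_equal(a$truth$painting$prob_A, (a$truth$labels == 1L) * 1,
               ignore_attr = TRUE)
  # per-marker label equals the covering tract's label
  tr <- a$truth$tracts
  for (h in unique(tr$haplotype_id)[1:3]) {
    hrow <- which(a$truth$painting$haplotype_ids == h)
    for (ch in c("1", "2")) {
      sel <- a$truth$painting$map$chrom == ch
      pos <- a$truth$painting$map$pos_bp[sel]
      trh <- tr[tr$haplotype_id == h & tr$chrom == ch, ]
      lab_from_tracts <- trh$label[findInterval(pos, trh$start_bp)]
      expect_equal(c("A", "B")[a$truth$labels[hrow, sel]], lab_from_tracts)
    }
  }
})
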