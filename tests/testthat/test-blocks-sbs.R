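test_that("block boundaries fall at midpoints and tile the marker span", {
  p <- make_painting(c(0.9, 0.9, 0.1, 0.1), c(10, 20, 30, 40))
  b <- call_blocks(p)
  expect_equal(b$label, c("A", "B"))
  expect_equal(b$start_bp, c(10, 25))
  expect_equal(b$end_bp, c(25, 40))
  sp <- attr(b, "span")
  expect_equal(sp$span_start, 10)
  expect_equal(sp$span_end, 40)
})

test_that("threshold ties are uncertain and intermediates merge", {
  p <- make_painting(c(0.9, 0.75, 0.9), c(0, 100, 200))
  b <- call_blocks(p)
  expect_equal(b$label, c("A", "uncertain", "A"))
  p2 <- make_painting(c(0.3, 0.5, 0.7, 0.26), c(0, 10, 20, 30))
  b2 <- call_blocks(p2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$label, "uncertain")
  expect_equal(c(b2$start_bp, b2$end_bp), c(0, 30))
})

test_that("single-marker chromosomes warn and produce zero-length blocks", {
  map <- marker_map(c("1", "1", "2"), c("a", "b", "c"), c(10, 20, 5))
  p <- ancestry_painting(matrix(c(0.9, 0.9, 0.9), 1), "h_0", map)
  expect_warning(b <- call_blocks(p), "single marker")
  one <- b[b$chrom == "2", ]
  expect_equal(one$end_bp - one$start_bp, 0)
})

test_that("minority ancestry is the smaller labelled total", {
  mk <- function(lens, labels, hap = "s1_0", chrom = "1") {
    data.frame(haplotype_id = hap, chrom = chrom,
               start_bp = cumsum(c(0, head(lens, -1))),
               end_bp = cumsum(lens), label = labels,
               stringsAsFactors = FALSE)
  }
  b <- block_set(mk(c(70e6, 30e6), c("A", "B")))
  m <- minority_label(b)
  expect_equal(m$minority, "B")
  expect_equal(m$fraction, 0.30)
  # uncertain length excluded from numerator and denominator
  b2 <- block_set(mk(c(60e6, 20e6, 20e6), c("A", "B", "uncertain")))
  m2 <- minority_label(b2)
  expect_equal(m2$minority, "B")
  expect_equal(m2$fraction, 0.25)
  # exact tie errors
  b3 <- block_set(mk(c(50e6, 50e6), c("A", "B")))
  expect_error(minority_label(b3), "tie")
  # X blocks are ignored for the genome-wide call
  b4 <- block_set(rbind(mk(c(70e6, 30e6), c("A", "B")),
                        mk(c(100e6), "B", chrom = "X")))
  expect_equal(minority_label(b4)$fraction, 0.30)
})

test_that("a single introgressed block scores SBS exactly 1", {
  b <- block_set(data.frame(
    haplotype_id = "s1_0", chrom = "1",
    start_bp = c(0, 40e6, 60e6), end_bp = c(40e6, 60e6, 100e6),
    label = c("A", "B", "A")))
  expect_identical(chromosome_sbs(b, "B", 100e6), 1)
})

test_that("SBS is median over sum of minority block proportions", {
  b <- block_set(data.frame(
    haplotype_id = "h_0", chrom = "1",
    start_bp = c(0, 10e6, 15e6, 40e6, 50e6, 60e6),
    end_bp = c(10e6, 15e6, 40e6, 50e6, 60e6, 75e6),
    label = c("A", "B", "A", "B", "A", "B")))
  # minority blocks 5, 10, 15 Mb on a 100 Mb span
  expect_equal(chromosome_sbs(b, "B", 100e6), (10 / 100) / (30 / 100))
  # no minority block -> undefined
  expect_true(is.na(chromosome_sbs(b, "uncertain", 100e6)))
  b_a_only <- block_set(data.frame(haplotype_id = "h_0", chrom = "1",
                                   start_bp = 0, end_bp = 10e6,
                                   label = "A"))
  expect_true(is.na(chromosome_sbs(b_a_only, "B", 10e6)))
})

test_that("individual SBS averages the defined components", {
  m <- list(minority = "B", fraction = 0.2)
  expect_equal(individual_sbs(c(1.0, 0.5, NA), m)$sbs, 0.75)
  r <- individual_sbs(c(NA, NA), m)
  expect_true(is.na(r$sbs))
  expect_equal(r$n_defined, 0)
  expect_equal(individual_sbs(c(0.4, 0.4, NA, 0.1), m)$sbs, 0.3)
})

test_that("SBS lies in (0,1], equals 1 iff a single minority block", {
  set.seed(5)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    lens <- runif(k, 1, 10)           # minority (B) block widths
    gaps <- runif(k + 1, 1, 30)       # majority (A) separators
    widths <- c(rbind(gaps[seq_len(k)], lens), gaps[k + 1])
    labs <- c(rbind(rep("A", k), rep("B", k)), "A")
    span <- sum(widths)
    blocks <- data.frame(haplotype_id = "h_0", chrom = "1",
                         start_bp = cumsum(c(0, head(widths, -1))),
                         end_bp = cumsum(widths), label = labs,
                         stringsAsFactors = FALSE)
    v <- chromosome_sbs(block_set(blocks), "B", span)
    expect_true(v > 0 && v <= 1)
    expect_equal(v == 1, k == 1)
  }
})

test_that("SBS is invariant under uniform coordinate rescaling", {
  b <- data.frame(haplotype_id = "h_0", chrom = "1",
                  start_bp = c(0, 10, 30, 45), end_bp = c(10, 30, 45, 90),
                  label = c("B", "A", "B", "A"))
  v1 <- chromosome_sbs(block_set(b), "B", 90)
  b2 <- b
  b2$start_bp <- b2$start_bp * 1e6
  b2$end_bp <- b2$end_bp * 1e6
  expect_equal(chromosome_sbs(block_set(b2), "B", 90e6), v1)
})

test_that("sbs() assembles per-individual results from a cohort block set", {
  # s1: hap0 chrom1 single B block (SBS 1); hap1 chrom1 all A (undefined);
  #     chrom2 hap0 two B blocks of equal size (SBS 1/2); hap1 all A
  rows <- rbind(
    data.frame(haplotype_id = "s1_0", chrom = "1",
               start_bp = c(0, 40, 60), end_bp = c(40, 60, 100),
               label = c("A", "B", "A")),
    data.frame(haplotype_id = "s1_1", chrom = "1", start_bp = 0,
               end_bp = 100, label = "A"),
    data.frame(haplotype_id = "s1_0", chrom = "2",
               start_bp = c(0, 10, 20, 30), end_bp = c(10, 20, 30, 100),
               label = c("B", "A", "B", "A")),
    data.frame(haplotype_id = "s1_1", chrom = "2", start_bp = 0,
               end_bp = 100, label = "A"))
  res <- sbs(block_set(rows))
  expect_equal(nrow(res), 1)
  expect_equal(res$minority, "B")
  expect_equal(res$n_defined, 2)
  expect_equal(res$sbs, mean(c(1, 0.5)))
})

test_that("recent-hybrid classification uses the minimum reference SBS", {
  res <- structure(
    data.frame(individual = c("r1", "r2", "r3", "t1", "t2", "t3"),
               sbs = c(0.11, 0.09, 0.15, 0.10, 0.05, 0.09),
               n_defined = 5, minority = "B", minority_fraction = 0.3,
               stringsAsFactors = FALSE),
    class = c("sbs_result", "data.frame"))
  cls <- classify_recent(res, c("r1", "r2", "r3"))
  expect_equal(attr(cls, "cutoff"), 0.09)
  flags <- setNames(cls$recent, cls$individual)
  expect_true(all(flags[c("r1", "r2", "r3")]))  # references self-classify
  expect_true(flags[["t1"]])                    # 0.10 >= 0.09
  expect_false(flags[["t2"]])                   # 0.05 < cutoff
  expect_true(flags[["t3"]])                    # exactly at cutoff
  # undefined reference SBS only -> error
  res_na <- res
  res_na$sbs[1:3] <- NA
  expect_error(classify_recent(res_na, c("r1", "r2", "r3")), "reference")
})
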