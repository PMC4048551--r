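#' Default run configuration
#'
#' Every pipeline parameter with its default. Path-valued keys default to
#' `NA` (unset). A config file (see [read_config()]) or CLI flags may
#' override any entry; unknown keys are rejected.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    # simulate
    n_loci = 300, n_chrom = 10, chrom_length_cm = 100, F = 0.2, m = 0.33,
    g = 25, N = 1000, n_sample = 50, maf_min = 0.1, sim_mode = "pulse",
    n_donors_a = 50, n_donors_b = 50,
    # preprocess
    n_breed_threshold = 10, het_threshold = 0.5, callrate_threshold = 0.8,
    missing_ind_threshold = 0.70, ind_missing_threshold = 0.10,
    locus_missing_threshold = 0.10, par_start_bp = 137109768,
    sex_het_threshold = 0.01,
    # painter
    rho = 0.02, epsilon = 0.2, cm_per_mb = 1, donor_threshold = 0.02,
    ne_surrogate = 4000,
    # blocks / sbs
    block_threshold = 0.75, reference_ids = NA,
    # stats
    alpha_family = 0.05, n_chromosomes = 30, n_groups = 4,
    reps_bootstrap = 50000, reps_perm = 5000,
    # inputs / global
    ped = NA, map = NA, haplotypes = NA, panel_a = NA, panel_b = NA,
    painting = NA, blocks = NA, ancestry_matrix = NA,
    seed = 1
  )
}

# Per-stage child seeds: stage k reruns identically in isolation because
# its seed depends only on the global seed and the stage name.
stage_seed <- function(seed, stage) {
  k <- match(stage, c("simulate", "preprocess", "paint", "blocks", "sbs",
                      "stats"))
  (as.integer(seed) + 9973L * k) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in the fixed order
#' simulate, preprocess, paint, blocks, sbs, stats. Each stage reads its
#' inputs from `out_dir` (or the paths named in the config) and writes its
#' outputs there, so later stages can be run without earlier ones when
#' their input files already exist. Identical config and seed produce
#' byte-identical outputs. A provenance YAML echoing the effective config
#' is written at the end of every run.
#'
#' @param config named list of overrides of [default_config()].
#' @param stages character subset of the stage names, any order (executed
#'   in pipeline order).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress per-stage log lines (written with [message()]).
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = list(), stages = c("simulate", "blocks",
                                                     "sbs"),
                         out_dir = ".", quiet = FALSE) {
  cfg <- utils::modifyList(default_config(), config)
  unknown <- setdiff(names(cfg), names(default_config()))
  if (length(unknown)) {
    stop("run_pipeline: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  order_all <- c("simulate", "preprocess", "paint", "blocks", "sbs", "stats")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("run_pipeline: unknown stage: ", bad[1])
  stages <- order_all[order_all %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  log_line <- function(...) if (!quiet) message("[blockclock] ", ...)
  written <- list()

  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop("run_pipeline: missing input ", path, "; run stage '", producer,
           "' first (or point the config at an existing file)")
    }
    path
  }
  path_or <- function(key, fallback) {
    if (!is.na(cfg[[key]])) cfg[[key]] else fallback
  }

  if ("simulate" %in% stages) {
    scfg <- sim_config(n_loci = cfg$n_loci, n_chrom = cfg$n_chrom,
                       chrom_length_cm = cfg$chrom_length_cm, F = cfg$F,
                       m = cfg$m, g = cfg$g, N = cfg$N,
                       n_sample = cfg$n_sample, maf_min = cfg$maf_min,
                       cm_per_mb = cfg$cm_per_mb,
                       seed = stage_seed(cfg$seed, "simulate"))
    div <- sim_divergent_panels(scfg, cfg$n_donors_a, cfg$n_donors_b)
    adm <- if (cfg$sim_mode == "forward") {
      sim_admixed_forward(scfg, div$freqs, div$map)
    } else sim_admixed_pulse(scfg, div$freqs, div$map)
    gt_map <- div$map
    cm <- gt_map$pos_cm
    utils::write.table(
      data.frame(gt_map$chrom, gt_map$name, cm,
                 format(gt_map$pos_bp, scientific = FALSE, trim = TRUE)),
      p("markers.map"), quote = FALSE, sep = "\t", row.names = FALSE,
      col.names = FALSE)
    write_haplotypes(adm$panel, p("haplotypes.tsv"))
    write_haplotypes(div$panels$panel_A, p("donors_a.tsv"))
    write_haplotypes(div$panels$panel_B, p("donors_b.tsv"))
    write_painting(adm$truth$painting, p("truth_painting.tsv"))
    write_blocks(call_blocks(adm$truth$painting, cfg$block_threshold),
                 p("truth_blocks.bed"))
    written$map <- p("markers.map")
    written$haplotypes <- p("haplotypes.tsv")
    written$truth_painting <- p("truth_painting.tsv")
    log_line(sprintf(
      "simulate: %d loci x %d chrom, %d targets, %d+%d donors (mode %s)",
      cfg$n_loci, cfg$n_chrom, cfg$n_sample, cfg$n_donors_a,
      cfg$n_donors_b, cfg$sim_mode))
  }

  if ("preprocess" %in% stages) {
    ped <- need(path_or("ped", p("genotypes.ped")), "none (supply 'ped')")
    mp <- need(path_or("map", p("genotypes.map")), "none (supply 'map')")
    gin <- read_genotypes(ped, mp)
    fl <- filter_loci(gin$genotypes,
                      n_breed_threshold = cfg$n_breed_threshold,
                      het_threshold = cfg$het_threshold,
                      callrate_threshold = cfg$callrate_threshold,
                      missing_ind_threshold = cfg$missing_ind_threshold)
    fm <- filter_missingness(fl$genotypes,
                             ind_threshold = cfg$ind_missing_threshold,
                             locus_threshold = cfg$locus_missing_threshold)
    gt <- fm$genotypes
    x_map <- exclude_par(gt$map[gt$map$chrom == "X", , drop = FALSE],
                         cfg$par_start_bp)
    class(x_map) <- c("marker_map", "data.frame")
    if (nrow(x_map)) {
      sx <- assign_sex(gt, x_map, cfg$sex_het_threshold)
      gt <- sx$genotypes
      write_table(sx$sex, p("sex.tsv"), sort_by = "individual")
      written$sex <- p("sex.tsv")
    }
    drop_par <- gt$map$chrom == "X" & gt$map$pos_bp >= cfg$par_start_bp
    gt <- subset_loci(gt, !drop_par)
    write_genotypes(gt, p("filtered.ped"), p("filtered.map"))
    rep_all <- rbind(fl$report$removed_loci, fm$report$removed_loci)
    write_table(rep_all, p("filter_report.tsv"), sort_by = "name")
    written$filtered_ped <- p("filtered.ped")
    log_line(sprintf(
      "preprocess: %d -> %d loci, %d -> %d individuals",
      ncol(gin$genotypes$calls), ncol(gt$calls),
      nrow(gin$genotypes$calls), nrow(gt$calls)))
  }

  if ("paint" %in% stages) {
    mp <- need(path_or("map", p("markers.map")), "simulate")
    tg <- need(path_or("haplotypes", p("haplotypes.tsv")), "simulate")
    pa <- need(path_or("panel_a", p("donors_a.tsv")), "simulate")
    pb <- need(path_or("panel_b", p("donors_b.tsv")), "simulate")
    targets <- read_haplotypes(tg, mp)
    panels <- donor_panels(
      read_haplotypes(pa, targets$map)$haplotypes,
      read_haplotypes(pb, targets$map)$haplotypes)
    params <- painter_params(rho = cfg$rho, epsilon = cfg$epsilon,
                             cm_per_mb = cfg$cm_per_mb)
    painting <- paint_cohort(targets$haplotypes, panels, params)
    write_painting(painting, p("painting.tsv"))
    written$painting <- p("painting.tsv")
    log_line(sprintf("paint: %d haplotypes x %d markers",
                     nrow(painting$prob_A), ncol(painting$prob_A)))
  }

  if ("blocks" %in% stages) {
    mp <- need(path_or("map", p("markers.map")), "simulate")
    src <- path_or("painting",
                   if (file.exists(p("painting.tsv"))) p("painting.tsv")
                   else p("truth_painting.tsv"))
    need(src, "paint (or simulate for the truth painting)")
    map <- read_haplotypes_map(mp)
    painting <- read_painting(src, map)
    bl <- call_blocks(painting, cfg$block_threshold)
    write_blocks(bl, p("blocks.bed"))
    written$blocks <- p("blocks.bed")
    log_line(sprintf("blocks: %d blocks from %s", nrow(bl), src))
  }

  if ("sbs" %in% stages) {
    bp <- need(path_or("blocks", p("blocks.bed")), "blocks")
    bl <- read_blocks(bp)
    res <- sbs(bl)
    write_table(as.data.frame(res), p("sbs.tsv"), sort_by = "individual")
    written$sbs <- p("sbs.tsv")
    if (!all(is.na(cfg$reference_ids))) {
      cls <- classify_recent(res, cfg$reference_ids)
      con <- file(p("classification.tsv"), "w")
      writeLines(sprintf("# cutoff\t%s", signif6(attr(cls, "cutoff"))), con)
      close(con)
      suppressWarnings(utils::write.table(
        cls, p("classification.tsv"), quote = FALSE, sep = "\t",
        row.names = FALSE, col.names = TRUE, append = TRUE))
      written$classification <- p("classification.tsv")
    }
    log_line(sprintf("sbs: %d individuals, mean SBS %.3f", nrow(res),
                     mean(res$sbs, na.rm = TRUE)))
  }

  if ("stats" %in% stages) {
    am_path <- path_or("ancestry_matrix", NA)
    if (!is.na(am_path)) {
      need(am_path, "none (supply 'ancestry_matrix')")
      m <- read_ancestry_matrix(am_path)
    } else {
      bp <- path_or("blocks", p("blocks.bed"))
      if (!file.exists(bp)) {
        stop("run_pipeline: stats needs 'ancestry_matrix' or block output; ",
             "run stage 'paint'/'blocks' first or set ancestry_matrix")
      }
      m <- chromosome_ancestry_proportions(read_blocks(bp))
    }
    alpha <- bonferroni_alpha(cfg$alpha_family, cfg$n_chromosomes,
                              cfg$n_groups)$alpha
    bt <- bootstrap_median_test(m, n_reps = cfg$reps_bootstrap,
                                alpha = alpha,
                                seed = stage_seed(cfg$seed, "stats"))
    pv <- permutation_variability_test(m, n_reps = cfg$reps_perm,
                                       seed = stage_seed(cfg$seed, "stats"))
    tab <- bt$per_chrom
    tab$lower_cutoff <- bt$lower_cutoff
    tab$upper_cutoff <- bt$upper_cutoff
    write_table(tab, p("stats.tsv"), sort_by = "chrom")
    written$stats <- p("stats.tsv")
    log_line(sprintf(
      "stats: %d chromosomes tested, %d significant; variability F = %.3g (p = %.3g)",
      nrow(tab), sum(tab$significant), pv$F_observed, pv$p))
  }

  cfg_out <- cfg[!vapply(cfg, function(v) all(is.na(v)), logical(1))]
  yaml::write_yaml(c(cfg_out, list(stages = stages)), p("provenance.yaml"))
  written$provenance <- p("provenance.yaml")
  invisible(written)
}

# Read a 4-column .map (or pass through a marker_map).
read_haplotypes_map <- function(mp) {
  if (inherits(mp, "marker_map")) return(mp)
  m <- read_plink_map(mp)
  attr(m, "read_order") <- NULL
  attr(m, "read_names") <- NULL
  m
}

#' Read an individual x chromosome ancestry matrix from TSV
#'
#' First column `individual`, optional second column `group`, remaining
#' columns one per chromosome. The drop-in point for externally computed
#' per-chromosome ancestry proportions.
#'
#' @param path TSV path.
#' @return a `chrom_ancestry` matrix with optional `groups` attribute.
#' @export
read_ancestry_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  groups <- NULL
  if (ncol(tab) >= 2 && names(tab)[2] == "group") {
    groups <- stats::setNames(as.character(tab[[2]]),
                              as.character(tab[[1]]))
    vals <- tab[, -(1:2), drop = FALSE]
  } else {
    vals <- tab[, -1, drop = FALSE]
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  structure(m, groups = groups, class = c("chrom_ancestry", "matrix"))
}

#' Write an ancestry matrix to TSV
#'
#' @param m a `chrom_ancestry` matrix.
#' @param path output path.
#' @export
write_ancestry_matrix <- function(m, path) {
  groups <- attr(m, "groups")
  df <- data.frame(individual = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- unname(groups[rownames(m)])
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_table(df, path, sort_by = "individual")
}
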