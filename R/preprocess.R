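#' SNP-array and individual quality control
#'
#' The preprocessing stage applies the array-quality filters in a fixed
#' order: (1) breed-level locus rules — excess heterozygosity (a paralogy
#' signal) and low call rate (a null-allele signal) in many breeds, and
#' gross missingness; (2) removal of high-missingness individuals; (3)
#' removal of loci that became high-missingness among the remaining
#' individuals. Each removed locus records the first rule that triggered.
#'
#' @name preprocess
NULL

filter_report <- function(removed_loci, removed_individuals) {
  counts <- c(table(removed_loci$reason), table(removed_individuals$reason))
  structure(list(removed_loci = removed_loci,
                 removed_individuals = removed_individuals,
                 counts = counts),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d loci, %d individuals removed\n",
              nrow(x$removed_loci), nrow(x$removed_individuals)))
  if (length(x$counts)) {
    for (r in names(x$counts)) cat(sprintf("  %-12s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

#' Filter loci on breed-level heterozygosity, call rate and missingness
#'
#' Removes a locus when (a) its observed heterozygosity (heterozygous
#' fraction among non-missing calls, within breed) exceeds
#' `het_threshold` in at least `n_breed_threshold` breeds; or (b) its call
#' rate (non-missing fraction within breed) is below `callrate_threshold`
#' in at least `n_breed_threshold` breeds; or (c) it is missing in at least
#' `missing_ind_threshold` of all individuals. Rules are evaluated in order
#' (a), (b), (c) and the report records the first-triggering rule per
#' locus. Heterozygosity and call-rate comparisons are strict; the gross
#' missingness rule uses "at least".
#'
#' @param gt a [genotype_table()].
#' @param n_breed_threshold number of breeds that must breach a breed-level
#'   rule for it to fire (default 10).
#' @param het_threshold within-breed heterozygosity above which a breed
#'   counts against rule (a) (default 0.5).
#' @param callrate_threshold within-breed call rate below which a breed
#'   counts against rule (b) (default 0.8).
#' @param missing_ind_threshold overall missing fraction at or above which
#'   rule (c) fires (default 0.70).
#' @param exclude character vector of marker names to drop unconditionally
#'   before any rule (a curated exclusion list, e.g. markers absent from
#'   the array manifest); reported with reason `"excluded"`.
#' @return list with elements `genotypes` (filtered table, map subset to
#'   match) and `report` (a `filter_report`).
#' @export
filter_loci <- function(gt, n_breed_threshold = 10, het_threshold = 0.5,
                        callrate_threshold = 0.8,
                        missing_ind_threshold = 0.70, exclude = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!nrow(gt$calls) || !ncol(gt$calls)) stop("filter_loci: empty table")
  breeds <- unique(gt$breed)
  if (any(!breeds %in% gt$breed)) stop("filter_loci: breed with no members")

  reason <- rep(NA_character_, ncol(gt$calls))
  names(reason) <- colnames(gt$calls)
  if (!is.null(exclude)) reason[colnames(gt$calls) %in% exclude] <- "excluded"

  by_breed <- split(seq_len(nrow(gt$calls)), gt$breed)
  n_breed_het <- integer(ncol(gt$calls))
  n_breed_lowcall <- integer(ncol(gt$calls))
  for (idx in by_breed) {
    sub <- gt$calls[idx, , drop = FALSE]
    ncall <- colSums(!is.na(sub))
    nhet <- colSums(sub == 1, na.rm = TRUE)
    het <- ifelse(ncall > 0, nhet / ncall, 0)
    callrate <- ncall / length(idx)
    n_breed_het <- n_breed_het + (het > het_threshold)
    n_breed_lowcall <- n_breed_lowcall + (callrate < callrate_threshold)
  }
  miss_frac <- colMeans(is.na(gt$calls))

  hit <- is.na(reason) & n_breed_het >= n_breed_threshold
  reason[hit] <- "high_het"
  hit <- is.na(reason) & n_breed_lowcall >= n_breed_threshold
  reason[hit] <- "low_callrate"
  hit <- is.na(reason) & miss_frac >= missing_ind_threshold
  reason[hit] <- "missing_70"

  keep <- is.na(reason)
  removed <- data.frame(name = names(reason)[!keep],
                        reason = unname(reason[!keep]),
                        stringsAsFactors = FALSE)
  out <- subset_loci(gt, keep)
  list(genotypes = out,
       report = filter_report(removed, data.frame(
         id = character(), reason = character(), stringsAsFactors = FALSE)))
}

#' Filter individuals then loci on missingness
#'
#' First drops individuals whose missing fraction across all retained loci
#' (autosomes and X together) exceeds `ind_threshold`, then drops loci
#' missing in more than `locus_threshold` of the remaining individuals.
#' Both comparisons are strict, so an individual missing exactly the
#' threshold fraction is retained. The two steps are order-dependent: loci
#' are judged against the post-removal cohort.
#'
#' @param gt a [genotype_table()].
#' @param ind_threshold maximum tolerated per-individual missing fraction
#'   (default 0.10).
#' @param locus_threshold maximum tolerated per-locus missing fraction
#'   among remaining individuals (default 0.10).
#' @return list with elements `genotypes` and `report`.
#' @export
filter_missingness <- function(gt, ind_threshold = 0.10,
                               locus_threshold = 0.10) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!nrow(gt$calls)) stop("filter_missingness: empty table")
  ind_miss <- rowMeans(is.na(gt$calls))
  keep_ind <- ind_miss <= ind_threshold
  if (!any(keep_ind)) {
    stop("filter_missingness: every individual exceeds the ",
         ind_threshold * 100, "% missingness threshold; review thresholds")
  }
  removed_ind <- data.frame(id = gt$individuals[!keep_ind],
                            reason = rep("missing_10", sum(!keep_ind)),
                            stringsAsFactors = FALSE)
  gt2 <- structure(list(calls = gt$calls[keep_ind, , drop = FALSE],
                        individuals = gt$individuals[keep_ind],
                        breed = gt$breed[keep_ind], map = gt$map),
                   class = "genotype_table")
  locus_miss <- colMeans(is.na(gt2$calls))
  keep_loc <- locus_miss <= locus_threshold
  removed_loc <- data.frame(name = colnames(gt2$calls)[!keep_loc],
                            reason = rep("missing_10", sum(!keep_loc)),
                            stringsAsFactors = FALSE)
  list(genotypes = subset_loci(gt2, keep_loc),
       report = filter_report(removed_loc, removed_ind))
}

subset_loci <- function(gt, keep) {
  map <- gt$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  structure(list(calls = gt$calls[, keep, drop = FALSE],
                 individuals = gt$individuals, breed = gt$breed, map = map),
            class = "genotype_table")
}

#' Exclude the X pseudoautosomal region
#'
#' Removes X-chromosome markers at or beyond the pseudoautosomal-region
#' boundary; the PAR recombines with the Y and must not enter hemizygosity-
#' based sex assignment or X ancestry analyses. Autosomes are untouched and
#' a map without an X chromosome passes through unchanged. The comparison
#' is `pos_bp >= par_start_bp` on the map's own coordinate scale; the
#' default is the bovine UMD3.1 PAR boundary.
#'
#' @param map a [marker_map()].
#' @param par_start_bp first position belonging to the PAR
#'   (default 137109768).
#' @return the map with PAR markers removed.
#' @export
exclude_par <- function(map, par_start_bp = 137109768) {
  stopifnot(inherits(map, "marker_map"))
  drop <- map$chrom == "X" & map$pos_bp >= par_start_bp
  out <- map[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Assign sex from X-chromosome heterozygosity
#'
#' Males carry one X, so true X-linked loci cannot be heterozygous in
#' males; residual heterozygous calls reflect genotyping error. An
#' individual is called male when its heterozygous fraction among
#' non-missing non-PAR X calls is below `het_threshold`, female otherwise.
#' Heterozygous X calls in assigned males are then recoded to missing.
#' Individuals with no non-missing X call are unassignable and reported
#' separately (sex `NA`).
#'
#' @param gt a [genotype_table()] still containing the X markers.
#' @param x_map [marker_map()] of the X markers to use, PAR already
#'   excluded (see [exclude_par()]).
#' @param het_threshold heterozygosity fraction below which an individual
#'   is male (default 0.01).
#' @return list with elements `sex` (data.frame `individual`, `sex`,
#'   `x_het_fraction`, `n_x_calls`) and `genotypes` (the table with male
#'   heterozygous X calls recoded to missing).
#' @export
assign_sex <- function(gt, x_map, het_threshold = 0.01) {
  stopifnot(inherits(gt, "genotype_table"), inherits(x_map, "marker_map"))
  if (any(x_map$chrom != "X")) stop("assign_sex: x_map must be X-only")
  xcols <- match(x_map$name, colnames(gt$calls))
  if (anyNA(xcols)) {
    stop("assign_sex: X marker absent from table: ",
         x_map$name[which(is.na(xcols))[1]])
  }
  x <- gt$calls[, xcols, drop = FALSE]
  ncall <- rowSums(!is.na(x))
  nhet <- rowSums(x == 1, na.rm = TRUE)
  frac <- ifelse(ncall > 0, nhet / ncall, NA_real_)
  sex <- ifelse(is.na(frac), NA_character_,
                ifelse(frac < het_threshold, "male", "female"))
  calls <- gt$calls
  male <- which(!is.na(sex) & sex == "male")
  for (i in male) {
    het_at <- xcols[which(x[i, ] == 1)]
    if (length(het_at)) calls[i, het_at] <- NA_integer_
  }
  gt2 <- structure(list(calls = calls, individuals = gt$individuals,
                        breed = gt$breed, map = gt$map),
                   class = "genotype_table")
  list(sex = data.frame(individual = gt$individuals, sex = sex,
                        x_het_fraction = frac, n_x_calls = ncall,
                        stringsAsFactors = FALSE),
       genotypes = gt2)
}
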