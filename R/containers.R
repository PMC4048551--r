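#' Construct a diploid genotype table
#'
#' Genotypes are stored as counts of the reference-coded allele in
#' \{0, 1, 2\} with `NA` for missing, one row per individual and one column
#' per marker in marker-map order. The breed (group) label travels with each
#' individual.
#'
#' @param calls integer matrix individuals x markers, values 0/1/2/NA.
#' @param individuals character vector of sample identifiers (unique).
#' @param breed character vector of breed/group labels per individual.
#' @param map the matching [marker_map()]; column count must agree.
#' @return A `genotype_table` list with elements `calls`, `individuals`,
#'   `breed`, `map`.
#' @export
genotype_table <- function(calls, individuals, breed, map) {
  stopifnot(inherits(map, "marker_map"))
  calls <- as.matrix(calls)
  if (nrow(calls) != length(individuals) || nrow(calls) != length(breed)) {
    stop("genotype_table: row count does not match individuals/breed")
  }
  if (ncol(calls) != nrow(map)) {
    stop("genotype_table: ", ncol(calls), " call columns but ",
         nrow(map), " markers in map")
  }
  if (anyDuplicated(individuals)) stop("genotype_table: duplicated sample id")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype_table: calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(individuals, map$name)
  structure(list(calls = calls, individuals = as.character(individuals),
                 breed = as.character(breed), map = map),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d markers, %d breed(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$breed))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct a phased haplotype panel
#'
#' Phased binary alleles, one row per haplotype. Diploid individuals
#' contribute two haplotypes named `<sample>_0` and `<sample>_1`; hemizygous
#' males contribute one on the X.
#'
#' @param alleles integer matrix haplotypes x markers, values 0/1/NA.
#' @param haplotype_ids character vector of unique haplotype identifiers.
#' @param labels breed/group label per haplotype (from the source
#'   individual).
#' @param map the matching [marker_map()].
#' @return A `haplotype_panel` list with elements `alleles`,
#'   `haplotype_ids`, `labels`, `map`.
#' @export
haplotype_panel <- function(alleles, haplotype_ids, labels, map) {
  stopifnot(inherits(map, "marker_map"))
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(haplotype_ids) ||
      nrow(alleles) != length(labels)) {
    stop("haplotype_panel: row count does not match ids/labels")
  }
  if (ncol(alleles) != nrow(map)) {
    stop("haplotype_panel: ", ncol(alleles), " allele columns but ",
         nrow(map), " markers in map")
  }
  if (anyDuplicated(haplotype_ids)) {
    stop("haplotype_panel: duplicated haplotype id")
  }
  ok <- alleles[!is.na(alleles)]
  if (length(ok) && !all(ok %in% 0:1)) {
    stop("haplotype_panel: alleles must be 0, 1 or NA")
  }
  dimnames(alleles) <- list(haplotype_ids, map$name)
  structure(list(alleles = alleles,
                 haplotype_ids = as.character(haplotype_ids),
                 labels = as.character(labels), map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d markers, %d group(s)\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$labels))))
  invisible(x)
}

# Individual id of a haplotype id "<sample>_<phase>".
hap_individual <- function(haplotype_ids) {
  sub("_[01]$", "", haplotype_ids)
}

#' Construct an ancestry painting
#'
#' Per-(haplotype, marker) posterior probability that the site copies from
#' donor panel A. Under the two-panel model the panel-B probability is the
#' complement, so a single matrix suffices.
#'
#' @param prob_A numeric matrix haplotypes x markers, values in \[0, 1\].
#' @param haplotype_ids character vector of haplotype identifiers.
#' @param map the matching [marker_map()].
#' @return An `ancestry_painting` list with elements `prob_A`,
#'   `haplotype_ids`, `map`.
#' @export
ancestry_painting <- function(prob_A, haplotype_ids, map) {
  stopifnot(inherits(map, "marker_map"))
  prob_A <- as.matrix(prob_A)
  if (nrow(prob_A) != length(haplotype_ids)) {
    stop("ancestry_painting: row count does not match haplotype_ids")
  }
  if (ncol(prob_A) != nrow(map)) {
    stop("ancestry_painting: column count does not match map")
  }
  if (anyNA(prob_A) || any(prob_A < 0) || any(prob_A > 1)) {
    stop("ancestry_painting: prob_A values must lie in [0, 1]")
  }
  dimnames(prob_A) <- list(haplotype_ids, map$name)
  structure(list(prob_A = prob_A,
                 haplotype_ids = as.character(haplotype_ids), map = map),
            class = "ancestry_painting")
}

#' @export
print.ancestry_painting <- function(x, ...) {
  cat(sprintf(
    "ancestry_painting: %d haplotypes x %d markers (mean P(A) = %.3f)\n",
    nrow(x$prob_A), ncol(x$prob_A), mean(x$prob_A)))
  invisible(x)
}

#' Construct a block set
#'
#' Contiguous ancestry-labelled intervals per haplotype-chromosome. Within a
#' haplotype-chromosome the blocks are non-overlapping, sorted, exactly tile
#' the first-to-last-marker span, and adjacent blocks carry different
#' labels. Coordinates are 0-based half-open base pairs.
#'
#' @param blocks data.frame with columns `haplotype_id`, `chrom`,
#'   `start_bp`, `end_bp`, `label` (one of "A", "B", "uncertain").
#' @param span data.frame with columns `chrom`, `span_start`, `span_end`
#'   giving the first/last marker positions per chromosome (the SBS
#'   denominator extent). Derived from the blocks when omitted.
#' @return A `block_set`: the block data.frame (sorted by haplotype,
#'   chromosome, start) with the span table as attribute `span`.
#' @export
block_set <- function(blocks, span = NULL) {
  need <- c("haplotype_id", "chrom", "start_bp", "end_bp", "label")
  if (!all(need %in% names(blocks))) {
    stop("block_set: blocks must have columns ", paste(need, collapse = ", "))
  }
  blocks <- as.data.frame(blocks)[need]
  blocks$haplotype_id <- as.character(blocks$haplotype_id)
  blocks$chrom <- as.character(blocks$chrom)
  if (nrow(blocks) && !all(blocks$label %in% c("A", "B", "uncertain"))) {
    stop("block_set: labels must be A, B or uncertain")
  }
  ord <- order(blocks$haplotype_id, chrom_rank(blocks$chrom), blocks$start_bp)
  blocks <- blocks[ord, , drop = FALSE]
  rownames(blocks) <- NULL
  key <- paste(blocks$haplotype_id, blocks$chrom)
  for (k in unique(key)) {
    b <- blocks[key == k, ]
    if (any(b$end_bp < b$start_bp)) stop("block_set: negative block on ", k)
    if (nrow(b) > 1) {
      if (any(b$start_bp[-1] != b$end_bp[-nrow(b)])) {
        stop("block_set: blocks do not tile contiguously on ", k)
      }
      if (any(b$label[-1] == b$label[-nrow(b)])) {
        stop("block_set: adjacent blocks share a label on ", k)
      }
    }
  }
  if (is.null(span)) {
    span <- do.call(rbind, lapply(split(blocks, blocks$chrom), function(b) {
      data.frame(chrom = b$chrom[1], span_start = min(b$start_bp),
                 span_end = max(b$end_bp), stringsAsFactors = FALSE)
    }))
    if (is.null(span)) {
      span <- data.frame(chrom = character(), span_start = numeric(),
                         span_end = numeric(), stringsAsFactors = FALSE)
    }
    rownames(span) <- NULL
  }
  structure(blocks, span = span, class = c("block_set", "data.frame"))
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks, %d haplotype(s), %d chromosome(s)\n",
              nrow(x), length(unique(x$haplotype_id)),
              length(unique(x$chrom))))
  if (nrow(x)) {
    tab <- table(x$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
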