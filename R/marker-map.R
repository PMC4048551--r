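#' Construct a marker map
#'
#' A marker map holds the ordered physical (and optionally genetic) positions
#' of SNP markers. Chromosome labels are strings: autosomes "1".."29" sort
#' numerically and "X" sorts after "29". Within each chromosome physical
#' positions must be strictly increasing; construction canonicalises the
#' order by (chromosome, position).
#'
#' Coordinates are 0-based throughout the package; intervals derived from the
#' map (ancestry blocks) are half-open.
#'
#' @param chrom character vector of chromosome labels.
#' @param name character vector of marker identifiers (unique).
#' @param pos_bp integer/numeric physical positions in base pairs.
#' @param pos_cm optional numeric genetic positions in centimorgans;
#'   non-decreasing within chromosome. When absent, genetic positions are
#'   derived from `pos_bp` on demand (see [genetic_positions()]).
#' @return A `marker_map`: a data.frame with columns `chrom`, `name`,
#'   `pos_bp`, `pos_cm` (possibly all-`NA`), sorted by (chrom, pos_bp).
#' @seealso [genetic_positions()], [read_genotypes()]
#' @export
marker_map <- function(chrom, name, pos_bp, pos_cm = NULL) {
  chrom <- as.character(chrom)
  name <- as.character(name)
  pos_bp <- as.numeric(pos_bp)
  n <- length(name)
  if (length(chrom) != n || length(pos_bp) != n) {
    stop("marker_map: chrom, name and pos_bp must have equal length")
  }
  if (anyDuplicated(name)) {
    stop("marker_map: duplicated marker name: ",
         name[anyDuplicated(name)])
  }
  if (is.null(pos_cm)) pos_cm <- rep(NA_real_, n)
  pos_cm <- as.numeric(pos_cm)
  if (length(pos_cm) != n) stop("marker_map: pos_cm length mismatch")

  ord <- order(chrom_rank(chrom), pos_bp)
  map <- data.frame(chrom = chrom[ord], name = name[ord],
                    pos_bp = pos_bp[ord], pos_cm = pos_cm[ord],
                    stringsAsFactors = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker_map: pos_bp not strictly increasing on chromosome ", ch)
    }
    g <- map$pos_cm[map$chrom == ch]
    if (!all(is.na(g)) && any(diff(g) < 0, na.rm = TRUE)) {
      stop("marker_map: pos_cm decreasing on chromosome ", ch)
    }
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

# Numeric sort rank: "1".."29" numeric, "X" after all autosomes.
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom %in% c("X", "x")] <- 1e6
  r[is.na(r)] <- 2e6  # unknown labels sort last, stably
  r
}

#' Genetic map positions for a marker map
#'
#' Returns per-marker genetic positions in centimorgans. If the map carries
#' `pos_cm` they are used directly; otherwise positions are derived from
#' physical positions at a uniform rate (default 1 cM/Mb, the genome-average
#' assumption used when no linkage map is available for the marker set).
#'
#' @param map a [marker_map()].
#' @param cm_per_mb uniform recombination rate used when `pos_cm` is absent.
#' @return numeric vector of cM positions, parallel to the map rows.
#' @export
genetic_positions <- function(map, cm_per_mb = 1) {
  stopifnot(inherits(map, "marker_map"))
  if (!all(is.na(map$pos_cm))) {
    if (anyNA(map$pos_cm)) stop("genetic_positions: partial pos_cm column")
    return(map$pos_cm)
  }
  map$pos_bp * cm_per_mb / 1e6
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers on %d chromosome(s) [%s]\n",
              nrow(x), length(unique(x$chrom)),
              paste(utils::head(unique(x$chrom), 8), collapse = ", ")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Split map row indices by chromosome, in canonical chromosome order.
map_chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
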