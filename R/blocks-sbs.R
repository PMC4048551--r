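#' Call ancestry blocks from a painting
#'
#' Thresholds the per-site panel-A posterior into three marker labels —
#' A when prob_A > threshold, B when prob_A < 1 - threshold, uncertain in
#' between (ties at the threshold are uncertain) — then merges runs of
#' identical labels into blocks. Block boundaries fall at the midpoint
#' between adjacent markers with different labels; the first and last
#' blocks end at the first/last marker positions, so blocks exactly tile
#' the marker span. Lengths are in base pairs, 0-based half-open.
#'
#' @param painting an [ancestry_painting()].
#' @param threshold posterior probability above which a marker is assigned
#'   to a panel (default 0.75, i.e. markers between 0.25 and 0.75 are
#'   uncertain); must lie in (0.5, 1).
#' @return a [block_set()] covering every haplotype and chromosome.
#' @export
call_blocks <- function(painting, threshold = 0.75) {
  stopifnot(inherits(painting, "ancestry_painting"))
  if (threshold <= 0.5 || threshold >= 1) {
    stop("call_blocks: threshold must lie in (0.5, 1)")
  }
  map <- painting$map
  idx_by_chrom <- map_chrom_index(map)
  out <- vector("list", length(idx_by_chrom) * nrow(painting$prob_A))
  k <- 0
  for (idx in idx_by_chrom) {
    ch <- map$chrom[idx[1]]
    pos <- map$pos_bp[idx]
    if (length(idx) == 1) {
      warning("call_blocks: chromosome ", ch,
              " has a single marker; zero-length blocks")
    }
    for (i in seq_len(nrow(painting$prob_A))) {
      p <- painting$prob_A[i, idx]
      lab <- ifelse(p > threshold, "A",
                    ifelse(p < 1 - threshold, "B", "uncertain"))
      r <- rle(lab)
      ends_i <- cumsum(r$lengths)         # last marker index of each run
      starts_i <- c(1, utils::head(ends_i, -1) + 1)
      cuts <- if (length(ends_i) > 1) {
        (pos[ends_i[-length(ends_i)]] + pos[starts_i[-1]]) / 2
      } else numeric(0)
      start_bp <- c(pos[1], cuts)
      end_bp <- c(cuts, pos[length(pos)])
      k <- k + 1
      out[[k]] <- data.frame(haplotype_id = painting$haplotype_ids[i],
                             chrom = ch, start_bp = start_bp,
                             end_bp = end_bp, label = r$values,
                             stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out[seq_len(k)])
  span <- do.call(rbind, lapply(idx_by_chrom, function(idx) {
    data.frame(chrom = map$chrom[idx[1]], span_start = map$pos_bp[idx[1]],
               span_end = map$pos_bp[idx[length(idx)]],
               stringsAsFactors = FALSE)
  }))
  rownames(span) <- NULL
  block_set(blocks, span = span)
}

#' Determine the minority (introgressed) ancestry of an individual
#'
#' Over all autosomal blocks of both haplotypes, the ancestry with the
#' smaller total labelled length is the introgressed genome; the other is
#' the parental genome. Uncertain intervals count in neither numerator nor
#' denominator. An exact 50/50 split has no majority ancestor and is an
#' error.
#'
#' @param blocks a [block_set()] holding one individual's haplotypes.
#' @return list with `minority` ("A" or "B") and `fraction` (minority bp /
#'   labelled bp, in \[0, 0.5)).
#' @export
minority_label <- function(blocks) {
  stopifnot(inherits(blocks, "block_set"))
  auto <- blocks[blocks$chrom != "X", , drop = FALSE]
  len <- auto$end_bp - auto$start_bp
  bp_A <- sum(len[auto$label == "A"])
  bp_B <- sum(len[auto$label == "B"])
  if (bp_A + bp_B == 0) stop("minority_label: no labelled ancestry")
  if (bp_A == bp_B) stop("minority_label: exact 50/50 tie, no majority ancestor")
  minority <- if (bp_A < bp_B) "A" else "B"
  list(minority = minority, fraction = min(bp_A, bp_B) / (bp_A + bp_B))
}

#' Scaled block size of one haplotype-chromosome
#'
#' With minority-block lengths b_1..b_k expressed as proportions of the
#' chromosome span and p = sum(b_i) the chromosome's introgressed
#' proportion, the scaled block size is median(b_i) / p. A chromosome with
#' a single introgressed block scores exactly 1; recombination splits the
#' introgressed material into more, smaller blocks and drives the score
#' toward 0. With no minority block the value is undefined (`NA`).
#'
#' @param blocks a [block_set()] restricted to one haplotype-chromosome.
#' @param minority the individual's minority label ("A" or "B").
#' @param span_bp the chromosome's first-to-last-marker extent in bp.
#' @return scaled value in (0, 1\], or `NA` when the haplotype-chromosome
#'   carries no minority block.
#' @export
chromosome_sbs <- function(blocks, minority, span_bp) {
  if (span_bp <= 0) stop("chromosome_sbs: span_bp must be positive")
  b <- (blocks$end_bp - blocks$start_bp)[blocks$label == minority] / span_bp
  b <- b[b > 0]
  if (!length(b)) return(NA_real_)
  stats::median(b) / sum(b)
}

#' Per-individual scaled block size
#'
#' Averages defined haplotype-autosome components into the individual's
#' SBS (undefined components — chromosomes without introgressed blocks —
#' are excluded from the mean). An individual with no defined component is
#' reported non-admixed (`NA` SBS).
#'
#' @param components numeric vector of per-(haplotype, autosome) scaled
#'   values, `NA` where undefined.
#' @param minority list from [minority_label()].
#' @param individual sample identifier.
#' @return one-row data.frame: `individual`, `sbs`, `n_defined`,
#'   `minority`, `minority_fraction`.
#' @export
individual_sbs <- function(components, minority, individual = "ind") {
  def <- components[!is.na(components)]
  data.frame(individual = individual,
             sbs = if (length(def)) mean(def) else NA_real_,
             n_defined = length(def), minority = minority$minority,
             minority_fraction = minority$fraction,
             stringsAsFactors = FALSE)
}

#' Scaled block sizes for every individual in a block set
#'
#' Groups haplotypes `<sample>_0`/`<sample>_1` by individual, determines
#' each individual's genome-wide minority ancestry once, computes the
#' scaled block size of every autosomal haplotype-chromosome, and averages
#' the defined components.
#'
#' @param blocks a [block_set()] for a cohort (autosomes; X blocks are
#'   ignored).
#' @return an `sbs_result` data.frame, one row per individual, with the
#'   per-component table in attribute `components`.
#' @export
sbs <- function(blocks) {
  stopifnot(inherits(blocks, "block_set"))
  span <- attr(blocks, "span")
  span_of <- stats::setNames(span$span_end - span$span_start, span$chrom)
  ind <- hap_individual(blocks$haplotype_id)
  rows <- list(); comps <- list()
  for (id in unique(ind)) {
    b_ind <- block_set(blocks[ind == id, , drop = FALSE], span = span)
    minor <- minority_label(b_ind)
    auto <- b_ind[b_ind$chrom != "X", , drop = FALSE]
    key <- interaction(auto$haplotype_id, auto$chrom, drop = TRUE)
    comp <- vapply(split(seq_len(nrow(auto)), key), function(ii) {
      chromosome_sbs(auto[ii, , drop = FALSE], minor$minority,
                     span_of[[auto$chrom[ii[1]]]])
    }, numeric(1))
    rows[[id]] <- individual_sbs(comp, minor, id)
    comps[[id]] <- data.frame(individual = id,
                              component = names(comp), value = unname(comp),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$individual), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, components = do.call(rbind, comps),
            class = c("sbs_result", "data.frame"))
}

#' @export
print.sbs_result <- function(x, ...) {
  cat(sprintf("sbs_result: %d individuals (mean SBS %.3f, %d undefined)\n",
              nrow(x), mean(x$sbs, na.rm = TRUE), sum(is.na(x$sbs))))
  print(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.sbs_result <- function(object, ...) {
  cat("Scaled block size summary\n")
  print(summary(object$sbs))
  cat(sprintf("minority ancestry: %s\n",
              paste(names(table(object$minority)), table(object$minority),
                    sep = "=", collapse = " ")))
  invisible(object)
}

#' Classify recently admixed individuals against known-hybrid standards
#'
#' Large scaled block sizes mark recent admixture. The lowest SBS among
#' the known recent hybrids serves as the lower cutoff; any individual at
#' or above it is flagged as likely recently admixed (references
#' therefore always self-classify as recent). Individuals with undefined
#' SBS are non-admixed and never flagged.
#'
#' @param results an `sbs_result` from [sbs()].
#' @param reference_ids ids of known recently admixed individuals present
#'   in `results`.
#' @return data.frame `individual`, `sbs`, `recent` (logical), with the
#'   cutoff in attribute `cutoff`.
#' @export
classify_recent <- function(results, reference_ids) {
  stopifnot(inherits(results, "sbs_result"))
  ref <- results$sbs[results$individual %in% reference_ids]
  ref <- ref[!is.na(ref)]
  if (!length(ref)) {
    stop("classify_recent: no reference individual with a defined SBS")
  }
  cutoff <- min(ref)
  flag <- !is.na(results$sbs) & results$sbs >= cutoff
  structure(data.frame(individual = results$individual, sbs = results$sbs,
                       recent = flag, stringsAsFactors = FALSE),
            cutoff = cutoff)
}
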