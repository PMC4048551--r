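#' Read genotypes from PLINK text files
#'
#' Parses a standard PLINK-text pair: a 4-column `.map`
#' (chrom, name, cM, bp) and a `.ped` with the 6-column sample prefix
#' followed by two allele columns per marker. The breed/group label is taken
#' from the family-ID column. Allele code "0" means missing; markers must be
#' biallelic. After reading, markers are in canonical (chrom, pos_bp) order
#' and genotype columns are permuted to match.
#'
#' Genotypes are coded as copies of the reference allele, where the
#' reference at each marker is the lexicographically smaller of its two
#' observed allele symbols (a stable convention; downstream statistics are
#' symmetric in allele coding).
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return list with elements `genotypes` (a [genotype_table()]) and `map`
#'   (a [marker_map()]).
#' @export
read_genotypes <- function(ped_path, map_path) {
  map <- read_plink_map(map_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_genotypes: empty .ped file: ", ped_path)
  n_mark <- nrow(map)
  n_ind <- length(lines)
  a1 <- matrix(NA_character_, n_ind, n_mark)
  a2 <- matrix(NA_character_, n_ind, n_mark)
  breed <- character(n_ind)
  ids <- character(n_ind)
  for (i in seq_len(n_ind)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * n_mark) {
      stop(sprintf(
        "read_genotypes: %s line %d has %d fields, expected %d (map %s has %d markers)",
        ped_path, i, length(f), 6 + 2 * n_mark, map_path, n_mark))
    }
    breed[i] <- f[1]
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, length(al), by = 2)]
    a2[i, ] <- al[seq(2, length(al), by = 2)]
  }
  calls <- matrix(NA_integer_, n_ind, n_mark)
  read_order <- attr(map, "read_order")
  for (j in seq_len(n_mark)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- setdiff(unique(c(x1, x2)), "0")
    if (length(obs) > 2) {
      stop("read_genotypes: marker ", attr(map, "read_names")[j],
           " has >2 alleles: ", paste(sort(obs), collapse = "/"))
    }
    ref <- if (length(obs)) sort(obs)[1] else NA_character_
    miss <- x1 == "0" | x2 == "0"
    if (!is.na(ref)) {
      calls[, j] <- (x1 == ref) + (x2 == ref)
    } else {
      calls[, j] <- NA_integer_
    }
    calls[miss, j] <- NA_integer_
  }
  # permute ped columns (read order) into the map's canonical order
  calls <- calls[, read_order, drop = FALSE]
  attr(map, "read_order") <- NULL
  attr(map, "read_names") <- NULL
  list(genotypes = genotype_table(calls, ids, breed, map), map = map)
}

read_plink_map <- function(map_path) {
  raw <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 4) {
    stop("read_genotypes: ", map_path, " must have 4 columns, has ",
         ncol(raw))
  }
  pos_cm <- as.numeric(raw[[3]])
  if (all(pos_cm == 0, na.rm = TRUE)) pos_cm <- NULL  # PLINK placeholder
  map <- marker_map(chrom = raw[[1]], name = raw[[2]],
                    pos_bp = as.numeric(raw[[4]]), pos_cm = pos_cm)
  attr(map, "read_order") <- match(map$name, raw[[2]])
  attr(map, "read_names") <- raw[[2]]
  map
}

#' Write genotypes to PLINK text files
#'
#' Inverse of [read_genotypes()]. Alleles are written as "A"/"B" symbols
#' (reference count 2 -> "A A", 1 -> "A B", 0 -> "B B", missing -> "0 0").
#'
#' @param gt a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @export
write_genotypes <- function(gt, ped_path, map_path) {
  stopifnot(inherits(gt, "genotype_table"))
  map <- gt$map
  cm <- if (all(is.na(map$pos_cm))) rep(0, nrow(map)) else map$pos_cm
  utils::write.table(
    data.frame(map$chrom, map$name, cm, format(map$pos_bp, scientific = FALSE,
                                               trim = TRUE)),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  gmap <- c("B B", "A B", "A A")
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(gt$individuals)) {
    g <- gt$calls[i, ]
    al <- ifelse(is.na(g), "0 0", gmap[g + 1])
    writeLines(paste(c(gt$breed[i], gt$individuals[i], "0", "0", "0", "-9",
                       al), collapse = " "), con)
  }
  invisible(NULL)
}

#' Read phased haplotypes from TSV
#'
#' The haplotype TSV dialect has a header
#' `haplotype_id<TAB>breed<TAB>m1<TAB>m2...` and one row per haplotype with
#' alleles coded 0/1 and "." for missing.
#'
#' @param tsv_path path to the haplotype TSV.
#' @param map_path path to the 4-column `.map` for the same markers, or an
#'   already-read [marker_map()].
#' @return list with elements `haplotypes` (a [haplotype_panel()]) and
#'   `map`.
#' @export
read_haplotypes <- function(tsv_path, map_path) {
  map <- if (inherits(map_path, "marker_map")) map_path else {
    m <- read_plink_map(map_path)
    attr(m, "read_order") <- NULL; attr(m, "read_names") <- NULL
    m
  }
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("read_haplotypes: empty file: ", tsv_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n_mark <- length(header) - 2
  if (n_mark != nrow(map)) {
    stop(sprintf("read_haplotypes: %s has %d marker columns but map has %d",
                 tsv_path, n_mark, nrow(map)))
  }
  body <- lines[-1]
  n <- length(body)
  alleles <- matrix(NA_integer_, n, n_mark)
  ids <- character(n); labels <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_mark + 2) {
      stop(sprintf("read_haplotypes: %s line %d has %d fields, expected %d",
                   tsv_path, i + 1, length(f), n_mark + 2))
    }
    ids[i] <- f[1]; labels[i] <- f[2]
    a <- f[-(1:2)]
    bad <- !a %in% c("0", "1", ".")
    if (any(bad)) {
      stop(sprintf("read_haplotypes: %s line %d: invalid allele '%s'",
                   tsv_path, i + 1, a[which(bad)[1]]))
    }
    a[a == "."] <- NA
    alleles[i, ] <- as.integer(a)
  }
  list(haplotypes = haplotype_panel(alleles, ids, labels, map), map = map)
}

#' Write phased haplotypes to TSV
#'
#' Inverse of [read_haplotypes()].
#'
#' @param panel a [haplotype_panel()].
#' @param tsv_path output path.
#' @export
write_haplotypes <- function(panel, tsv_path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  con <- file(tsv_path, "w")
  on.exit(close(con))
  writeLines(paste(c("haplotype_id", "breed", panel$map$name),
                   collapse = "\t"), con)
  for (i in seq_along(panel$haplotype_ids)) {
    a <- panel$alleles[i, ]
    a <- ifelse(is.na(a), ".", as.character(a))
    writeLines(paste(c(panel$haplotype_ids[i], panel$labels[i], a),
                     collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Write an ancestry painting matrix to TSV
#'
#' One row per haplotype; first column the haplotype id, then one panel-A
#' posterior per marker at 6 significant digits.
#'
#' @param painting an [ancestry_painting()].
#' @param path output path.
#' @export
write_painting <- function(painting, path) {
  stopifnot(inherits(painting, "ancestry_painting"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("haplotype_id", painting$map$name), collapse = "\t"),
             con)
  for (i in seq_along(painting$haplotype_ids)) {
    writeLines(paste(c(painting$haplotype_ids[i],
                       signif6(painting$prob_A[i, ])), collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read an ancestry painting matrix from TSV
#'
#' @param path painting TSV written by [write_painting()].
#' @param map the matching [marker_map()].
#' @return an [ancestry_painting()].
#' @export
read_painting <- function(path, map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
  if (ncol(tab) - 1 != nrow(map)) {
    stop(sprintf("read_painting: %s has %d marker columns but map has %d",
                 path, ncol(tab) - 1, nrow(map)))
  }
  prob <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(prob) <- "double"
  ancestry_painting(prob, as.character(tab[[1]]), map)
}

#' Write ancestry blocks to a BED-like table
#'
#' BED5-like format with a "#"-prefixed header:
#' `chrom  start  end  label  haplotype_id`, 0-based half-open, sorted by
#' (haplotype_id, chrom, start).
#'
#' @param blocks a [block_set()].
#' @param path output path.
#' @export
write_blocks <- function(blocks, path) {
  stopifnot(inherits(blocks, "block_set"))  # constructor enforced tiling
  span <- attr(blocks, "span")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tlabel\thaplotype_id", con)
  for (i in seq_len(nrow(span))) {
    writeLines(sprintf("#span\t%s\t%s\t%s", span$chrom[i],
                       format(span$span_start[i], scientific = FALSE),
                       format(span$span_end[i], scientific = FALSE)), con)
  }
  ord <- order(blocks$haplotype_id, chrom_rank(blocks$chrom),
               blocks$start_bp)
  b <- blocks[ord, , drop = FALSE]
  if (nrow(b)) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", b$chrom,
                       format(b$start_bp, scientific = FALSE, trim = TRUE),
                       format(b$end_bp, scientific = FALSE, trim = TRUE),
                       b$label, b$haplotype_id), con)
  }
  invisible(NULL)
}

#' Read ancestry blocks written by [write_blocks()]
#'
#' @param path block BED path.
#' @return a [block_set()].
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  spans <- lines[startsWith(lines, "#span")]
  body <- lines[!startsWith(lines, "#")]
  span <- NULL
  if (length(spans)) {
    f <- do.call(rbind, strsplit(spans, "\t", fixed = TRUE))
    span <- data.frame(chrom = f[, 2], span_start = as.numeric(f[, 3]),
                       span_end = as.numeric(f[, 4]),
                       stringsAsFactors = FALSE)
  }
  if (!length(body)) {
    return(block_set(data.frame(haplotype_id = character(),
                                chrom = character(), start_bp = numeric(),
                                end_bp = numeric(), label = character()),
                     span = span))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 5)) {
    stop(sprintf("read_blocks: %s line %d has %d fields, expected 5",
                 path, which(nf != 5)[1], nf[nf != 5][1]))
  }
  f <- do.call(rbind, f)
  block_set(data.frame(haplotype_id = f[, 5], chrom = f[, 1],
                       start_bp = as.numeric(f[, 2]),
                       end_bp = as.numeric(f[, 3]), label = f[, 4],
                       stringsAsFactors = FALSE), span = span)
}

# 6-significant-digit float formatting shared by all writers.
signif6 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = 6, format = "g")
  }, character(1))
  out
}

#' Write a result table to TSV
#'
#' Generic result writer: TSV with header, floats at 6 significant digits,
#' rows sorted by the first column (the primary key) for deterministic
#' output.
#'
#' @param rows a data.frame of homogeneous records.
#' @param path output path.
#' @param sort_by column name used as primary key; defaults to the first
#'   column.
#' @export
write_table <- function(rows, path, sort_by = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows)) {
    key <- if (is.null(sort_by)) names(rows)[1] else sort_by
    rows <- rows[order(rows[[key]]), , drop = FALSE]
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif6(out[[j]])
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read a flat key:value configuration file
#'
#' Flat YAML mapping of scalar values; unknown keys are rejected against
#' the set of recognised pipeline parameters (see [default_config()]).
#'
#' @param path YAML file of `key: value` pairs.
#' @param known character vector of accepted keys; defaults to the pipeline
#'   parameter set.
#' @return named list of configuration values.
#' @export
read_config <- function(path, known = names(default_config())) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}
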