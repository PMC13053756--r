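#' Read a BED file of candidate cis-regulatory regions
#'
#' Coordinates are kept in BED convention: 0-based, half-open
#' `[start, end)`. Region ids come from the BED name column when present,
#' otherwise they are synthesized as `"chrom:start-end"`.
#'
#' @param path Path to a 3+-column BED file (no header).
#' @return A tibble with columns `region_id`, `chrom`, `start`, `end`.
#' @export
read_region_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("Empty BED file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3)
  if (length(bad) > 0) {
    abort(sprintf("Malformed BED line %d in %s: fewer than 3 columns.", bad[1], path))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("Malformed BED line %d in %s: non-numeric coordinates.", bad, path))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid region at line %d in %s: start (%d) >= end (%d).",
      bad[1], path, start[bad[1]], end[bad[1]]
    ))
  }
  region_id <- ifelse(
    ncols >= 4,
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", ""),
    sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  )
  region_id[!nzchar(region_id)] <-
    sprintf("%s:%d-%d", chrom, start, end)[!nzchar(region_id)]
  out <- tibble(
    region_id = region_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end)
  )
  validate_region_table(out)
  out
}

validate_region_table <- function(regions) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  if (anyDuplicated(regions$region_id)) {
    abort("Region ids must be unique.")
  }
  if (anyNA(regions$start) || anyNA(regions$end)) {
    abort("Region coordinates must not be missing.")
  }
  if (any(regions$start >= regions$end)) abort("All regions need start < end.")
  invisible(regions)
}

#' Write a region table back to BED
#'
#' @param regions Tibble as returned by [read_region_table()].
#' @param path Output path.
#' @export
write_region_table <- function(regions, path) {
  validate_region_table(regions)
  readr::write_tsv(
    regions[, c("chrom", "start", "end", "region_id")],
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read Bismark coverage output into a CpG count table
#'
#' Bismark coverage files are 1-based with columns chrom, start, end,
#' methylation percentage, methylated count, unmethylated count. Positions
#' are converted to 0-based on read; counts are taken from columns 5-6 and
#' the percentage column is ignored (it is recomputable). A percentage
#' inconsistent with the counts triggers a warning; the counts win.
#'
#' @param path Path to a Bismark `.cov`-format file (tab or space separated).
#' @param sample_id Sample label attached to every row.
#' @return A tibble with columns `chrom`, `position` (0-based),
#'   `count_methylated`, `count_unmethylated`, `sample_id`.
#' @export
read_methylation_counts <- function(path, sample_id) {
  raw <- utils::read.table(
    path,
    col.names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    colClasses = c("character", "integer", "integer", "numeric", "numeric", "numeric")
  )
  if (any(raw$meth < 0) || any(raw$unmeth < 0)) {
    abort(sprintf("Negative read counts in %s.", path))
  }
  tot <- raw$meth + raw$unmeth
  recomputed <- ifelse(tot > 0, 100 * raw$meth / tot, NA_real_)
  off <- which(tot > 0 & abs(recomputed - raw$pct) > 0.5)
  if (length(off) > 0) {
    warn(sprintf(
      "%d row(s) in %s have a methylation %% inconsistent with the counts; counts are used.",
      length(off), path
    ))
  }
  out <- tibble(
    chrom = raw$chrom,
    position = raw$start - 1L, # Bismark is 1-based; internal convention is 0-based
    count_methylated = as.integer(raw$meth),
    count_unmethylated = as.integer(raw$unmeth),
    sample_id = sample_id
  )
  if (anyDuplicated(out[, c("chrom", "position", "sample_id")])) {
    abort(sprintf("Duplicate (chrom, position) rows in %s.", path))
  }
  out
}

#' Read a TSS/promoter annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `tss`, `strand`.
#' @return A tibble with those columns.
#' @export
read_tss_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", chrom = "c",
                           tss = "i", strand = "c"
                         ))
  if (!all(out$strand %in% c("+", "-"))) abort("Strand must be '+' or '-'.")
  if (anyNA(out$tss)) abort("TSS positions must not be missing.")
  out
}

#' Motif-by-region ranking matrix
#'
#' Container for per-motif rankings of candidate regions: entry `[l, r]` is
#' the rank of region `r` for motif `l` (rank 1 = best sequence match), so
#' each motif row is a permutation of `1..R`. Each motif maps to a TF gene
#' id via `tf_map`.
#'
#' @param rank A motif x region integer matrix with dimnames; each row a
#'   permutation of `1..ncol(rank)`.
#' @param tf_map Tibble with columns `motif_id`, `tf_id`; defaults to the
#'   identity map (motif ids used directly as TF ids).
#' @return An object of class `motif_ranking`.
#' @export
motif_ranking <- function(rank, tf_map = NULL) {
  if (is.null(rownames(rank)) || is.null(colnames(rank))) {
    abort("`rank` needs motif row names and region column names.")
  }
  storage.mode(rank) <- "integer"
  R <- ncol(rank)
  for (l in seq_len(nrow(rank))) {
    if (!identical(sort(unname(rank[l, ])), seq_len(R))) {
      abort(sprintf(
        "Motif '%s': ranks are not a permutation of 1..%d.", rownames(rank)[l], R
      ))
    }
  }
  if (is.null(tf_map)) {
    tf_map <- tibble(motif_id = rownames(rank), tf_id = rownames(rank))
  }
  if (!all(rownames(rank) %in% tf_map$motif_id)) {
    abort("Every motif must map to at least one TF id.")
  }
  structure(
    list(rank = rank, motif_ids = rownames(rank),
         region_ids = colnames(rank), tf_map = as_tibble(tf_map)),
    class = "motif_ranking"
  )
}

#' @export
print.motif_ranking <- function(x, ...) {
  cat(sprintf(
    "<motif_ranking> %d motifs x %d regions (%d TFs)\n",
    length(x$motif_ids), length(x$region_ids),
    dplyr::n_distinct(x$tf_map$tf_id)
  ))
  invisible(x)
}

#' Read a motif-ranking TSV
#'
#' Expects a header row naming the regions, a first column `motif_id`, and
#' integer rank entries; each row must be a permutation of `1..R`.
#'
#' @param path TSV path.
#' @inheritParams motif_ranking
#' @return A `motif_ranking` object.
#' @export
read_motif_rankings <- function(path, tf_map = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "motif_id") abort("First column must be 'motif_id'.")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$motif_id
  motif_ranking(m, tf_map = tf_map)
}

#' Write a motif-ranking object to TSV
#' @param rankings A `motif_ranking` object.
#' @param path Output path.
#' @export
write_motif_rankings <- function(rankings, path) {
  tab <- as_tibble(rankings$rank, rownames = "motif_id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read / write weighted TF -> target edge lists
#'
#' Round-trips are lossless on ids, weights (to 1e-12) and the selection
#' flag. Duplicate (tf, target) pairs or negative weights are rejected.
#'
#' @param edges Tibble with columns `tf_id`, `target_id`, `weight`,
#'   `selected`.
#' @param path File path.
#' @return `read_edge_list` returns the edge tibble.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("tf_id", "target_id", "weight", "selected") %in% names(edges)))
  readr::write_tsv(edges[, c("tf_id", "target_id", "weight", "selected")], path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           tf_id = "c", target_id = "c",
                           weight = "d", selected = "l"
                         ))
  if (anyDuplicated(out[, c("tf_id", "target_id")])) {
    abort(sprintf("Duplicate (tf, target) pair in %s.", path))
  }
  if (any(out$weight < 0)) abort(sprintf("Negative edge weight in %s.", path))
  out
}

#' Read / write an expression matrix as TSV
#'
#' Genes are rows, samples are columns; the first column (`gene_id`) holds
#' gene ids. `normalized` records whether values are CPM-scaled already.
#'
#' @param path TSV path.
#' @param normalized Logical flag stored on the returned matrix.
#' @return A numeric genes x samples matrix with a `normalized` attribute.
#' @export
read_expression_matrix <- function(path, normalized = FALSE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("Expression values must be non-negative.")
  attr(m, "normalized") <- normalized
  m
}

#' @rdname read_expression_matrix
#' @param expr Genes x samples matrix.
#' @export
write_expression_matrix <- function(expr, path) {
  tab <- as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read an expression matrix from MatrixMarket (MTX) files
#'
#' @param mtx_path Path to the `.mtx` file (genes x cells).
#' @param genes_path,cells_path One-id-per-line text files for row and
#'   column names.
#' @inheritParams read_expression_matrix
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path,
                                normalized = FALSE) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    abort("The Matrix package is required to read MTX files.")
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(cells_path)
  if (any(m < 0)) abort("Expression values must be non-negative.")
  attr(m, "normalized") <- normalized
  m
}

#' Read / write a region-by-sample signal matrix in long TSV form
#'
#' Long format with columns `region_id`, `sample_id`, `value`, `covered`.
#' Uncovered entries may carry `NA` values.
#'
#' @param path TSV path.
#' @param type `"rate"` (DNAme rates in `[0,1]`) or `"binary"` (peaks).
#' @export
read_region_signal <- function(path, type = c("rate", "binary")) {
  type <- match.arg(type)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           region_id = "c", sample_id = "c",
                           value = "d", covered = "l"
                         ))
  regions <- unique(tab$region_id)
  samples <- unique(tab$sample_id)
  value <- matrix(NA_real_, length(regions), length(samples),
                  dimnames = list(regions, samples))
  coverage <- matrix(FALSE, length(regions), length(samples),
                     dimnames = list(regions, samples))
  value[cbind(tab$region_id, tab$sample_id)] <- tab$value
  coverage[cbind(tab$region_id, tab$sample_id)] <- tab$covered
  region_signal(value, coverage, type = type)
}

#' @rdname read_region_signal
#' @param signal A `region_signal` object.
#' @export
write_region_signal <- function(signal, path) {
  tab <- tidyr::expand_grid(
    region_id = signal$region_ids,
    sample_id = signal$sample_ids
  )
  tab$value <- signal$value[cbind(tab$region_id, tab$sample_id)]
  tab$covered <- signal$coverage[cbind(tab$region_id, tab$sample_id)]
  readr::write_tsv(tab, path)
  invisible(path)
}
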