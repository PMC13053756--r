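#' Region-by-sample epigenomic signal matrix
#'
#' Holds one epigenomic value per (region, sample): a region-averaged DNAme
#' rate in `[0, 1]` (`type = "rate"`) or a binary peak-presence indicator
#' (`type = "binary"`), plus a coverage mask marking which entries carry
#' data.
#'
#' @param value Region x sample numeric matrix with dimnames. `NA` allowed
#'   where coverage is `FALSE`.
#' @param coverage Logical matrix of the same shape; `TRUE` where the entry
#'   has data.
#' @param type `"rate"` or `"binary"`.
#' @return An object of class `region_signal`.
#' @export
region_signal <- function(value, coverage = NULL, type = c("rate", "binary")) {
  type <- match.arg(type)
  if (is.null(rownames(value)) || is.null(colnames(value))) {
    abort("`value` needs region row names and sample column names.")
  }
  if (is.null(coverage)) {
    coverage <- !is.na(value)
    dimnames(coverage) <- dimnames(value)
  }
  stopifnot(identical(dim(value), dim(coverage)))
  v <- value[coverage]
  if (type == "rate" && any(v < 0 | v > 1, na.rm = TRUE)) {
    abort("DNAme rates must lie in [0, 1] where covered.")
  }
  if (type == "binary" && !all(v %in% c(0, 1))) {
    abort("Binary signal must be 0/1 where covered.")
  }
  structure(
    list(value = value, coverage = coverage, type = type,
         region_ids = rownames(value), sample_ids = colnames(value)),
    class = "region_signal"
  )
}

#' @export
print.region_signal <- function(x, ...) {
  cat(sprintf(
    "<region_signal:%s> %d regions x %d samples (%.1f%% covered)\n",
    x$type, length(x$region_ids), length(x$sample_ids),
    100 * mean(x$coverage)
  ))
  invisible(x)
}

#' Aggregate CpG-level methylation counts over regions
#'
#' For each region and sample, methylated and unmethylated read counts are
#' summed over the CpG sites falling inside the region, and the region
#' DNAme rate is the methylated fraction. Entries whose total read count is
#' below `min_reads` are marked uncovered. Averaging over regions mitigates
#' the noise of individual CpG calls.
#'
#' @param cpgs CpG count tibble as from [read_methylation_counts()]
#'   (0-based positions), possibly row-bound over samples.
#' @param regions Region tibble (0-based half-open) as from
#'   [read_region_table()].
#' @param min_reads Minimum total reads for a (region, sample) entry to
#'   count as covered. Default 10.
#' @return A `region_signal` of type `"rate"`.
#' @export
aggregate_region_methylation <- function(cpgs, regions, min_reads = 10) {
  validate_region_table(regions)
  if (nrow(regions) == 0) abort("Empty region set.")
  if (any(cpgs$count_methylated < 0) || any(cpgs$count_unmethylated < 0)) {
    abort("CpG counts must be non-negative.")
  }
  samples <- sort(unique(cpgs$sample_id))
  # 0-based half-open [start, end) -> 1-based closed [start+1, end]
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end)
  )
  cpg_gr <- GenomicRanges::GRanges(
    cpgs$chrom,
    IRanges::IRanges(cpgs$position + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(cpg_gr, reg_gr)
  value <- matrix(NA_real_, nrow(regions), length(samples),
                  dimnames = list(regions$region_id, samples))
  coverage <- matrix(FALSE, nrow(regions), length(samples),
                     dimnames = dimnames(value))
  if (length(hits) == 0) {
    warn("No CpG site falls inside any region; all entries uncovered.")
    return(region_signal(value, coverage, type = "rate"))
  }
  agg <- tibble(
    region_id = regions$region_id[S4Vectors::subjectHits(hits)],
    sample_id = cpgs$sample_id[S4Vectors::queryHits(hits)],
    meth = cpgs$count_methylated[S4Vectors::queryHits(hits)],
    unmeth = cpgs$count_unmethylated[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::group_by(.data$region_id, .data$sample_id) |>
    dplyr::summarise(
      meth = sum(.data$meth), unmeth = sum(.data$unmeth), .groups = "drop"
    ) |>
    dplyr::mutate(
      total = .data$meth + .data$unmeth,
      rate = ifelse(.data$total > 0, .data$meth / .data$total, NA_real_)
    )
  idx <- cbind(agg$region_id, agg$sample_id)
  value[idx] <- agg$rate
  coverage[idx] <- agg$total >= min_reads
  value[!coverage] <- ifelse(is.na(value[!coverage]), NA_real_, value[!coverage])
  region_signal(value, coverage, type = "rate")
}

#' Regions matched by a motif
#'
#' A region counts as "matched" by a motif when its rank for that motif is
#' within the top `top_frac` fraction, i.e. `rank <= ceiling(top_frac * R)`.
#' The match cutoff is a package parameter.
#'
#' @param rankings A `motif_ranking` object.
#' @param motif Motif id.
#' @param top_frac Fraction of best-ranked regions that count as matched
#'   (default 0.05).
#' @return Character vector of matched region ids.
#' @export
matched_regions <- function(rankings, motif, top_frac = 0.05) {
  stopifnot(inherits(rankings, "motif_ranking"))
  if (!(top_frac > 0 && top_frac <= 1)) abort("`top_frac` must be in (0, 1].")
  if (!motif %in% rankings$motif_ids) {
    abort(sprintf("Unknown motif id '%s'.", motif))
  }
  k <- ceiling(top_frac * length(rankings$region_ids))
  r <- rankings$rank[motif, ]
  rankings$region_ids[r <= k]
}

#' Assign regions to their closest gene promoter
#'
#' Each region is assigned to the gene whose TSS is nearest, with distance
#' 0 when the TSS falls inside the region and otherwise the gap to the
#' closer interval boundary (half-open convention: a TSS 300 bp past `end`
#' is at distance 300). Assignments at or beyond `max_dist` are dropped
#' (candidate cis-regulation requires the promoter within 5 kb by default);
#' distance ties break by lexicographic gene id.
#'
#' @param regions Region tibble (0-based half-open).
#' @param tss TSS tibble as from [read_tss_table()].
#' @param max_dist Drop assignments with distance >= this (default 5000 bp).
#' @return Tibble with columns `region_id`, `gene_id`, `distance`.
#' @export
assign_regions_to_genes <- function(regions, tss, max_dist = 5000) {
  validate_region_table(regions)
  if (nrow(tss) == 0) abort("Empty TSS table.")
  pairs <- dplyr::inner_join(
    regions, tss,
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      distance = ifelse(
        .data$tss >= .data$start & .data$tss < .data$end,
        0L,
        pmin(abs(.data$tss - .data$start), abs(.data$tss - .data$end))
      )
    ) |>
    dplyr::filter(.data$distance < max_dist) |>
    dplyr::arrange(.data$region_id, .data$distance, .data$gene_id) |>
    dplyr::distinct(.data$region_id, .keep_all = TRUE)
  pairs[, c("region_id", "gene_id", "distance")]
}

#' Epigenomic prior network
#'
#' Target-specific candidate-regulator sets: for each target gene `i` the
#' TFs whose motifs are both significantly associated with the epigenomic
#' signal and matched in a region assigned to `i`'s promoter.
#'
#' @param edges Tibble with columns `tf_id`, `target_id`.
#' @param support Tibble with columns `tf_id`, `target_id`, `region_id`
#'   recording the cis-regulatory regions supporting each edge (may be
#'   empty for synthetic priors).
#' @param method Provenance tag: `"mlc"`, `"methcor"`, `"synthetic"` or
#'   `"uniform"`.
#' @param motif_stats Optional per-motif retention table.
#' @param assoc Optional per-(motif, sample) association table.
#' @return An object of class `prior_network`.
#' @export
prior_network <- function(edges, support = NULL, method = "synthetic",
                          motif_stats = NULL, assoc = NULL) {
  edges <- dplyr::distinct(as_tibble(edges), .data$tf_id, .data$target_id)
  if (is.null(support)) {
    support <- tibble(tf_id = character(), target_id = character(),
                      region_id = character())
  }
  structure(
    list(edges = edges, support = as_tibble(support), method = method,
         motif_stats = motif_stats, assoc = assoc),
    class = "prior_network"
  )
}

#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf(
    "<prior_network:%s> %d candidate regulations: %d TFs -> %d targets\n",
    x$method, nrow(x$edges),
    dplyr::n_distinct(x$edges$tf_id), dplyr::n_distinct(x$edges$target_id)
  ))
  invisible(x)
}

#' Candidate-regulator sets of a prior network
#'
#' @param prior A `prior_network`.
#' @return Named list: target gene id -> character vector of candidate TFs.
#' @export
prior_candidates <- function(prior) {
  stopifnot(inherits(prior, "prior_network"))
  split(prior$edges$tf_id, prior$edges$target_id)
}

#' Uniform (non-specific) prior: every TF a candidate for every target
#'
#' The GENIE3/GRNBoost2-style baseline in which the candidate-regulator
#' list is the full TF set, identical for all targets.
#'
#' @param tf_ids,target_ids Character vectors.
#' @return A `prior_network` with method `"uniform"`.
#' @export
uniform_prior <- function(tf_ids, target_ids) {
  edges <- tidyr::expand_grid(tf_id = tf_ids, target_id = target_ids) |>
    dplyr::filter(.data$tf_id != .data$target_id)
  prior_network(edges, method = "uniform")
}

# Shared engine behind build_prior_mlc / build_prior_methcor.
# stat_fun(score, signal_values) -> statistic in [-1, 1] or an
# epigrn_undefined_statistic condition.
build_prior_engine <- function(signal, rankings, regions, tss, alpha,
                               sample_rule, k, min_covered_samples,
                               top_frac, max_dist, stat_fun, method) {
  stopifnot(inherits(signal, "region_signal"),
            inherits(rankings, "motif_ranking"))
  if (!(alpha >= 0 && alpha <= 1)) abort("`alpha` must be in [0, 1].")
  common <- intersect(rankings$region_ids, signal$region_ids)
  if (length(common) == 0) abort("Rankings and signal share no region ids.")
  n <- length(signal$sample_ids)
  if (is.null(min_covered_samples)) min_covered_samples <- floor(n / 2) + 1
  covered_n <- rowSums(signal$coverage[common, , drop = FALSE])
  eligible <- common[covered_n >= min_covered_samples]
  gene_map <- assign_regions_to_genes(regions, tss, max_dist = max_dist)

  if (length(eligible) == 0) {
    warn("No region meets the coverage rule; prior network is empty.")
    return(prior_network(
      tibble(tf_id = character(), target_id = character()),
      method = method
    ))
  }

  R_all <- length(rankings$region_ids)
  assoc <- purrr::map_dfr(rankings$motif_ids, function(l) {
    # closeness score: higher = better motif match (rank 1 is best)
    score_all <- R_all + 1L - rankings$rank[l, eligible]
    purrr::map_dfr(signal$sample_ids, function(j) {
      has <- signal$coverage[eligible, j]
      idx <- which(has)
      out <- tibble(motif_id = l, sample_id = j, statistic = NA_real_,
                    z = NA_real_, p = NA_real_, R_used = length(idx))
      if (length(idx) < 4) return(out)
      stat <- tryCatch(
        stat_fun(score_all[idx], signal$value[eligible[idx], j]),
        epigrn_undefined_statistic = function(e) NA_real_
      )
      if (is.na(stat)) return(out)
      ft <- fisher_z_test(stat, length(idx))
      out$statistic <- stat
      out$z <- ft$z
      out$p <- ft$p
      out
    })
  })

  motif_stats <- assoc |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(
      n_tested = sum(!is.na(.data$p)),
      n_significant = sum(.data$p < alpha, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      retained = .data$n_tested > 0 & switch(
        sample_rule,
        majority = .data$n_significant > .data$n_tested / 2,
        at_least_k = .data$n_significant >= k
      )
    )

  kept <- motif_stats$motif_id[motif_stats$retained]
  if (length(kept) == 0) {
    warn("No motif retained at the chosen significance level; prior network is empty.")
    return(prior_network(
      tibble(tf_id = character(), target_id = character()),
      method = method, motif_stats = motif_stats, assoc = assoc
    ))
  }

  support <- purrr::map_dfr(kept, function(l) {
    regs <- matched_regions(rankings, l, top_frac = top_frac)
    hit <- gene_map[gene_map$region_id %in% regs, ]
    if (nrow(hit) == 0) return(NULL)
    tfs <- rankings$tf_map$tf_id[rankings$tf_map$motif_id == l]
    tidyr::expand_grid(tf_id = tfs, hit[, c("gene_id", "region_id")]) |>
      dplyr::rename(target_id = "gene_id")
  })
  if (nrow(support) == 0) {
    warn("Retained motifs match no promoter-assigned region; prior network is empty.")
    return(prior_network(
      tibble(tf_id = character(), target_id = character()),
      method = method, motif_stats = motif_stats, assoc = assoc
    ))
  }
  support <- dplyr::distinct(support, .data$tf_id, .data$target_id, .data$region_id) |>
    dplyr::arrange(.data$tf_id, .data$target_id, .data$region_id)
  edges <- dplyr::distinct(support, .data$tf_id, .data$target_id)
  prior_network(edges, support = support, method = method,
                motif_stats = motif_stats, assoc = assoc)
}

#' Build an epigenomic prior network from binary chromatin signal (MLC)
#'
#' Modified lever-cistarget: per motif and sample, Somers' D tests whether
#' peak presence at a region is concordant with the closeness of the
#' motif's sequence match; D is Fisher-transformed (`z = atanh(D) *
#' sqrt(R-3)`) and a motif is significant in a sample when the two-sided
#' p-value is below `alpha`. A motif is retained when it is significant in
#' a majority of samples (or in at least `k` samples under
#' `sample_rule = "at_least_k"`). Edges connect each retained motif's TF to
#' the genes whose promoters lie within `max_dist` of the motif's matched
#' regions.
#'
#' @param signal A binary `region_signal` (peak calls per sample).
#' @param rankings A `motif_ranking`.
#' @param regions,tss Region and TSS tables.
#' @param alpha Per-sample significance level (default 0.1; a permissive
#'   level is used on purpose — false positives are filtered downstream by
#'   the expression-based regression).
#' @param sample_rule `"majority"` (default) or `"at_least_k"`.
#' @param k Minimum significant samples under `"at_least_k"`.
#' @param min_covered_samples Minimum samples with data for a region to
#'   enter the statistics; default strict majority.
#' @param top_frac,max_dist Match cutoff and promoter distance; see
#'   [matched_regions()] and [assign_regions_to_genes()].
#' @return A `prior_network` with method `"mlc"`.
#' @export
build_prior_mlc <- function(signal, rankings, regions, tss, alpha = 0.1,
                            sample_rule = c("majority", "at_least_k"), k = 2,
                            min_covered_samples = NULL,
                            top_frac = 0.05, max_dist = 5000) {
  sample_rule <- match.arg(sample_rule)
  if (signal$type != "binary") abort("MLC expects a binary region signal.")
  build_prior_engine(
    signal, rankings, regions, tss, alpha, sample_rule, k,
    min_covered_samples, top_frac, max_dist,
    stat_fun = function(score, y) somers_d(score, y)$D,
    method = "mlc"
  )
}

#' Build an epigenomic prior network from DNAme rates (MethCorTarget)
#'
#' As [build_prior_mlc()], but the per-(motif, sample) statistic is the
#' Spearman correlation between the motif match closeness and the
#' region-averaged DNAme rate. The test is two-sided (equivalently a test
#' on |rho|); the signed statistic is kept for interpretation — active TFs
#' typically show low methylation at well-matched regions.
#'
#' @inheritParams build_prior_mlc
#' @param signal A rate-type `region_signal` from
#'   [aggregate_region_methylation()].
#' @param min_covered_samples Regions must carry data in at least this many
#'   samples to enter the correlations (e.g. 3 for sparse single-cell
#'   bisulphite data); default strict majority of samples.
#' @return A `prior_network` with method `"methcor"`.
#' @export
build_prior_methcor <- function(signal, rankings, regions, tss, alpha = 0.1,
                                sample_rule = c("majority", "at_least_k"), k = 2,
                                min_covered_samples = NULL,
                                top_frac = 0.05, max_dist = 5000) {
  sample_rule <- match.arg(sample_rule)
  if (signal$type != "rate") abort("MethCorTarget expects a rate-type region signal.")
  build_prior_engine(
    signal, rankings, regions, tss, alpha, sample_rule, k,
    min_covered_samples, top_frac, max_dist,
    stat_fun = spearman_rho,
    method = "methcor"
  )
}

#' Write / read a prior network as TSV
#'
#' One row per edge, with supporting regions comma-joined in a
#' `support_regions` column.
#'
#' @param prior A `prior_network`.
#' @param path TSV path.
#' @export
write_prior_network <- function(prior, path) {
  supp <- prior$support |>
    dplyr::group_by(.data$tf_id, .data$target_id) |>
    dplyr::summarise(
      support_regions = paste(sort(.data$region_id), collapse = ","),
      .groups = "drop"
    )
  tab <- dplyr::left_join(prior$edges, supp, by = c("tf_id", "target_id")) |>
    dplyr::mutate(support_regions = dplyr::coalesce(.data$support_regions, "")) |>
    dplyr::arrange(.data$tf_id, .data$target_id)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_prior_network
#' @param method Provenance tag recorded on the read object.
#' @export
read_prior_network <- function(path, method = "synthetic") {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           tf_id = "c", target_id = "c",
                           support_regions = "c"
                         ))
  support <- tab |>
    dplyr::filter(nzchar(dplyr::coalesce(.data$support_regions, ""))) |>
    dplyr::mutate(region_id = strsplit(.data$support_regions, ",", fixed = TRUE)) |>
    tidyr::unnest("region_id") |>
    dplyr::select("tf_id", "target_id", "region_id")
  prior_network(tab[, c("tf_id", "target_id")], support = support,
                method = method)
}
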