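#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Two-sample z-test of proportions
#'
#' Pooled-variance z-statistic for comparing `kA / nA` against `kB / nB`,
#' with a two-sided Gaussian p-value.
#'
#' @param kA,nA Successes and trials in group A.
#' @param kB,nB Successes and trials in group B.
#' @return A list with `z`, `p`, `propA`, `propB`.
#' @export
proportions_ztest <- function(kA, nA, kB, nB) {
  stopifnot(nA >= 1, nB >= 1, kA >= 0, kB >= 0, kA <= nA, kB <= nB)
  p_pool <- (kA + kB) / (nA + nB)
  if (p_pool == 0 || p_pool == 1) {
    undefined_stat("Pooled proportion is 0 or 1; z undefined.")
  }
  se <- sqrt(p_pool * (1 - p_pool) * (1 / nA + 1 / nB))
  z <- (kA / nA - kB / nB) / se
  list(z = z, p = 2 * pnorm(-abs(z)), propA = kA / nA, propB = kB / nB)
}

#' Per-TF differential-regulation test between two conditions
#'
#' For each TF, the importance gains it receives across its shared prior
#' targets are compared between conditions A and B with a paired t-test
#' (paired by target; candidates fitted but never split on contribute gain
#' 0, keeping the pairing complete). P-values are Benjamini-Hochberg
#' adjusted across TFs. Direction `"hyper"` means stronger regulation in
#' condition A.
#'
#' @param fitsA,fitsB Lists of `target_fit` objects (or `grn` objects),
#'   both built from the same prior.
#' @param prior The shared `prior_network`.
#' @param fdr_threshold Significance level on the adjusted p (default
#'   0.05), recorded on the result.
#' @return A tibble of class `diff_reg_table`: `tf_id`,
#'   `n_shared_targets`, `mean_diff`, `t`, `p`, `fdr`, `direction`,
#'   `significant`.
#' @export
diff_reg_test <- function(fitsA, fitsB, prior, fdr_threshold = 0.05) {
  get_fits <- function(f) if (inherits(f, "grn")) f$fits else f
  fitsA <- get_fits(fitsA); fitsB <- get_fits(fitsB)
  names(fitsA) <- purrr::map_chr(fitsA, "target_id")
  names(fitsB) <- purrr::map_chr(fitsB, "target_id")
  shared_targets <- intersect(names(fitsA), names(fitsB))
  tfs <- sort(unique(prior$edges$tf_id))
  rows <- purrr::map_dfr(tfs, function(tf) {
    tgts <- purrr::keep(shared_targets, function(tgt) {
      tf %in% fitsA[[tgt]]$candidates && tf %in% fitsB[[tgt]]$candidates
    })
    if (length(tgts) < 2) {
      inform(sprintf("TF '%s' has < 2 shared fitted targets; excluded.", tf))
      return(NULL)
    }
    ga <- vapply(tgts, function(t) unname(fitsA[[t]]$gain[tf]), numeric(1))
    gb <- vapply(tgts, function(t) unname(fitsB[[t]]$gain[tf]), numeric(1))
    diffs <- ga - gb
    if (sd(diffs) <= 1e-10 * max(1, abs(mean(diffs)))) {
      # constant paired differences: a zero shift is a clean null, a
      # non-zero constant shift is detected with certainty
      if (abs(mean(diffs)) <= 1e-12) {
        tstat <- 0; pval <- 1
      } else {
        tstat <- sign(mean(diffs)) * Inf; pval <- 0
      }
    } else {
      tt <- t.test(ga, gb, paired = TRUE)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    }
    tibble(tf_id = tf, n_shared_targets = length(tgts),
           mean_diff = mean(diffs), t = tstat, p = pval)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(tf_id = character(), n_shared_targets = integer(),
                   mean_diff = numeric(), t = numeric(), p = numeric())
  }
  rows$fdr <- bh_adjust(rows$p)
  rows$direction <- ifelse(rows$mean_diff >= 0, "hyper", "hypo")
  rows$significant <- rows$fdr < fdr_threshold
  structure(rows, class = c("diff_reg_table", class(tibble())),
            fdr_threshold = fdr_threshold)
}

#' Assemble a differential-regulation network
#'
#' Nodes are the significantly differentially regulating TFs plus their
#' selected target genes that carry a differential-expression label
#' (labels are consumed as input, e.g. from a limma analysis); edges are
#' the selected GRN edges between included nodes, tagged by condition.
#'
#' @param diff A `diff_reg_table`.
#' @param de_labels Tibble with columns `gene_id` and `label` in
#'   `{"up", "down", "ns"}`; genes absent from the table default to
#'   `"ns"`.
#' @param grnA,grnB The two conditions' `grn` objects.
#' @param fdr_threshold Significance level on the TF fdr (default 0.05).
#' @return A list of class `diff_network` with `nodes` (`id`, `type`,
#'   `label`) and `edges` (`tf_id`, `target_id`, `condition`).
#' @export
build_differential_network <- function(diff, de_labels, grnA, grnB,
                                       fdr_threshold = 0.05) {
  sig_tfs <- diff$tf_id[diff$fdr < fdr_threshold]
  label_of <- setNames(de_labels$label, de_labels$gene_id)
  sel <- dplyr::bind_rows(
    dplyr::mutate(grn_edge_list(grnA, selected_only = TRUE), condition = "A"),
    dplyr::mutate(grn_edge_list(grnB, selected_only = TRUE), condition = "B")
  )
  edges <- sel |>
    dplyr::filter(.data$tf_id %in% sig_tfs) |>
    dplyr::mutate(target_label = dplyr::coalesce(label_of[.data$target_id], "ns")) |>
    dplyr::filter(.data$target_label != "ns")
  nodes <- dplyr::bind_rows(
    tibble(id = sig_tfs, type = "tf",
           label = diff$direction[match(sig_tfs, diff$tf_id)]),
    tibble(id = unique(edges$target_id), type = "target",
           label = unname(label_of[unique(edges$target_id)]))
  )
  structure(
    list(nodes = nodes,
         edges = edges[, c("tf_id", "target_id", "condition")],
         fdr_threshold = fdr_threshold),
    class = "diff_network"
  )
}

#' @export
print.diff_network <- function(x, ...) {
  cat(sprintf(
    "<diff_network> %d TFs + %d DE targets, %d edges (fdr < %g)\n",
    sum(x$nodes$type == "tf"), sum(x$nodes$type == "target"),
    nrow(x$edges), x$fdr_threshold
  ))
  invisible(x)
}
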