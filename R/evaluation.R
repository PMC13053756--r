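#' Edge-ranking AUC of a GRN against ground truth
#'
#' How well do importance gains rank true regulatory edges above non-edges?
#' Over a candidate-edge universe, each edge's score is its gain (0 when
#' the edge is absent from `gains`) and its label is membership in the
#' ground-truth network; the AUC is the mid-rank Mann-Whitney statistic,
#' identical to `(somers_d(score, label)$D + 1) / 2`.
#'
#' @param gains Edge tibble with `tf_id`, `target_id` and a score column
#'   (`gain` or `weight`); e.g. `grn$edges` or [grn_edge_list()] output.
#' @param truth A `ground_truth_network` or an edge tibble with `tf_id`,
#'   `target_id`.
#' @param universe Candidate-edge tibble (`tf_id`, `target_id`); defaults
#'   to all TF x target pairs of the truth network. Every truth edge must
#'   lie in the universe.
#' @return AUC in `[0, 1]`.
#' @export
grn_auc <- function(gains, truth, universe = NULL) {
  truth_edges <- if (inherits(truth, "ground_truth_network")) truth$edges else as_tibble(truth)
  if (is.null(universe)) {
    if (!inherits(truth, "ground_truth_network")) {
      abort("`universe` is required unless `truth` is a ground_truth_network.")
    }
    universe <- tidyr::expand_grid(tf_id = truth$tf_ids,
                                   target_id = truth$gene_ids) |>
      dplyr::filter(.data$tf_id != .data$target_id)
  }
  universe <- dplyr::distinct(as_tibble(universe), .data$tf_id, .data$target_id)
  key <- function(d) paste(d$tf_id, d$target_id, sep = "\r")
  if (!all(key(truth_edges) %in% key(universe))) {
    abort("Every ground-truth edge must be contained in the candidate universe.")
  }
  score_col <- intersect(c("gain", "weight"), names(gains))[1]
  if (is.na(score_col)) abort("`gains` needs a 'gain' or 'weight' column.")
  score <- setNames(gains[[score_col]], key(gains))[key(universe)]
  score[is.na(score)] <- 0
  label <- as.integer(key(universe) %in% key(truth_edges))
  somers_d(unname(score), label)$auc
}

#' Ablation z-score for one target gene
#'
#' Quantifies how much a target-specific prior improves explained variance
#' over non-specific priors of the same size. Observed statistic: fit the
#' target model on its `p` prior candidates, keep the `q` selected TFs
#' (gain above threshold), and compute the R-squared of an ordinary linear
#' model of target expression on those `q` TFs (0 when `q = 0`). Null
#' distribution: draw `p` TFs uniformly without replacement from all TFs
#' appearing anywhere in the prior (excluding the target), apply the
#' identical select-then-linear-fit procedure, repeat `n_rand` times. The
#' z-score standardises the observed R-squared by the null mean and sd.
#' R-squared is computed on the fitting samples, identically for observed
#' and null, so the z-score is internally consistent.
#'
#' @param target Target gene id (must be a prior target).
#' @param prior A `prior_network`.
#' @param expr CPM-normalized expression matrix.
#' @param n_rand Number of null randomizations (default 100).
#' @param thresholds A `threshold_table` or single threshold.
#' @param hyper A [grn_hyper()] record.
#' @param seed Integer seed.
#' @return One-row tibble of class `ablation_record`: `target_id`,
#'   `R2_obs`, `null_mean`, `null_sd`, `z`, `n_randomizations`.
#' @export
ablation_zscore <- function(target, prior, expr, n_rand = 100, thresholds = 0,
                            hyper = grn_hyper(), seed = 1L) {
  stopifnot(inherits(prior, "prior_network"), n_rand >= 2)
  cand_sets <- prior_candidates(prior)
  if (!target %in% names(cand_sets)) {
    abort(sprintf("'%s' is not a target of the prior network.", target))
  }
  candidates <- sort(intersect(setdiff(cand_sets[[target]], target),
                               rownames(expr)))
  p <- length(candidates)
  if (p < 1) abort("Target has no prior candidates present in the data.")
  pool <- sort(setdiff(unique(prior$edges$tf_id), target))
  pool <- intersect(pool, rownames(expr))
  if (length(pool) < p) {
    abort("The prior's TF pool is smaller than the candidate set.")
  }
  thr <- lookup_threshold(thresholds, n = ncol(expr), p = p)

  select_then_r2 <- function(cand, fit_seed) {
    fit <- fit_target_model(target, cand, expr, hyper = hyper,
                            seed = fit_seed, threshold = thr)
    if (length(fit$selected) == 0) return(0)
    y <- expr[target, ]
    x <- t(expr[fit$selected, , drop = FALSE])
    summary(lm(y ~ x))$r.squared
  }

  r2_obs <- select_then_r2(candidates, derive_seed(seed, 0))
  r2_null <- vapply(seq_len(n_rand), function(b) {
    set.seed(derive_seed(seed, b))
    select_then_r2(sort(sample(pool, p)), derive_seed(seed, n_rand + b))
  }, numeric(1))
  null_sd <- sd(r2_null)
  z <- if (null_sd > 0) (r2_obs - mean(r2_null)) / null_sd else NA_real_
  if (is.na(z)) {
    warn(sprintf("Null sd is 0 for target '%s'; z undefined.", target))
  }
  structure(
    tibble(target_id = target, R2_obs = r2_obs,
           null_mean = mean(r2_null), null_sd = null_sd, z = z,
           n_randomizations = as.integer(n_rand)),
    class = c("ablation_record", class(tibble())))
}

#' Genome-wide ablation study
#'
#' Runs [ablation_zscore()] over targets and tests whether the z-scores
#' are significantly greater than 0 (one-sample, one-sided t-test) — i.e.
#' whether the target-specific prior explains target expression better
#' than size-matched random candidate sets drawn from the same prior.
#'
#' @inheritParams ablation_zscore
#' @param targets Targets to ablate; default all prior targets present in
#'   `expr`.
#' @return An object of class `ablation_study`: `records` tibble,
#'   `t_statistic`, `p_value`, `mean_z`.
#' @export
ablation_study <- function(prior, expr, targets = NULL, n_rand = 100,
                           thresholds = 0, hyper = grn_hyper(), seed = 1L) {
  cand_sets <- prior_candidates(prior)
  targets <- targets %||% sort(intersect(names(cand_sets), rownames(expr)))
  records <- purrr::map_dfr(seq_along(targets), function(i) {
    ablation_zscore(targets[i], prior, expr, n_rand = n_rand,
                    thresholds = thresholds, hyper = hyper,
                    seed = derive_seed(seed, i * 37))
  })
  z <- records$z[!is.na(records$z)]
  if (length(z) < 2) abort("Need at least 2 targets with a defined z-score.")
  tt <- t.test(z, mu = 0, alternative = "greater")
  structure(
    list(records = records, t_statistic = unname(tt$statistic),
         p_value = tt$p.value, mean_z = mean(z)),
    class = "ablation_study"
  )
}

#' @export
print.ablation_study <- function(x, ...) {
  cat(sprintf(
    "<ablation_study> %d targets; mean z = %.3f; t = %.3f, one-sided p = %.3g\n",
    nrow(x$records), x$mean_z, x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' Overlap odds ratio between two edge sets
#'
#' Cross-tabulates membership in `setA` and `setB` over a common edge
#' universe and reports the sample odds ratio `ad / bc`, a Woolf logit 95%
#' confidence interval, and the two-sided p-value of Fisher's exact test.
#' Zero cells get the Haldane 0.5 correction (flagged).
#'
#' @param setA,setB Edge tibbles (`tf_id`, `target_id`) or character key
#'   vectors; must be subsets of `universe`.
#' @param universe Edge tibble or character key vector.
#' @return A list with `odds_ratio`, `conf_low`, `conf_high`, `p_value`,
#'   `table` (2x2), `haldane`.
#' @export
overlap_odds_ratio <- function(setA, setB, universe) {
  as_keys <- function(x) {
    if (is.character(x)) return(unique(x))
    unique(paste(x$tf_id, x$target_id, sep = "\r"))
  }
  a_keys <- as_keys(setA); b_keys <- as_keys(setB); u_keys <- as_keys(universe)
  if (!all(a_keys %in% u_keys) || !all(b_keys %in% u_keys)) {
    abort("Both sets must be subsets of the universe.")
  }
  in_a <- u_keys %in% a_keys
  in_b <- u_keys %in% b_keys
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  haldane <- any(tab == 0)
  cc <- if (haldane) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  p <- fisher.test(tab)$p.value
  list(
    odds_ratio = or,
    conf_low = exp(log(or) - 1.96 * se),
    conf_high = exp(log(or) + 1.96 * se),
    p_value = p, table = tab, haldane = haldane
  )
}
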