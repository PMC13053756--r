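#' Bayesian-bootstrap observation weights
#'
#' One draw of flat-Dirichlet(1, ..., 1) weights over `n` observations:
#' strictly positive, summing to 1. Unlike classical bootstrap resampling
#' this never repeats observations, which suits tree-ensemble regression.
#'
#' @param n Number of observations (>= 1).
#' @param seed Integer seed.
#' @return Numeric weight vector of length `n`.
#' @export
bayesian_bootstrap_weights <- function(n, seed = 1L) {
  if (n < 1) abort("`n` must be at least 1.")
  set.seed(as.integer(seed))
  g <- rexp(n)
  g / sum(g)
}

#' Bayesian-bootstrap edge robustness scores
#'
#' Estimates the reproducibility Pr(E | D) of each candidate edge of one
#' target gene: across `B` Bayesian-bootstrap replicates, the target model
#' is refitted with Dirichlet observation weights and an edge's score is
#' the fraction of replicates in which its importance gain exceeds the
#' selection threshold.
#'
#' @param target Target gene id.
#' @param candidates Candidate TF ids.
#' @param expr CPM-normalized expression matrix.
#' @param B Number of bootstrap replicates (default 200).
#' @param threshold Importance-gain selection threshold (>= 0).
#' @param hyper A [grn_hyper()] record.
#' @param seed Integer seed.
#' @param weight_fn Weight generator `function(n, seed)`; the default is
#'   [bayesian_bootstrap_weights()]. (Passing a constant-weight function
#'   gives a degenerate mode in which all replicates coincide.)
#' @return An object of class `robustness_result` with a `scores` tibble
#'   (`tf_id`, `score`, `gain_mean`, `gain_sd`), `B`, `threshold`.
#' @export
edge_robustness <- function(target, candidates, expr, B = 200, threshold = 0,
                            hyper = grn_hyper(), seed = 1L,
                            weight_fn = bayesian_bootstrap_weights) {
  stopifnot(B >= 1, threshold >= 0)
  candidates <- sort(unique(candidates))
  n <- ncol(expr)
  gains <- matrix(NA_real_, B, length(candidates),
                  dimnames = list(NULL, candidates))
  kept <- logical(B)
  fit_seed <- derive_seed(seed, 0) # replicates differ only in their weights
  for (b in seq_len(B)) {
    w <- weight_fn(n, derive_seed(seed, b))
    fit <- tryCatch(
      fit_target_model(target, candidates, expr, hyper = hyper,
                       seed = fit_seed, threshold = threshold,
                       weights = w),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      inform(sprintf("Bootstrap replicate %d failed; dropped.", b))
      next
    }
    gains[b, ] <- fit$gain[candidates]
    kept[b] <- TRUE
  }
  if (!any(kept)) abort("All bootstrap replicates failed.")
  g <- gains[kept, , drop = FALSE]
  scores <- tibble(
    tf_id = candidates,
    score = colMeans(g > threshold),
    gain_mean = colMeans(g),
    gain_sd = apply(g, 2, sd)
  )
  structure(
    list(target_id = target, scores = scores, B = sum(kept),
         threshold = threshold, seed = as.integer(seed), hyper = hyper),
    class = "robustness_result"
  )
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "<robustness_result> %s: %d candidates, B = %d, threshold = %.4g\n",
    x$target_id, nrow(x$scores), x$B, x$threshold
  ))
  print(dplyr::arrange(x$scores, dplyr::desc(.data$score)), n = 10)
  invisible(x)
}
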