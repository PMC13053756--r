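#' Somers' D concordance between a continuous score and a binary label
#'
#' Somers' D measures how well a continuous score separates the two classes
#' of a binary label: over all cross-class pairs, concordant pairs (the
#' positive-class observation has the higher score) count +1, discordant
#' pairs -1 and ties 0, normalised by the number of cross-class pairs.
#' `D` relates to the area under the ROC curve as `AUC = (D + 1) / 2`.
#'
#' Computed via the mid-rank Mann-Whitney identity `D = 2 U / (n1 n0) - 1`,
#' which equals the pairwise definition including the ties-count-zero rule.
#'
#' @param score Numeric vector.
#' @param label Binary vector (0/1 or logical), same length as `score`.
#' @return A list of class `concordance_stat` with elements `D`, `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' somers_d(c(1, 2, 3, 4), c(0, 0, 1, 1)) # perfect separation: D = 1
#' @export
somers_d <- function(score, label) {
  if (length(score) != length(label)) {
    abort("`score` and `label` must have the same length.")
  }
  if (length(score) < 2) abort("Need at least 2 observations.")
  if (is.logical(label)) label <- as.integer(label)
  if (!all(label %in% c(0, 1))) abort("`label` must be binary (0/1).")
  if (anyNA(score) || anyNA(label)) abort("Missing values are not allowed.")
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) {
    undefined_stat("Somers' D is undefined when only one class is present.")
  }
  r <- rank(score) # mid-ranks: tied cross-class pairs contribute 1/2 to U
  u <- sum(r[label == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  structure(
    list(D = 2 * auc - 1, auc = auc, n_pos = n1, n_neg = n0),
    class = "concordance_stat"
  )
}

#' @export
print.concordance_stat <- function(x, ...) {
  cat(sprintf(
    "Somers' D = %.4f (AUC = %.4f; %d positive / %d negative)\n",
    x$D, x$auc, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Spearman rank correlation with mid-rank ties
#'
#' Rank correlation between two numeric vectors; ties receive mid-ranks.
#' Degenerate inputs (constant vector, fewer than 3 observations) raise an
#' undefined-statistic condition rather than returning `NA` or 0.
#'
#' @param score,value Numeric vectors of equal length (>= 3), finite.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:3, c(3, 1, 2)) # -0.5
#' @export
spearman_rho <- function(score, value) {
  if (length(score) != length(value)) {
    abort("`score` and `value` must have the same length.")
  }
  if (length(score) < 3) {
    undefined_stat("Spearman's rho needs at least 3 observations.")
  }
  if (!all(is.finite(score)) || !all(is.finite(value))) {
    abort("Inputs must be finite.")
  }
  if (sd(score) == 0 || sd(value) == 0) {
    undefined_stat("Spearman's rho is undefined for a constant vector.")
  }
  unname(cor(score, value, method = "spearman"))
}

#' Fisher-transform z-test for a correlation-type statistic
#'
#' Maps a correlation-type statistic (Spearman's rho, or Somers' D under the
#' same distributional approximation) to an approximately standard-normal z
#' via `z = atanh(stat) * sqrt(R_used - 3)`, with a two-sided Gaussian
#' p-value. A statistic at exactly +/-1 yields infinite z; this is reported
#' as `p = 0` with `infinite = TRUE` rather than an error.
#'
#' @param stat Statistic in `[-1, 1]`.
#' @param R_used Number of observations the statistic was computed over
#'   (must be >= 4).
#' @return A list with `z`, `p`, `infinite`.
#' @examples
#' fisher_z_test(0.5, 103) # z ~ 5.49
#' @export
fisher_z_test <- function(stat, R_used) {
  if (!is.numeric(stat) || length(stat) != 1 || is.na(stat)) {
    abort("`stat` must be a single non-missing number.")
  }
  if (abs(stat) > 1) abort("`stat` must lie in [-1, 1].")
  if (R_used < 4) abort("`R_used` must be at least 4 for the Fisher z-test.")
  if (abs(stat) == 1) {
    return(list(z = sign(stat) * Inf, p = 0, infinite = TRUE))
  }
  z <- atanh(stat) * sqrt(R_used - 3)
  list(z = z, p = 2 * pnorm(-abs(z)), infinite = FALSE)
}
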