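#' Tidy a target-gene fit
#'
#' @param x A `target_fit`.
#' @param ... Unused.
#' @return One row per candidate TF: `tf_id`, `target_id`, `gain`,
#'   `selected`.
#' @method tidy target_fit
#' @export
tidy.target_fit <- function(x, ...) {
  tibble(
    tf_id = names(x$gain), target_id = x$target_id,
    gain = unname(x$gain), selected = names(x$gain) %in% x$selected
  )
}

#' @rdname tidy.target_fit
#' @method glance target_fit
#' @export
glance.target_fit <- function(x, ...) {
  tibble(
    target_id = x$target_id, n_candidates = length(x$candidates),
    n_selected = length(x$selected), threshold = x$threshold,
    degenerate = isTRUE(x$degenerate)
  )
}

#' Tidy an inferred GRN
#'
#' @param x A `grn`.
#' @param ... Unused.
#' @return The edge tibble (`tf_id`, `target_id`, `gain`, `threshold`,
#'   `selected`).
#' @method tidy grn
#' @export
tidy.grn <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.grn
#' @method glance grn
#' @export
glance.grn <- function(x, ...) {
  tibble(
    n_targets = length(x$fits), n_candidate_edges = nrow(x$edges),
    n_selected_edges = sum(x$edges$selected), n_samples = x$n
  )
}

#' Tidy a prior network
#'
#' @param x A `prior_network`.
#' @param ... Unused.
#' @method tidy prior_network
#' @export
tidy.prior_network <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.prior_network
#' @method glance prior_network
#' @export
glance.prior_network <- function(x, ...) {
  tibble(
    method = x$method, n_edges = nrow(x$edges),
    n_tfs = dplyr::n_distinct(x$edges$tf_id),
    n_targets = dplyr::n_distinct(x$edges$target_id)
  )
}

#' Tidy an ablation study
#'
#' @param x An `ablation_study`.
#' @param ... Unused.
#' @return The per-target record tibble.
#' @method tidy ablation_study
#' @export
tidy.ablation_study <- function(x, ...) as_tibble(x$records)

#' @rdname tidy.ablation_study
#' @method glance ablation_study
#' @export
glance.ablation_study <- function(x, ...) {
  tibble(
    n_targets = nrow(x$records), mean_z = x$mean_z,
    t_statistic = x$t_statistic, p_value = x$p_value
  )
}

#' Tidy a robustness result
#'
#' @param x A `robustness_result`.
#' @param ... Unused.
#' @method tidy robustness_result
#' @export
tidy.robustness_result <- function(x, ...) {
  dplyr::mutate(x$scores, target_id = x$target_id, .before = 1)
}

#' @rdname tidy.robustness_result
#' @method glance robustness_result
#' @export
glance.robustness_result <- function(x, ...) {
  tibble(target_id = x$target_id, B = x$B, threshold = x$threshold,
         n_candidates = nrow(x$scores))
}

#' Tidy a threshold table
#'
#' @param x A `threshold_table`.
#' @param ... Unused.
#' @return The per-cell summary tibble.
#' @method tidy threshold_table
#' @export
tidy.threshold_table <- function(x, ...) as_tibble(x$summary)
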