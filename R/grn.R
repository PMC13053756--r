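#' Counts-per-million normalisation
#'
#' Scales each sample (column) to a total of one million. Refuses to
#' normalise twice: the `normalized` attribute guards against accidental
#' double scaling.
#'
#' @param counts Non-negative genes x samples matrix of raw counts.
#' @return The CPM matrix with attribute `normalized = TRUE`.
#' @export
cpm_normalize <- function(counts) {
  if (isTRUE(attr(counts, "normalized"))) {
    abort("Matrix is already CPM-normalized.")
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  tot <- colSums(counts)
  zero <- which(tot == 0)
  if (length(zero) > 0) {
    nm <- colnames(counts)[zero[1]] %||% as.character(zero[1])
    abort(sprintf("Sample '%s' has all-zero counts; cannot CPM-normalize.", nm))
  }
  out <- sweep(counts, 2, tot, "/") * 1e6
  attr(out, "normalized") <- TRUE
  out
}

#' Tree-ensemble hyperparameters
#'
#' Hyperparameters for the gradient-boosted-tree surrogate of random-forest
#' regression used in every target-gene fit. Recorded verbatim in each
#' `target_fit` for reproducibility.
#'
#' @param nrounds Number of boosting rounds (trees). Default 200.
#' @param max_depth Maximum tree depth. Default 4.
#' @param eta Learning rate. Default 0.1.
#' @param subsample Row subsample fraction per tree. Default 0.8.
#' @return A named list of class `grn_hyper`.
#' @export
grn_hyper <- function(nrounds = 200, max_depth = 4, eta = 0.1,
                      subsample = 0.8) {
  structure(
    list(nrounds = nrounds, max_depth = max_depth, eta = eta,
         subsample = subsample),
    class = "grn_hyper"
  )
}

#' Fit one target-gene regression model
#'
#' Models the expression of `target` as a (possibly non-linear) function of
#' the expression of its candidate regulators, using gradient-boosted trees
#' (the xgboost implementation of random forests as boosted trees). The
#' weight of a candidate TF is its total split-gain importance across the
#' ensemble — 0 for TFs never split on. Fits are deterministic given
#' `seed` and `hyper`.
#'
#' @param target Target gene id (must not be among `candidates`).
#' @param candidates Character vector of candidate TF gene ids.
#' @param expr Genes x samples expression matrix (CPM or otherwise
#'   monotone-equivalent scale; tree splits are invariant to monotone
#'   transforms of predictors).
#' @param hyper A [grn_hyper()] record.
#' @param seed Integer seed.
#' @param threshold Importance-gain selection threshold; candidates with
#'   gain strictly above it are `selected`. Default 0.
#' @param weights Optional per-sample non-negative weights (e.g. Bayesian
#'   bootstrap); internally rescaled to sum to the sample count so gains
#'   stay on the unweighted scale.
#' @return An object of class `target_fit` with fields `target_id`,
#'   `candidates`, `gain` (named vector), `selected`, `threshold`, `seed`,
#'   `hyper`, `degenerate`.
#' @export
fit_target_model <- function(target, candidates, expr, hyper = grn_hyper(),
                             seed = 1L, threshold = 0, weights = NULL) {
  candidates <- unique(candidates)
  if (target %in% candidates) {
    abort("`target` must not be among its own candidates.")
  }
  missing_ids <- setdiff(c(target, candidates), rownames(expr))
  if (length(missing_ids) > 0) {
    abort(sprintf("Ids absent from expression matrix: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  new_fit <- function(gain, degenerate = FALSE) {
    structure(
      list(
        target_id = target, candidates = candidates, gain = gain,
        selected = names(gain)[gain > threshold], threshold = threshold,
        seed = as.integer(seed), hyper = hyper, degenerate = degenerate
      ),
      class = "target_fit"
    )
  }
  if (length(candidates) == 0) {
    return(new_fit(setNames(numeric(0), character(0))))
  }
  y <- expr[target, ]
  gain <- setNames(numeric(length(candidates)), candidates)
  if (sd(y) == 0) {
    return(new_fit(gain, degenerate = TRUE))
  }
  x <- t(expr[candidates, , drop = FALSE])
  colnames(x) <- candidates
  if (!is.null(weights)) {
    if (length(weights) != ncol(expr) || any(weights < 0)) {
      abort("`weights` must be non-negative, one per sample.")
    }
    weights <- weights / sum(weights) * ncol(expr)
  }
  set.seed(as.integer(seed)) # xgboost's R interface draws from R's RNG
  dm <- xgboost::xgb.DMatrix(x, label = y, weight = weights, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror",
      max_depth = hyper$max_depth, eta = hyper$eta,
      subsample = hyper$subsample, nthread = 1
    ),
    data = dm, nrounds = hyper$nrounds, verbose = 0
  )
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  splits <- tree[tree$Feature != "Leaf", , drop = FALSE]
  gain_col <- if ("Gain" %in% names(splits)) splits$Gain else splits$Quality
  if (nrow(splits) > 0) {
    by_feat <- tapply(gain_col, splits$Feature, sum)
    gain[names(by_feat)] <- as.numeric(by_feat)
  }
  new_fit(gain)
}

#' @export
print.target_fit <- function(x, ...) {
  cat(sprintf(
    "<target_fit> %s ~ %d candidates; %d selected (gain > %.4g)%s\n",
    x$target_id, length(x$candidates), length(x$selected), x$threshold,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Importance-gain threshold table
#'
#' Per-replicate optimal importance-gain thresholds on a grid of sample
#' size `n` and candidate-parent count `p`, summarised by the lower
#' quartile. The lower quartile (rather than the median) deliberately
#' trades extra false positives for fewer false negatives; downstream
#' validation and aggregation tolerate the former better.
#'
#' @param optima Tibble with columns `n`, `p`, `replicate`,
#'   `threshold_opt`.
#' @return An object of class `threshold_table` with an `optima` tibble and
#'   a `summary` tibble (`n`, `p`, `threshold`, `threshold_median`,
#'   `n_replicates`).
#' @export
threshold_table <- function(optima) {
  optima <- as_tibble(optima)
  stopifnot(all(c("n", "p", "replicate", "threshold_opt") %in% names(optima)))
  if (any(optima$threshold_opt < 0)) abort("Thresholds must be >= 0.")
  summary <- optima |>
    dplyr::group_by(.data$n, .data$p) |>
    dplyr::summarise(
      threshold = unname(quantile(.data$threshold_opt, 0.25)),
      threshold_median = median(.data$threshold_opt),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(list(optima = optima, summary = summary),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("<threshold_table> %d (n, p) grid cells\n", nrow(x$summary)))
  print(x$summary, n = 10)
  invisible(x)
}

#' Look up the selection threshold for a given (n, p)
#'
#' Off-grid queries use the nearest grid cell in log space.
#'
#' @param thresholds A `threshold_table`, or a single non-negative number
#'   used directly.
#' @param n Sample size.
#' @param p Number of candidate parents.
#' @return A single threshold value.
#' @export
lookup_threshold <- function(thresholds, n, p) {
  if (is.numeric(thresholds) && length(thresholds) == 1) {
    if (thresholds < 0) abort("Threshold must be >= 0.")
    return(unname(thresholds))
  }
  stopifnot(inherits(thresholds, "threshold_table"))
  s <- thresholds$summary
  d <- (log(s$n) - log(n))^2 + (log(s$p) - log(p))^2
  s$threshold[which.min(d)]
}

#' Write / read a threshold table as TSV
#' @param thresholds A `threshold_table`.
#' @param path TSV path (the per-replicate optima table; the summary is
#'   recomputed on read).
#' @export
write_threshold_table <- function(thresholds, path) {
  readr::write_tsv(thresholds$optima, path)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  threshold_table(readr::read_tsv(path, show_col_types = FALSE,
                                  col_types = readr::cols(
                                    n = "d", p = "d",
                                    replicate = "i", threshold_opt = "d"
                                  )))
}

#' Calibrate importance-gain thresholds on simulated ground truth
#'
#' For every grid cell (n, p) and replicate: simulate a ground-truth
#' network and kinetic expression data, build a decoy-augmented prior whose
#' candidate sets have size `p`, fit all target models, then choose the
#' gain threshold that maximises Youden's J (TPR - FPR) of the implied edge
#' classification against the ground truth — the threshold that maximises
#' the AUC of the binarised gain, since that AUC is (J+1)/2. The stored
#' per-cell threshold is the lower quartile of the replicate optima.
#'
#' @param spec A [simulation_spec()]; its network shape fields are reused
#'   for every replicate (sample size is overridden by `n_grid`).
#' @param n_grid,p_grid Integer vectors of sample sizes and candidate-set
#'   sizes.
#' @param replicates Replicates per grid cell (>= 4).
#' @param seed Integer seed.
#' @param hyper A [grn_hyper()] record.
#' @return A `threshold_table`.
#' @export
calibrate_thresholds <- function(spec, n_grid, p_grid, replicates = 8,
                                 seed = 1L, hyper = grn_hyper()) {
  if (replicates < 4) abort("Need at least 4 replicates per grid cell.")
  grid <- tidyr::expand_grid(n = n_grid, p = p_grid, replicate = seq_len(replicates))
  optima <- purrr::pmap_dfr(grid, function(n, p, replicate) {
    s <- derive_seed(seed, n * 131 + p * 17 + replicate)
    net <- simulate_network(spec, seed = s)
    counts <- simulate_expression(net, n_cells = n, spec = spec,
                                  seed = derive_seed(s, 1))
    expr <- cpm_normalize(counts)
    truth_edges <- net$edges
    if (nrow(truth_edges) == 0) {
      inform(sprintf("Replicate (n=%d, p=%d, r=%d) had no true edges; discarded.",
                     n, p, replicate))
      return(NULL)
    }
    # candidate sets of size p: true parents topped up with decoy TFs
    set.seed(derive_seed(s, 2))
    targets <- unique(truth_edges$target_id)
    pooled <- purrr::map_dfr(seq_along(targets), function(ti) {
      tgt <- targets[ti]
      parents <- truth_edges$tf_id[truth_edges$target_id == tgt]
      pool <- setdiff(net$tf_ids, c(parents, tgt))
      extra <- max(0, min(p - length(parents), length(pool)))
      cand <- c(parents, if (extra > 0) sample(pool, extra))
      fit <- fit_target_model(tgt, cand, expr, hyper = hyper,
                              seed = derive_seed(s, 100 + ti))
      tibble(gain = unname(fit$gain),
             is_true = names(fit$gain) %in% parents)
    })
    if (!any(pooled$is_true) || all(pooled$is_true)) {
      inform(sprintf("Replicate (n=%d, p=%d, r=%d) degenerate; discarded.",
                     n, p, replicate))
      return(NULL)
    }
    tibble(n = n, p = p, replicate = replicate,
           threshold_opt = optimal_gain_threshold(pooled$gain, pooled$is_true))
  })
  threshold_table(optima)
}

# Smallest threshold maximising Youden's J for the rule gain > t.
optimal_gain_threshold <- function(gain, is_true) {
  ts <- c(0, sort(unique(gain)))
  j <- vapply(ts, function(t) {
    mean(gain[is_true] > t) - mean(gain[!is_true] > t)
  }, numeric(1))
  ts[which.max(j)]
}

#' Infer a gene-regulatory network from expression data and a prior
#'
#' Runs one [fit_target_model()] per prior target, with candidates
#' restricted to the target's prior regulators present in the expression
#' matrix, and selects edges whose importance gain exceeds the calibrated
#' threshold for the fit's (n, p). The GRN is the union of the local
#' target-gene fits.
#'
#' @param expr CPM-normalized genes x samples matrix.
#' @param prior A `prior_network`.
#' @param thresholds A `threshold_table` or a single threshold.
#' @param hyper A [grn_hyper()] record.
#' @param seed Integer seed; per-target fits get derived seeds.
#' @return An object of class `grn`: edge tibble (`tf_id`, `target_id`,
#'   `gain`, `threshold`, `selected`) plus the per-target fits.
#' @export
infer_grn <- function(expr, prior, thresholds, hyper = grn_hyper(),
                      seed = 1L) {
  stopifnot(inherits(prior, "prior_network"))
  if (!isTRUE(attr(expr, "normalized"))) {
    abort("`expr` must be CPM-normalized (see cpm_normalize()).")
  }
  cand_sets <- prior_candidates(prior)
  if (length(cand_sets) == 0) {
    warn("Empty prior network; returning an empty GRN.")
    return(new_grn(list(), ncol(expr), hyper))
  }
  targets <- sort(names(cand_sets))
  fits <- list()
  skipped <- character(0)
  for (ti in seq_along(targets)) {
    tgt <- targets[ti]
    if (!tgt %in% rownames(expr)) {
      skipped <- c(skipped, tgt)
      next
    }
    cand <- intersect(setdiff(cand_sets[[tgt]], tgt), rownames(expr))
    if (length(cand) == 0) {
      skipped <- c(skipped, tgt)
      next
    }
    thr <- lookup_threshold(thresholds, n = ncol(expr), p = length(cand))
    fits[[tgt]] <- fit_target_model(
      tgt, sort(cand), expr, hyper = hyper,
      seed = derive_seed(seed, ti), threshold = thr
    )
  }
  if (length(skipped) > 0) {
    inform(sprintf("Skipped %d target(s) absent from the expression data or without candidates: %s",
                   length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  new_grn(fits, ncol(expr), hyper)
}

new_grn <- function(fits, n, hyper) {
  edges <- purrr::map_dfr(fits, function(f) {
    tibble(
      tf_id = names(f$gain), target_id = f$target_id,
      gain = unname(f$gain), threshold = f$threshold,
      selected = names(f$gain) %in% f$selected
    )
  })
  if (nrow(edges) == 0) {
    edges <- tibble(tf_id = character(), target_id = character(),
                    gain = numeric(), threshold = numeric(),
                    selected = logical())
  }
  structure(list(edges = edges, fits = fits, n = n, hyper = hyper),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf(
    "<grn> %d targets, %d candidate edges, %d selected (n = %d samples)\n",
    length(x$fits), nrow(x$edges), sum(x$edges$selected), x$n
  ))
  invisible(x)
}

#' Export a GRN's edges as an edge list tibble
#'
#' @param grn A `grn` object.
#' @param selected_only Keep only edges above threshold.
#' @return Tibble with `tf_id`, `target_id`, `weight`, `selected`.
#' @export
grn_edge_list <- function(grn, selected_only = FALSE) {
  out <- grn$edges |>
    dplyr::transmute(
      tf_id = .data$tf_id, target_id = .data$target_id,
      weight = .data$gain, selected = .data$selected
    )
  if (selected_only) out <- dplyr::filter(out, .data$selected)
  out
}
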