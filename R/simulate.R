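#' Simulation specification for synthetic ground-truth data
#'
#' Parameters of the kinetic data generator: an acyclic signed TF -> gene
#' network whose steady-state expression follows Hill-kinetics production
#' balanced by first-order degradation, with multiplicative lognormal cell
#' noise and Poisson sequencing counts at a configured library depth.
#'
#' @param n_tf,n_targets Numbers of TF genes and non-TF target genes.
#' @param mean_parents Mean number of TF parents per target gene (>= 1).
#' @param tf_parent_rate Mean TF parents of a non-root TF (Poisson).
#' @param activation_frac Probability an edge is activating (the rest
#'   repress). Default 0.7.
#' @param hill Hill coefficient `h` (cooperativity). Default 2.
#' @param K Half-saturation constant, in the same (arbitrary concentration)
#'   units as expression levels. Default 1.
#' @param v Maximal production rate. Default 2.
#' @param lambda First-order degradation rate; steady-state level is
#'   production / `lambda`. Default 1.
#' @param noise_sd Lognormal sdlog of per-gene, per-cell biological noise.
#'   Default 0.2.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of root-TF
#'   expression across cells.
#' @param depth Expected library size (total counts per cell). Default 1e5
#'   ("sequenced at high depth", so CPM closely tracks the underlying
#'   rates).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tf = 20, n_targets = 80, mean_parents = 2,
                            tf_parent_rate = 0.5, activation_frac = 0.7,
                            hill = 2, K = 1, v = 2, lambda = 1,
                            noise_sd = 0.2, baseline_meanlog = 0,
                            baseline_sdlog = 0.7, depth = 1e5) {
  stopifnot(n_tf >= 2, n_targets >= 1, mean_parents >= 1,
            activation_frac >= 0, activation_frac <= 1,
            hill > 0, K > 0, v > 0, lambda > 0, noise_sd >= 0, depth > 0)
  if (mean_parents > n_tf) {
    abort("`mean_parents` cannot exceed the number of TFs.")
  }
  structure(
    list(n_tf = n_tf, n_targets = n_targets, mean_parents = mean_parents,
         tf_parent_rate = tf_parent_rate, activation_frac = activation_frac,
         hill = hill, K = K, v = v, lambda = lambda, noise_sd = noise_sd,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         depth = depth),
    class = "simulation_spec"
  )
}

#' Simulate a signed acyclic ground-truth network
#'
#' TFs are ordered; each non-root TF draws parents among earlier TFs, and
#' each target gene draws `1 + Poisson(mean_parents - 1)` TF parents, so
#' the graph is a DAG by construction with target genes as sinks. Each
#' edge is an activator with probability `activation_frac`, otherwise a
#' repressor.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return An object of class `ground_truth_network` with `edges`
#'   (`tf_id`, `target_id`, `sign` in {activate, repress}), `tf_ids`,
#'   `target_ids`, `gene_ids` (topological order).
#' @export
simulate_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  tf_ids <- sprintf("TF%03d", seq_len(spec$n_tf))
  target_ids <- sprintf("G%03d", seq_len(spec$n_targets))
  edges <- list()
  # TF layer: later TFs may be regulated by earlier ones
  for (k in seq(2, spec$n_tf)) {
    np <- min(rpois(1, spec$tf_parent_rate), k - 1)
    if (np > 0) {
      parents <- sample(tf_ids[seq_len(k - 1)], np)
      edges[[length(edges) + 1]] <- tibble(tf_id = parents, target_id = tf_ids[k])
    }
  }
  # target genes: sinks with >= 1 TF parent
  for (g in target_ids) {
    np <- min(1 + rpois(1, spec$mean_parents - 1), spec$n_tf)
    parents <- sample(tf_ids, np)
    edges[[length(edges) + 1]] <- tibble(tf_id = parents, target_id = g)
  }
  edges <- dplyr::bind_rows(edges)
  edges$sign <- ifelse(runif(nrow(edges)) < spec$activation_frac,
                       "activate", "repress")
  stopifnot(!any(edges$tf_id == edges$target_id))
  structure(
    list(edges = edges, tf_ids = tf_ids, target_ids = target_ids,
         gene_ids = c(tf_ids, target_ids), spec = spec,
         seed = as.integer(seed)),
    class = "ground_truth_network"
  )
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_network> %d TFs, %d targets, %d signed edges (%.0f%% activating)\n",
    length(x$tf_ids), length(x$target_ids), nrow(x$edges),
    100 * mean(x$edges$sign == "activate")
  ))
  invisible(x)
}

# Steady-state rate of one gene given parent levels (vectors over cells).
hill_rate <- function(parent_levels, signs, spec) {
  h <- spec$hill
  kh <- spec$K^h
  term <- function(x, s) {
    xh <- x^h
    if (s == "activate") xh / (kh + xh) else kh / (kh + xh)
  }
  prod_terms <- Reduce(`*`, purrr::map2(parent_levels, signs, term))
  spec$v / spec$lambda * prod_terms
}

#' Simulate expression profiles from a ground-truth network
#'
#' Each cell draws root-TF levels from a lognormal baseline; every
#' downstream gene's steady-state level is `v / lambda` times the product
#' of Hill terms over its parents (`x^h / (K^h + x^h)` for activators,
#' `K^h / (K^h + x^h)` for repressors), evaluated in topological order and
#' multiplied by per-gene lognormal cell noise. With `counts = TRUE`
#' (default) sequencing counts are drawn per cell as Poisson at the
#' configured library depth, emulating deeply sequenced normalised
#' single-cell libraries.
#'
#' @param net A `ground_truth_network`.
#' @param n_cells Number of cells/profiles (default 300).
#' @param spec Simulation spec; defaults to the one stored on `net`.
#' @param seed Integer seed.
#' @param counts Return Poisson counts (`TRUE`) or the underlying
#'   steady-state rates (`FALSE`).
#' @return Genes x cells matrix (`normalized` attribute unset for counts).
#' @export
simulate_expression <- function(net, n_cells = 300, spec = NULL, seed = 1L,
                                counts = TRUE) {
  stopifnot(inherits(net, "ground_truth_network"))
  spec <- spec %||% net$spec
  set.seed(as.integer(seed))
  genes <- net$gene_ids # already topologically ordered
  x <- matrix(0, length(genes), n_cells,
              dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  parents_of <- split(seq_len(nrow(net$edges)), net$edges$target_id)
  for (g in genes) {
    rows <- parents_of[[g]]
    if (is.null(rows)) {
      x[g, ] <- rlnorm(n_cells, spec$baseline_meanlog, spec$baseline_sdlog)
    } else {
      pl <- purrr::map(net$edges$tf_id[rows], ~ x[.x, ])
      base <- hill_rate(pl, net$edges$sign[rows], spec)
      noise <- if (spec$noise_sd > 0) rlnorm(n_cells, 0, spec$noise_sd) else 1
      x[g, ] <- base * noise
    }
  }
  if (!counts) {
    attr(x, "normalized") <- FALSE
    return(x)
  }
  cnt <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(n_cells)) {
    cnt[, j] <- rpois(nrow(x), spec$depth * x[, j] / sum(x[, j]))
  }
  attr(cnt, "normalized") <- FALSE
  cnt
}

#' Simulate a decoy-augmented prior network
#'
#' For every target gene, the candidate-regulator set is its true parents
#' plus `n_decoys` TFs sampled uniformly without replacement from the
#' non-parent TFs — the construction used to probe how prior specificity
#' affects inference accuracy.
#'
#' @param net A `ground_truth_network`.
#' @param n_decoys Decoy TFs per target (>= 0); capped (with a warning) at
#'   the number of available non-parents.
#' @param seed Integer seed.
#' @return A `prior_network` with method `"synthetic"` whose candidate
#'   sets always contain the true parents.
#' @export
simulate_prior <- function(net, n_decoys, seed = 1L) {
  stopifnot(inherits(net, "ground_truth_network"), n_decoys >= 0)
  set.seed(as.integer(seed))
  targets <- unique(net$edges$target_id)
  capped <- FALSE
  edges <- purrr::map_dfr(targets, function(tgt) {
    parents <- net$edges$tf_id[net$edges$target_id == tgt]
    pool <- setdiff(net$tf_ids, c(parents, tgt))
    nd <- min(n_decoys, length(pool))
    if (nd < n_decoys) capped <<- TRUE
    tibble(tf_id = c(parents, if (nd > 0) sample(pool, nd)), target_id = tgt)
  })
  if (capped) {
    warn("`n_decoys` exceeded the available non-parent TFs for some targets; capped.")
  }
  prior_network(edges, method = "synthetic")
}

#' Simulate motif rankings with planted epigenomic associations
#'
#' Fixture generator for the prior-network stage. Regions are placed on a
#' synthetic chromosome, a fraction of them with a gene TSS ~800 bp away
#' (well inside the 5 kb promoter rule); per-motif match scores are drawn
#' and converted to rankings. Active motifs jointly drive the epigenomic
#' signal: the per-region signal strength is `eta = effect * sum(z(score))
#' / sqrt(n_active)` over the active motifs' standardised scores, so every
#' active motif is associated with the signal at every region and the
#' total signal variance does not depend on how many motifs are active.
#' Methylation mode: `rate = clip(base - 0.2 * eta + noise, 0, 1)` (better
#' match, lower DNAme); peaks mode: `Bernoulli(plogis(qlogis(base) +
#' eta))`. Inactive motifs' scores are independent of the signal.
#' The truth record lists the planted (motif, TF, region, gene)
#' regulations, i.e. the active motifs' matched regions that carry a
#' promoter assignment.
#'
#' @param n_regions,n_motifs Problem size.
#' @param active_motifs Character vector of active motif ids (subset of
#'   `sprintf("M%03d", 1:n_motifs)`), or an integer count (the first so
#'   many motifs).
#' @param effect Association strength (>= 0; 0 = null).
#' @param mode `"methylation"` or `"peaks"`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param top_frac Match cutoff used for the truth record.
#' @param tss_frac Fraction of regions given a nearby gene TSS.
#' @param base Baseline DNAme rate / peak probability. Default 0.5.
#' @param noise_sd Gaussian noise sd in methylation mode. Default 0.1.
#' @return A list with `rankings`, `signal`, `regions`, `tss`, `truth`
#'   (tibble `motif_id`, `tf_id`, `region_id`, `gene_id`) and
#'   `active_motifs`.
#' @export
simulate_epigenome <- function(n_regions = 500, n_motifs = 20,
                               active_motifs = 5, effect = 1,
                               mode = c("methylation", "peaks"),
                               n_samples = 5, seed = 1L, top_frac = 0.05,
                               tss_frac = 0.8, base = 0.5, noise_sd = 0.1) {
  mode <- match.arg(mode)
  stopifnot(effect >= 0, n_regions >= 20, n_motifs >= 1)
  motif_ids <- sprintf("M%03d", seq_len(n_motifs))
  if (is.numeric(active_motifs) && length(active_motifs) == 1) {
    active_motifs <- motif_ids[seq_len(active_motifs)]
  }
  if (!all(active_motifs %in% motif_ids)) {
    abort("`active_motifs` must be a subset of the motif ids.")
  }
  set.seed(as.integer(seed))
  # regions 10 kb apart so each TSS is <5 kb from exactly one region
  regions <- tibble(
    region_id = sprintf("r%04d", seq_len(n_regions)),
    chrom = "chrS",
    start = as.integer(seq_len(n_regions) * 10000L),
    end = as.integer(seq_len(n_regions) * 10000L + 500L)
  )
  has_tss <- runif(n_regions) < tss_frac
  tss <- tibble(
    gene_id = sprintf("gene%04d", which(has_tss)),
    chrom = "chrS",
    tss = regions$start[has_tss] - 800L,
    strand = "+"
  )
  score <- matrix(rnorm(n_motifs * n_regions), n_motifs, n_regions,
                  dimnames = list(motif_ids, regions$region_id))
  rank <- t(apply(-score, 1, rank, ties.method = "first"))
  dimnames(rank) <- dimnames(score)
  tf_map <- tibble(motif_id = motif_ids,
                   tf_id = sub("^M", "TF", motif_ids))
  rankings <- motif_ranking(rank, tf_map = tf_map)

  samples <- sprintf("s%02d", seq_len(n_samples))
  value <- matrix(NA_real_, n_regions, n_samples,
                  dimnames = list(regions$region_id, samples))
  if (length(active_motifs) == 0 || effect == 0) {
    eta <- rep(0, n_regions)
  } else {
    zs <- (score - rowMeans(score)) / apply(score, 1, sd)
    eta <- effect *
      colSums(zs[active_motifs, , drop = FALSE]) / sqrt(length(active_motifs))
  }
  for (j in seq_len(n_samples)) {
    if (mode == "methylation") {
      value[, j] <- pmin(pmax(base - 0.2 * eta + rnorm(n_regions, 0, noise_sd), 0), 1)
    } else {
      p <- plogis(qlogis(base) + eta)
      v <- rbinom(n_regions, 1, p)
      tries <- 0
      while (length(unique(v)) == 1 && tries < 10) {
        warn(sprintf("Sample %s: constant peak class; regenerating.", samples[j]))
        v <- rbinom(n_regions, 1, p)
        tries <- tries + 1
      }
      value[, j] <- v
    }
  }
  coverage <- matrix(TRUE, n_regions, n_samples,
                     dimnames = dimnames(value))
  signal <- region_signal(
    value, coverage,
    type = if (mode == "methylation") "rate" else "binary"
  )

  gene_map <- assign_regions_to_genes(regions, tss, max_dist = 5000)
  truth <- purrr::map_dfr(active_motifs, function(l) {
    regs <- matched_regions(rankings, l, top_frac = top_frac)
    hit <- gene_map[gene_map$region_id %in% regs, ]
    if (nrow(hit) == 0) return(NULL)
    tibble(motif_id = l,
           tf_id = tf_map$tf_id[tf_map$motif_id == l],
           region_id = hit$region_id, gene_id = hit$gene_id)
  })
  list(rankings = rankings, signal = signal, regions = regions, tss = tss,
       truth = truth, active_motifs = active_motifs)
}
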