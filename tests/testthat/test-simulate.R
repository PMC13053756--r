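test_that("simulated networks are acyclic, signed and reproducible", {
  spec <- simulation_spec(n_tf = 5, n_targets = 20, mean_parents = 2)
  net <- simulate_network(spec, seed = 1)
  expect_false(any(net$edges$tf_id == net$edges$target_id))
  expect_true(all(net$edges$sign %in% c("activate", "repress")))
  expect_gt(nrow(net$edges), 20) # >= 1 parent per target plus TF layer

  # DAG: every edge goes forward in the topological gene order
  pos <- setNames(seq_along(net$gene_ids), net$gene_ids)
  expect_true(all(pos[net$edges$tf_id] < pos[net$edges$target_id]))

  net2 <- simulate_network(spec, seed = 1)
  expect_identical(net$edges, net2$edges)

  all_act <- simulate_network(
    simulation_spec(n_tf = 5, n_targets = 10, activation_frac = 1), seed = 2
  )
  expect_true(all(all_act$edges$sign == "activate"))
  expect_error(simulation_spec(n_tf = 3, n_targets = 5, mean_parents = 10),
               "exceed")
})

test_that("expression library sizes match the configured depth", {
  spec <- simulation_spec(n_tf = 10, n_targets = 30, depth = 5e4)
  net <- simulate_network(spec, seed = 3)
  counts <- simulate_expression(net, n_cells = 50, seed = 4)
  # Poisson at depth 5e4: sd of a library size ~ sqrt(5e4) ~ 224
  expect_true(all(abs(colSums(counts) - 5e4) < 5 * sqrt(5e4)))
})

test_that("activator edges show positive parent-child rank correlation", {
  spec <- simulation_spec(n_tf = 8, n_targets = 30, activation_frac = 1,
                          noise_sd = 0.1)
  net <- simulate_network(spec, seed = 5)
  rates <- simulate_expression(net, n_cells = 300, seed = 6, counts = FALSE)
  single <- net$edges |>
    dplyr::add_count(target_id) |>
    dplyr::filter(n == 1) # isolate single-parent targets
  rho <- vapply(seq_len(nrow(single)), function(i) {
    cor(rates[single$tf_id[i], ], rates[single$target_id[i], ],
        method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho > 0), 0.9)
})

test_that("noiseless expression with fixed roots is deterministic", {
  spec <- simulation_spec(n_tf = 4, n_targets = 8, noise_sd = 0,
                          baseline_sdlog = 0)
  net <- simulate_network(spec, seed = 7)
  r1 <- simulate_expression(net, n_cells = 5, seed = 8, counts = FALSE)
  r2 <- simulate_expression(net, n_cells = 5, seed = 99, counts = FALSE)
  expect_equal(r1, r2) # no stochastic component left
  expect_equal(r1[, 1], r1[, 2]) # identical cells
})

test_that("decoy priors always contain the truth", {
  spec <- simulation_spec(n_tf = 12, n_targets = 20)
  net <- simulate_network(spec, seed = 9)
  p0 <- simulate_prior(net, n_decoys = 0, seed = 10)
  truth_keys <- sort(unique(edge_keys(net$edges)))
  expect_equal(sort(edge_keys(p0$edges)), truth_keys)

  p5 <- simulate_prior(net, n_decoys = 5, seed = 11)
  expect_true(all(truth_keys %in% edge_keys(p5$edges)))
  sizes <- table(p5$edges$target_id)
  parents <- table(net$edges$target_id)
  expect_equal(as.integer(sizes[names(parents)]),
               as.integer(parents) + 5L)

  expect_warning(simulate_prior(net, n_decoys = 50, seed = 12), "capped")
})

test_that("planted epigenome truth is recoverable in the strong-effect limit", {
  epi <- simulate_epigenome(
    n_regions = 200, n_motifs = 8, active_motifs = 2, effect = 50,
    mode = "methylation", n_samples = 4, seed = 13, noise_sd = 1e-6
  )
  # matched_regions + promoter assignment reproduce the truth record exactly
  map <- assign_regions_to_genes(epi$regions, epi$tss)
  rebuilt <- dplyr::bind_rows(lapply(epi$active_motifs, function(l) {
    regs <- matched_regions(epi$rankings, l)
    hit <- map[map$region_id %in% regs, ]
    tibble::tibble(motif_id = l, region_id = hit$region_id,
                   gene_id = hit$gene_id)
  }))
  expect_equal(
    dplyr::arrange(rebuilt, motif_id, region_id),
    dplyr::arrange(epi$truth[, c("motif_id", "region_id", "gene_id")],
                   motif_id, region_id)
  )
  # all planted edges obey the promoter rule by construction
  joined <- dplyr::inner_join(epi$truth, map, by = "region_id")
  expect_true(all(joined$gene_id.x == joined$gene_id.y))
  expect_true(all(joined$distance < 5000))
})

test_that("generators are pure functions of (spec, seed)", {
  e1 <- simulate_epigenome(n_regions = 100, n_motifs = 5, active_motifs = 2,
                           effect = 1, n_samples = 3, seed = 14)
  e2 <- simulate_epigenome(n_regions = 100, n_motifs = 5, active_motifs = 2,
                           effect = 1, n_samples = 3, seed = 14)
  expect_identical(e1$rankings$rank, e2$rankings$rank)
  expect_identical(e1$signal$value, e2$signal$value)
  expect_identical(e1$truth, e2$truth)
})
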