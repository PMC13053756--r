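test_that("region methylation aggregates counts and applies the read floor", {
  regions <- tiny_regions()
  cpgs <- tibble::tibble(
    chrom = "chr1",
    position = c(120L, 150L, 9550L, 9600L, 20150L),
    count_methylated = c(2L, 2L, 1L, 2L, 0L),
    count_unmethylated = c(3L, 3L, 2L, 4L, 12L),
    sample_id = "s1"
  )
  sig <- aggregate_region_methylation(cpgs, regions, min_reads = 10)
  # r1: (2+2) meth / 10 total -> 0.4, exactly at the 10-read floor
  expect_equal(sig$value["r1", "s1"], 0.4)
  expect_true(sig$coverage["r1", "s1"])
  # r2: 9 total reads -> below the floor, uncovered
  expect_equal(sig$value["r2", "s1"], 3 / 9)
  expect_false(sig$coverage["r2", "s1"])
  # r3: 0 methylated of 12 -> rate 0, covered
  expect_equal(sig$value["r3", "s1"], 0)
  expect_true(sig$coverage["r3", "s1"])

  expect_error(aggregate_region_methylation(cpgs, regions[0, ]), "Empty")
  far <- dplyr::mutate(cpgs, position = position + 10000000L)
  expect_warning(aggregate_region_methylation(far, regions), "uncovered")
})

test_that("matched_regions applies the ceiling rank cutoff", {
  set.seed(3)
  m <- t(vapply(1:2, function(i) sample(10L), integer(10)))
  rownames(m) <- c("M1", "M2")
  colnames(m) <- paste0("r", 1:10)
  rk <- motif_ranking(m)
  expect_equal(sort(matched_regions(rk, "M1", top_frac = 1)),
               sort(colnames(m)))
  expect_equal(matched_regions(rk, "M1", top_frac = 0.2),
               colnames(m)[m["M1", ] <= 2])
  # ceil(0.15 * 10) = 2
  expect_length(matched_regions(rk, "M1", top_frac = 0.15), 2)
  expect_error(matched_regions(rk, "nope"), "Unknown motif")
})

test_that("regions map to the closest promoter under 5 kb", {
  map <- assign_regions_to_genes(tiny_regions(), tiny_tss())
  # r1 contains geneA's TSS -> distance 0
  expect_equal(map$distance[map$region_id == "r1"], 0)
  expect_equal(map$gene_id[map$region_id == "r1"], "geneA")
  # r2 is 300 bp from geneB's TSS
  expect_equal(map$distance[map$region_id == "r2"], 300)
  # r3 is >5 kb from every TSS -> dropped
  expect_false("r3" %in% map$region_id)
  expect_error(assign_regions_to_genes(tiny_regions(), tiny_tss()[0, ]),
               "Empty TSS")
})

test_that("promoter ties break lexicographically by gene id", {
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
                            start = 1000L, end = 1100L)
  tss <- tibble::tibble(
    gene_id = c("geneZ", "geneA"), chrom = "chr1",
    tss = c(900L, 1200L), strand = "+"
  ) # both at distance 100
  map <- assign_regions_to_genes(regions, tss)
  expect_equal(map$gene_id, "geneA")
})

test_that("planted methylation associations are recovered by MethCorTarget", {
  epi <- simulate_epigenome(
    n_regions = 400, n_motifs = 12, active_motifs = 4, effect = 3,
    mode = "methylation", n_samples = 5, seed = 11
  )
  prior <- build_prior_methcor(epi$signal, epi$rankings, epi$regions, epi$tss)
  retained <- prior$motif_stats$motif_id[prior$motif_stats$retained]
  expect_true(all(epi$active_motifs %in% retained))
  # every planted (TF, gene) regulation appears in the prior
  expect_true(all(
    paste(epi$truth$tf_id, epi$truth$gene_id) %in% edge_keys(prior$edges)
  ))
  # alpha 0 retains nothing
  expect_warning(
    empty <- build_prior_methcor(epi$signal, epi$rankings, epi$regions,
                                 epi$tss, alpha = 0),
    "No motif retained"
  )
  expect_equal(nrow(empty$edges), 0)
})

test_that("planted peak associations are recovered by MLC", {
  epi <- simulate_epigenome(
    n_regions = 400, n_motifs = 12, active_motifs = 4, effect = 3,
    mode = "peaks", n_samples = 5, seed = 12
  )
  prior <- build_prior_mlc(epi$signal, epi$rankings, epi$regions, epi$tss)
  retained <- prior$motif_stats$motif_id[prior$motif_stats$retained]
  expect_true(all(epi$active_motifs %in% retained))
  expect_true(all(
    paste(epi$truth$tf_id, epi$truth$gene_id) %in% edge_keys(prior$edges)
  ))
})

test_that("majority sample rule requires more than half of samples", {
  # motif significant in 1 of 3 samples: perfect association in sample 1,
  # pure noise elsewhere
  set.seed(20)
  R <- 60
  score <- rnorm(R)
  rank_row <- rank(-score, ties.method = "first")
  m <- matrix(rank_row, 1, R,
              dimnames = list("M001", sprintf("r%03d", 1:R)))
  rk <- motif_ranking(m)
  value <- cbind(
    s1 = pmin(pmax(0.5 - 0.45 * scale(score)[, 1] / 2, 0), 1),
    s2 = runif(R), s3 = runif(R)
  )
  rownames(value) <- colnames(m)
  sig <- region_signal(value, type = "rate")
  regions <- tibble::tibble(region_id = rownames(value), chrom = "chrS",
                            start = (1:R) * 10000L, end = (1:R) * 10000L + 500L)
  tss <- tibble::tibble(gene_id = paste0("g", 1:R), chrom = "chrS",
                        tss = regions$start - 500L, strand = "+")
  expect_warning(
    prior <- build_prior_methcor(sig, rk, regions, tss, alpha = 0.01),
    "No motif retained"
  )
  expect_equal(nrow(prior$edges), 0)
  # the same motif passes with at_least_k = 1
  prior2 <- build_prior_methcor(sig, rk, regions, tss, alpha = 0.01,
                                sample_rule = "at_least_k", k = 1)
  expect_gt(nrow(prior2$edges), 0)
})

test_that("regions below the coverage rule are excluded from correlations", {
  epi <- simulate_epigenome(
    n_regions = 100, n_motifs = 4, active_motifs = 1, effect = 3,
    mode = "methylation", n_samples = 4, seed = 33
  )
  cov <- epi$signal$coverage
  cov[1:50, c("s03", "s04")] <- FALSE # half the regions covered in 2 of 4
  sig <- region_signal(epi$signal$value, cov, type = "rate")
  prior <- build_prior_methcor(sig, epi$rankings, epi$regions, epi$tss,
                               min_covered_samples = 3)
  # R_used never counts the under-covered regions
  expect_true(all(prior$assoc$R_used <= 50))
})

test_that("prior edges are invariant to region order permutations", {
  epi <- simulate_epigenome(
    n_regions = 150, n_motifs = 6, active_motifs = 2, effect = 3,
    mode = "methylation", n_samples = 4, seed = 44
  )
  prior1 <- build_prior_methcor(epi$signal, epi$rankings, epi$regions, epi$tss)
  perm <- sample(length(epi$signal$region_ids))
  sig_perm <- region_signal(epi$signal$value[perm, ],
                            epi$signal$coverage[perm, ], type = "rate")
  reg_perm <- epi$regions[sample(nrow(epi$regions)), ]
  prior2 <- build_prior_methcor(sig_perm, epi$rankings, reg_perm, epi$tss)
  expect_equal(
    dplyr::arrange(prior1$edges, tf_id, target_id),
    dplyr::arrange(prior2$edges, tf_id, target_id)
  )
})

test_that("every prior edge's support regions satisfy the promoter rule", {
  epi <- simulate_epigenome(
    n_regions = 300, n_motifs = 10, active_motifs = 3, effect = 3,
    mode = "methylation", n_samples = 5, seed = 55
  )
  prior <- build_prior_methcor(epi$signal, epi$rankings, epi$regions, epi$tss)
  map <- assign_regions_to_genes(epi$regions, epi$tss, max_dist = 5000)
  joined <- dplyr::inner_join(
    prior$support, map,
    by = c("region_id", "target_id" = "gene_id")
  )
  expect_equal(nrow(joined), nrow(prior$support))
  expect_true(all(joined$distance < 5000))
})

test_that("prior network TSV round-trips edges and support", {
  epi <- simulate_epigenome(
    n_regions = 150, n_motifs = 6, active_motifs = 2, effect = 3,
    mode = "methylation", n_samples = 4, seed = 66
  )
  prior <- build_prior_methcor(epi$signal, epi$rankings, epi$regions, epi$tss)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prior_network(prior, path)
  back <- read_prior_network(path, method = "methcor")
  expect_equal(dplyr::arrange(back$edges, tf_id, target_id),
               dplyr::arrange(prior$edges, tf_id, target_id))
  expect_equal(
    dplyr::arrange(back$support, tf_id, target_id, region_id),
    dplyr::arrange(prior$support, tf_id, target_id, region_id)
  )
})
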