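hyper_fast <- grn_hyper(nrounds = 60, max_depth = 3)

test_that("grn_auc matches the Mann-Whitney oracle and somers_d", {
  set.seed(8)
  for (i in 1:10) {
    n_edges <- sample(20:200, 1)
    universe <- tibble::tibble(
      tf_id = sprintf("TF%03d", seq_len(n_edges)),
      target_id = "G1"
    )
    truth <- universe[rbinom(n_edges, 1, 0.3) == 1, ]
    if (nrow(truth) == 0 || nrow(truth) == n_edges) next
    gains <- dplyr::mutate(universe,
                           gain = sample(0:5, n_edges, replace = TRUE))
    auc <- grn_auc(gains, truth, universe)
    label <- as.integer(edge_keys(universe) %in% edge_keys(truth))
    # brute-force U / (n1 n0)
    pos <- gains$gain[label == 1]; neg <- gains$gain[label == 0]
    u <- sum(vapply(pos, function(a) sum(a > neg) + 0.5 * sum(a == neg),
                    numeric(1)))
    expect_equal(auc, u / (length(pos) * length(neg)))
    expect_equal(auc, somers_d(gains$gain, label)$auc)
  }
})

test_that("perfect scores give AUC 1 and null scores sit near 0.5", {
  universe <- tibble::tibble(tf_id = sprintf("T%04d", 1:1000), target_id = "G")
  truth <- universe[1:100, ]
  gains <- dplyr::mutate(universe, gain = as.numeric(tf_id %in% truth$tf_id))
  expect_equal(grn_auc(gains, truth, universe), 1)

  set.seed(99)
  gains$gain <- runif(1000)
  expect_gt(grn_auc(gains, truth, universe), 0.45)
  expect_lt(grn_auc(gains, truth, universe), 0.55)

  expect_error(grn_auc(gains, universe, universe),
               class = "epigrn_undefined_statistic")
})

test_that("ablation z-scores centre correctly and respond to signal", {
  spec <- simulation_spec(n_tf = 10, n_targets = 15)
  net <- simulate_network(spec, seed = 21)
  expr <- cpm_normalize(simulate_expression(net, n_cells = 150, seed = 22))
  prior <- simulate_prior(net, n_decoys = 3, seed = 23)
  rec <- ablation_zscore(net$target_ids[1], prior, expr, n_rand = 20,
                         thresholds = 1, hyper = hyper_fast, seed = 24)
  expect_equal(rec$z, (rec$R2_obs - rec$null_mean) / rec$null_sd)
  expect_equal(rec$n_randomizations, 20L)

  # determinism + invariance to genes in expr that the prior never uses
  rec2 <- ablation_zscore(net$target_ids[1], prior, expr, n_rand = 20,
                          thresholds = 1, hyper = hyper_fast, seed = 24)
  expect_identical(rec$z, rec2$z)
  extra <- rbind(expr, matrix(runif(2 * ncol(expr)), 2,
                              dimnames = list(c("zzz1", "zzz2"), colnames(expr))))
  attr(extra, "normalized") <- TRUE
  rec3 <- ablation_zscore(net$target_ids[1], prior, extra, n_rand = 20,
                          thresholds = 1, hyper = hyper_fast, seed = 24)
  expect_identical(rec$z, rec3$z)
})

test_that("the ablation study t-test behaves at the null and with signal", {
  spec <- simulation_spec(n_tf = 10, n_targets = 20, noise_sd = 0.1)
  net <- simulate_network(spec, seed = 31)
  expr <- cpm_normalize(simulate_expression(net, n_cells = 150, seed = 32))
  prior <- simulate_prior(net, n_decoys = 3, seed = 33)
  study <- ablation_study(prior, expr, targets = net$target_ids[1:10],
                          n_rand = 15, thresholds = 1, hyper = hyper_fast,
                          seed = 34)
  expect_s3_class(study, "ablation_study")
  expect_equal(nrow(study$records), 10)
  expect_gt(study$mean_z, 0)
  expect_lt(study$p_value, 0.05)
  expect_error(
    ablation_study(prior, expr, targets = net$target_ids[1], n_rand = 5,
                   thresholds = 1, hyper = hyper_fast),
    "at least 2"
  )
})

test_that("overlap odds ratios match arithmetic and the enumeration oracle", {
  universe <- sprintf("e%03d", 1:100)
  setA <- universe[1:30]
  setB <- universe[c(1:20, 31:40)] # a=20, b=10, c=10, d=60
  res <- overlap_odds_ratio(setA, setB, universe)
  expect_equal(res$odds_ratio, 12)
  expect_false(res$haldane)
  expect_lt(res$conf_low, 12)
  expect_gt(res$conf_high, 12)

  # Fisher p equals complete enumeration on small tables
  set.seed(17)
  for (i in 1:20) {
    tot <- sample(8:40, 1)
    u <- sprintf("x%02d", seq_len(tot))
    a_set <- sample(u, sample(seq_len(tot), 1))
    b_set <- sample(u, sample(seq_len(tot), 1))
    r <- overlap_odds_ratio(a_set, b_set, u)
    tab <- r$table
    expect_equal(
      r$p_value,
      fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      tolerance = 1e-9
    )
  }

  # disjoint sets -> Haldane correction, flagged
  r0 <- overlap_odds_ratio(universe[1:10], universe[11:20], universe)
  expect_true(r0$haldane)
  expect_lt(r0$odds_ratio, 1)
})
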