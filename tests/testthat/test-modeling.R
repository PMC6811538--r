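test_that("split plans honor block fractions, disjointness and determinism", {
  cells <- sprintf("c%03d", 1:100)
  p <- make_split(cells, "enr", permutation = 1, master_seed = 5, drug = "d1")
  expect_length(p$train, 80)
  expect_length(p$test, 10)
  expect_length(p$validation, 10)
  expect_setequal(c(p$train, p$test, p$validation), cells)
  expect_length(intersect(p$train, p$test), 0)
  s <- make_split(cells, "svr", permutation = 1, master_seed = 5, drug = "d1")
  expect_length(s$train, 90)
  expect_length(s$test, 10)
  expect_length(s$validation, 0)
  again <- make_split(cells, "enr", permutation = 1, master_seed = 5, drug = "d1")
  expect_identical(p$train, again$train)
  other <- make_split(cells, "enr", permutation = 2, master_seed = 5, drug = "d1")
  expect_false(identical(p$train, other$train))
  expect_error(make_split(cells[1:29], "enr"), "at least 30")
})

test_that("uneven cohort sizes split into floor-sized blocks covering all cells", {
  cells <- sprintf("c%03d", 1:97)
  p <- make_split(cells, "enr", 3, 9, "dx")
  expect_length(p$train, floor(0.8 * 97))
  expect_length(p$test, floor(0.1 * 97))
  expect_equal(length(p$validation), 97 - floor(0.8 * 97) - floor(0.1 * 97))
})

test_that("the elastic net recovers a noiseless planted signal from the causal set", {
  # needs a wide gene panel: the response is linear in *raw* expression and
  # within-cell-line z-scoring adds a per-cell scale jitter of order
  # 1/sqrt(2G) that only vanishes for large G
  co <- generate_cohort(simulation_config(
    n_cell_lines = 120, n_genes = 1000, n_drugs = 1, causal_per_drug = 4,
    noise_sd = 1e-6, missing_response_fraction = 0, n_classes = 1, seed = 51))
  plan <- make_split(co$expression$cell_line, "enr", 1, 7, "drug_01")
  out <- fit_predict(co$expression, co$response, "drug_01",
                     co$truth$causal_genes[[1]], plan, "enr")
  expect_gt(out$r_pred_obs, 0.99)
  expect_lt(out$mae, 0.3)
})

test_that("noise features on a null drug score near zero on average", {
  co <- generate_cohort(simulation_config(
    n_cell_lines = 150, n_genes = 60, n_drugs = 1, causal_per_drug = 0,
    noise_sd = 1, missing_response_fraction = 0, n_classes = 1, seed = 52))
  ev <- run_fixed_pipeline(co$expression, co$response, "drug_01",
                           sprintf("g%04d", 1:20), learner = "enr",
                           config = pipeline_config(n_permutations = 30,
                                                    master_seed = 2))
  expect_lt(abs(glance(ev)$mean_r), 0.12)
})

test_that("near-unpenalized elastic net approaches least squares on a well-conditioned toy", {
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("c%03d", 1:n),
                                               c("g1", "g2", "g3")))
  y <- drop(x %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.1)
  tr <- 1:150; va <- 151:180; te <- 181:200
  fit <- inforx:::fit_enr(x[tr, ], y[tr], x[va, ], y[va], alpha_grid = 0.1)
  ols <- lm.fit(cbind(1, x[tr, ]), y[tr])$coefficients
  pred_enr <- fit$predict(x[te, ])
  pred_ols <- drop(cbind(1, x[te, ]) %*% ols)
  expect_gt(cor(pred_enr, pred_ols), 0.999)
  expect_lt(abs(cor(pred_enr, y[te]) - cor(pred_ols, y[te])), 1e-3)
})

test_that("model coefficients ignore test-block perturbations (no leakage)", {
  co <- generate_cohort(simulation_config(
    n_cell_lines = 100, n_genes = 50, n_drugs = 1, causal_per_drug = 3,
    noise_sd = 0.5, missing_response_fraction = 0, n_classes = 1, seed = 53))
  plan <- make_split(co$expression$cell_line, "enr", 1, 11, "drug_01")
  feats <- sprintf("g%04d", 1:10)
  m <- as.matrix(co$expression[, -1])
  rownames(m) <- co$expression$cell_line
  y <- stats::setNames(co$response$drug_01, co$response$cell_line)
  fit_on <- function(mm) {
    inforx:::fit_enr(mm[plan$train, feats], y[plan$train],
                     mm[plan$validation, feats], y[plan$validation],
                     alpha_grid = seq(0.1, 1, 0.1))$coefficients
  }
  m2 <- m
  m2[plan$test, ] <- m2[plan$test, ] * 5 + 3
  expect_identical(fit_on(m), fit_on(m2))
})

test_that("single-feature sets are modelable", {
  co <- generate_cohort(simulation_config(
    n_cell_lines = 80, n_genes = 30, n_drugs = 1, causal_per_drug = 1,
    noise_sd = 0.2, missing_response_fraction = 0, n_classes = 1, seed = 54))
  plan <- make_split(co$expression$cell_line, "enr", 1, 3, "drug_01")
  out <- fit_predict(co$expression, co$response, "drug_01",
                     co$truth$causal_genes[[1]], plan, "enr")
  expect_equal(out$n_features, 1)
  expect_gt(out$r_pred_obs, 0.8)
})

test_that("kernel and forest learners beat chance on a smooth planted signal", {
  co <- generate_cohort(simulation_config(
    n_cell_lines = 100, n_genes = 40, n_drugs = 1, causal_per_drug = 3,
    noise_sd = 0.5, missing_response_fraction = 0, n_classes = 1, seed = 55))
  feats <- co$truth$causal_genes[[1]]
  cfg <- pipeline_config(n_random_splits = 3, master_seed = 6)
  svr <- run_fixed_pipeline(co$expression, co$response, "drug_01", feats,
                            learner = "svr", config = cfg, method = "svr")
  expect_gt(glance(svr)$mean_r, 0.7)
  rf <- run_fixed_pipeline(co$expression, co$response, "drug_01", feats,
                           learner = "rf", config = cfg, method = "rf")
  expect_gt(glance(rf)$mean_r, 0.7)
})

test_that("comparisons are paired, adjusted, and order-aware", {
  co <- tiny_cohort(seed = 56, C = 90, G = 60, D = 3, k = 4, noise_sd = 0.5,
                    missing = 0, n_classes = 1)
  cfg <- pipeline_config(n_permutations = 6, master_seed = 4)
  drugs <- co$truth$drug_id
  causal_sets <- stats::setNames(co$truth$causal_genes, drugs)
  good <- run_fixed_pipeline(co$expression, co$response, drugs, causal_sets,
                             learner = "enr", config = cfg, method = "causal")
  noise <- run_fixed_pipeline(co$expression, co$response, drugs,
                              sprintf("g%04d", 50:60), learner = "enr",
                              config = cfg, method = "noise")
  fwd <- compare_methods(good, noise)
  expect_true(all(fwd$better))
  rev <- compare_methods(noise, good)
  expect_false(any(rev$better))
  self <- compare_methods(good, good)
  expect_false(any(self$better))
  # identical split plans under the shared master seed make the pairing real
  p1 <- make_split(co$expression$cell_line, "enr", 2, cfg$master_seed, drugs[1])
  p2 <- make_split(co$expression$cell_line, "enr", 2, cfg$master_seed, drugs[1])
  expect_identical(p1$test, p2$test)
})
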