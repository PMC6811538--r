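test_that("the drug-specific pipeline recovers planted signal and logs selections", {
  co <- generate_cohort(simulation_config(
    n_cell_lines = 120, n_genes = 150, n_drugs = 1, causal_per_drug = 4,
    noise_sd = calibrate_noise_sd(4, 0.4), missing_response_fraction = 0,
    n_classes = 1, seed = 71))
  cfg <- pipeline_config(n_permutations = 8, master_seed = 13)
  ev <- run_dsg_pipeline(co$expression, co$response, "drug_01", cfg)
  g <- glance(ev)
  expect_gt(g$mean_r, 0.3)
  counts <- ev$selection_counts
  causal <- co$truth$causal_genes[[1]]
  expect_gt(mean(counts$count[counts$gene_id %in% causal]),
            mean(counts$count[!counts$gene_id %in% causal]))
  expect_true(all(counts$count <= cfg$n_permutations))
  expect_equal(nrow(tidy(ev)), cfg$n_permutations)
})

test_that("per-gene contribution singles out a dominant causal gene", {
  w <- c(sqrt(0.7), rep(sqrt(0.3 / 3), 3))
  co <- generate_cohort(simulation_config(
    n_cell_lines = 100, n_genes = 80, n_drugs = 1, causal_per_drug = 4,
    weights = w, noise_sd = 0.3, missing_response_fraction = 0,
    n_classes = 1, seed = 72))
  causal <- co$truth$causal_genes[[1]]
  contrib <- gene_contribution(co$expression, co$response, "drug_01",
                               c(causal, "g0070", "g0071"),
                               pipeline_config(n_permutations = 4, master_seed = 5))
  expect_equal(contrib$gene_id[1], causal[1]) # sorted by delta_r
  expect_error(gene_contribution(co$expression, co$response, "drug_01",
                                 causal[1]), "at least 2")
})

test_that("class leave-one-out transfers response between clone drugs but not strangers", {
  clones <- generate_cohort(simulation_config(
    n_cell_lines = 120, n_genes = 150, n_drugs = 3, causal_per_drug = 4,
    noise_sd = 0.5, missing_response_fraction = 0, n_classes = 1,
    class_overlap = 1, seed = 73))
  cfg <- pipeline_config(n_permutations = 5, master_seed = 19)
  loo <- class_loo_predict(clones$expression, clones$response,
                           clones$annotation, "drug_01", cfg)
  expect_gt(glance(loo)$mean_r, 0.5)
  expect_match(loo$method, "label_transfer")
  strangers <- generate_cohort(simulation_config(
    n_cell_lines = 120, n_genes = 150, n_drugs = 3, causal_per_drug = 4,
    noise_sd = 0.5, missing_response_fraction = 0, n_classes = 1,
    class_overlap = 0, seed = 74))
  loo0 <- class_loo_predict(strangers$expression, strangers$response,
                            strangers$annotation, "drug_01", cfg)
  expect_lt(abs(glance(loo0)$mean_r), 0.35)
  ft <- class_loo_predict(clones$expression, clones$response,
                          clones$annotation, "drug_01",
                          pipeline_config(n_permutations = 2, master_seed = 19),
                          mode = "feature_transfer")
  expect_match(ft$method, "feature_transfer")
})

test_that("run_all writes a complete, reproducible result directory", {
  cfg <- list(
    simulate = list(n_cell_lines = 60, n_genes = 80, n_drugs = 3,
                    causal_per_drug = 4, noise_sd = 1, n_classes = 1,
                    class_overlap = 0, seed = 5),
    pipeline = list(n_permutations = 3, n_random_splits = 3, dug_top_n = 40,
                    master_seed = 2)
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressWarnings(run_all(cfg, d1))
  suppressWarnings(run_all(cfg, d2))
  expect_true(all(c("evaluation_summary.tsv", "selection_frequency.tsv",
                    "dug_genes.tsv", "manifest.json",
                    "comparison_dsg_vs_baseline.tsv") %in% list.files(d1)))
  s1 <- readLines(file.path(d1, "evaluation_summary.tsv"))
  s2 <- readLines(file.path(d2, "evaluation_summary.tsv"))
  expect_identical(s1, s2)
  summary <- readr::read_tsv(file.path(d1, "evaluation_summary.tsv"),
                             show_col_types = FALSE)
  expect_setequal(unique(summary$method),
                  c("whole_genome_enr", "dug_svr", "dsg_enr"))
  expect_equal(sum(summary$method == "dsg_enr"), 3) # one row per drug
  rep_ <- report(d1)
  expect_equal(nrow(rep_$best_method), 3)
  expect_error(report(withr::local_tempdir()), "incomplete run")
  expect_error(run_all(list(pipeline = list()), withr::local_tempdir()),
               "simulate")
})

test_that("evaluation plots and tidiers return well-formed objects", {
  co <- tiny_cohort(seed = 75, C = 60, G = 40, D = 2, missing = 0,
                    n_classes = 1)
  ev <- run_fixed_pipeline(co$expression, co$response, co$truth$drug_id,
                           sprintf("g%04d", 1:10), learner = "enr",
                           config = pipeline_config(n_permutations = 3,
                                                    master_seed = 1),
                           method = "demo")
  td <- tidy(ev)
  expect_true(all(c("method", "drug_id", "permutation", "r_pred_obs") %in% names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 2)
  p1 <- ggplot2::autoplot(ev)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_method_comparison(gl)
  expect_s3_class(p2, "ggplot")
  screen <- select_dsg(co$expression, co$response, "drug_01")
  p3 <- plot_dsg_screen(screen)
  expect_s3_class(p3, "ggplot")
})
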