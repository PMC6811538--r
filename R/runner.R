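# End-to-end orchestration: one configuration (R list or YAML file) drives
# simulate/load -> context sets -> DUG/DSG selection -> modeling ->
# downstream reports, with a manifest capturing everything needed to
# reproduce the run.

load_run_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim <- do.call(simulation_config, sim_args)
    cohort <- generate_cohort(sim)
    list(expression = cohort$expression, response = cohort$response,
         annotation = cohort$annotation, truth = cohort$truth,
         simulated = TRUE)
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    if (is.null(inp$expression) || is.null(inp$response)) {
      abort("config must provide either a `simulate` block or `inputs` with `expression` and `response` paths")
    }
    list(
      expression = zscore_cell_lines(read_expression(inp$expression,
                                                     isTRUE(inp$transpose))),
      response = read_response(inp$response, isTRUE(inp$transpose)),
      annotation = if (!is.null(inp$annotation)) read_drug_annotation(inp$annotation),
      truth = NULL, simulated = FALSE
    )
  } else {
    abort("config must provide either a `simulate` block or `inputs` with `expression` and `response` paths")
  }
}

#' Run the full pipeline from a configuration
#'
#' Loads or simulates the cohort, selects the drug-unspecific set, runs the
#' requested methods per drug, compares each to the all-genes baseline when
#' present, and writes per-method summaries, the selection-frequency table,
#' drug-unique genes, and a reproducibility manifest into `out_dir`.
#'
#' @param config A configuration list or path to a YAML file. Blocks:
#'   `simulate` (arguments of [simulation_config()]) or `inputs`
#'   (`expression` / `response` / `annotation` paths), optional `pipeline`
#'   (arguments of [pipeline_config()]), optional `methods` (subset of
#'   `"dsg"`, `"dug"`, `"baseline"`; default all three).
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly; side effect: result files.
#' @export
run_all <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  pcfg <- do.call(pipeline_config, cfg$pipeline %||% list())
  methods <- cfg$methods %||% c("dsg", "dug", "baseline")
  dat <- load_run_inputs(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  drugs <- setdiff(names(dat$response), "cell_line")
  drugs <- drugs[map_lgl(drugs, function(d) {
    sum(!is.na(dat$response[[d]])) >= max(30, pcfg$min_response_n)
  })]
  if (length(drugs) == 0) abort("no modelable drug (too few non-missing responses)")
  genes_all <- setdiff(names(dat$expression), "cell_line")

  evals <- list()
  if ("baseline" %in% methods) {
    evals$baseline <- run_fixed_pipeline(dat$expression, dat$response, drugs,
                                         genes_all, learner = "enr",
                                         config = pcfg, method = "whole_genome_enr")
  }
  if ("dug" %in% methods) {
    dug <- select_dug(dat$expression, top_n = pcfg$dug_top_n,
                      redundancy_r = pcfg$redundancy_r_threshold)
    readr::write_tsv(dug, file.path(out_dir, "dug_genes.tsv"), progress = FALSE)
    evals$dug <- run_dug_pipeline(dat$expression, dat$response, drugs, dug,
                                  config = pcfg)
  }
  if ("dsg" %in% methods) {
    evals$dsg <- run_dsg_pipeline(dat$expression, dat$response, drugs,
                                  config = pcfg)
    readr::write_tsv(evals$dsg$selection_counts,
                     file.path(out_dir, "selection_frequency.tsv"),
                     progress = FALSE)
    n_drugs_total <- length(unique(evals$dsg$selection_counts$drug_id))
    if (n_drugs_total >= 3) {
      readr::write_tsv(drug_unique_genes(evals$dsg$selection_counts,
                                         pcfg$uniqueness_z_threshold),
                       file.path(out_dir, "drug_unique_genes.tsv"),
                       progress = FALSE)
    }
  }

  summaries <- bind_rows(map(evals, glance))
  readr::write_tsv(summaries, file.path(out_dir, "evaluation_summary.tsv"),
                   progress = FALSE)
  for (nm in names(evals)) {
    out <- tidy(evals[[nm]]) |>
      select(-dplyr::any_of(c("test_cells", "predicted", "observed")))
    readr::write_tsv(out, file.path(out_dir, sprintf("outcomes_%s.tsv", nm)),
                     progress = FALSE)
  }
  if ("baseline" %in% names(evals)) {
    for (nm in setdiff(names(evals), "baseline")) {
      cmp <- compare_methods(evals[[nm]], evals$baseline,
                             alpha = pcfg$significance_alpha)
      readr::write_tsv(cmp, file.path(out_dir,
                                      sprintf("comparison_%s_vs_baseline.tsv", nm)),
                       progress = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("inforx")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = pcfg$master_seed,
    config = cfg,
    drugs = drugs,
    input_checksums = if (!is.null(cfg$inputs)) {
      as.list(tools::md5sum(unlist(cfg$inputs[map_lgl(cfg$inputs, is.character)])))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Summarize a completed run directory
#'
#' Pure function of the files [run_all()] wrote (no recomputation): reads
#' the per-method summaries and ranks the methods per drug by mean
#' predicted/observed correlation.
#'
#' @param results_dir Directory produced by [run_all()].
#' @return A list `summary` (per method x drug tibble), `ranking` (per drug,
#'   methods ordered best first), `best_method` (per drug winner).
#' @export
report <- function(results_dir) {
  path <- file.path(results_dir, "evaluation_summary.tsv")
  if (!file.exists(path)) {
    abort(sprintf("incomplete run: missing %s", path))
  }
  summary <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ranking <- summary |>
    group_by(.data$drug_id) |>
    arrange(desc(.data$mean_r), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  best <- ranking |> filter(.data$rank == 1) |>
    select("drug_id", best_method = "method", best_mean_r = "mean_r")
  list(summary = summary, ranking = ranking, best_method = best)
}
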