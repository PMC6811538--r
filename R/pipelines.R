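# Permutation pipelines tying selection, splitting and learning together,
# and the evaluation container their results live in.

new_eval <- function(outcomes, method, config, selection_counts = NULL,
                     screens = NULL) {
  structure(list(outcomes = outcomes, method = method, config = config,
                 selection_counts = selection_counts, screens = screens),
            class = "inforx_eval")
}

usable_cells <- function(response, drug) {
  response$cell_line[!is.na(response[[drug]])]
}

#' Per-permutation outcomes of an evaluation
#'
#' @param x An `inforx_eval` from [run_dsg_pipeline()], [run_dug_pipeline()]
#'   or [run_fixed_pipeline()].
#' @param ... Unused.
#' @return The tibble of per-permutation [fit_predict()] outcomes with a
#'   `method` column.
#' @method tidy inforx_eval
#' @export
tidy.inforx_eval <- function(x, ...) {
  mutate(x$outcomes, method = x$method, .before = 1)
}

#' Per-drug summary of an evaluation
#'
#' Averages the non-degenerate permutations: mean and sd of the
#' predicted/observed correlation, its Monte-Carlo standard error, and the
#' mean absolute error.
#'
#' @inheritParams tidy.inforx_eval
#' @return One row per drug: `method`, `drug_id`, `n_permutations`,
#'   `mean_r`, `sd_r`, `mc_se_r`, `mean_mae`, `mean_n_features`.
#' @method glance inforx_eval
#' @export
glance.inforx_eval <- function(x, ...) {
  x$outcomes |>
    filter(!.data$degenerate, !is.na(.data$r_pred_obs)) |>
    group_by(.data$drug_id) |>
    summarise(
      n_permutations = dplyr::n(),
      mean_r = mean(.data$r_pred_obs),
      sd_r = if (dplyr::n() >= 2) sd(.data$r_pred_obs) else NA_real_,
      mc_se_r = if (dplyr::n() >= 2) sd(.data$r_pred_obs) / sqrt(dplyr::n()) else NA_real_,
      mean_mae = mean(.data$mae),
      mean_n_features = mean(.data$n_features),
      .groups = "drop"
    ) |>
    mutate(method = x$method, .before = 1)
}

#' @export
print.inforx_eval <- function(x, ...) {
  cat(sprintf("<inforx evaluation: %s>\n", x$method))
  print(glance(x))
  invisible(x)
}

#' Evaluate a fixed feature set under a split protocol
#'
#' Runs [fit_predict()] over the configured permutations of each drug's
#' usable cells with a feature set that does not change across permutations
#' (the whole genome, a target-context set, the drug-unspecific set, a
#' random control, ...).
#'
#' @param expr,response Sample tables.
#' @param drugs Drug ids to evaluate.
#' @param features Gene ids / gene-set tibble used for every drug, or a
#'   named list mapping drug id to its feature set.
#' @param learner `"enr"`, `"svr"` or `"rf"`.
#' @param protocol Split protocol; defaults to `"enr"` (80/10/10,
#'   `n_permutations` permutations) for the elastic net and `"svr"` (90/10,
#'   `n_random_splits` splits) otherwise.
#' @param config An [pipeline_config()].
#' @param method Label recorded in the results.
#' @return An `inforx_eval`; see [tidy.inforx_eval()] and
#'   [glance.inforx_eval()].
#' @export
run_fixed_pipeline <- function(expr, response, drugs, features,
                               learner = "enr", protocol = NULL,
                               config = pipeline_config(),
                               method = paste0("fixed_", learner)) {
  protocol <- protocol %||% if (learner == "enr") "enr" else "svr"
  n_perm <- if (protocol == "enr") config$n_permutations else config$n_random_splits
  feature_for <- function(d) {
    if (is.list(features) && !is.data.frame(features) && !is.null(names(features))) {
      features[[d]]
    } else features
  }
  outcomes <- map(drugs, function(d) {
    cells <- usable_cells(response, d)
    map(seq_len(n_perm), function(p) {
      plan <- make_split(cells, protocol, p, config$master_seed, d,
                         enr_fractions = config$enr_fractions,
                         svr_train_fraction = config$svr_train_fraction)
      fit_predict(expr, response, d, feature_for(d), plan, learner, config)
    }) |> bind_rows()
  }) |> bind_rows()
  new_eval(outcomes, method, config)
}

#' Drug-specific-gene pipeline
#'
#' For each permutation of a drug's usable cells: build the 80/10/10 split,
#' screen drug-specific genes on the *training block only*, fit the elastic
#' net on the selected genes, and score the test block. Selection counts per
#' gene are accumulated across permutations (the substrate of the
#' drug-unique-gene rule). Permutations whose screen selects nothing are
#' recorded but not modeled; a drug whose every permutation comes up empty
#' is reported as having no drug-specific genes.
#'
#' @inheritParams run_fixed_pipeline
#' @return An `inforx_eval` whose `selection_counts` element is a tibble
#'   `drug_id`, `gene_id`, `count`, `n_permutations`, and whose outcomes
#'   carry `n_selected` per permutation.
#' @export
run_dsg_pipeline <- function(expr, response, drugs, config = pipeline_config(),
                             method = "dsg_enr") {
  genes_all <- setdiff(names(expr), "cell_line")
  res <- map(drugs, function(d) {
    cells <- usable_cells(response, d)
    counts <- setNames(integer(length(genes_all)), genes_all)
    rows <- list()
    for (p in seq_len(config$n_permutations)) {
      plan <- make_split(cells, "enr", p, config$master_seed, d,
                         enr_fractions = config$enr_fractions,
                         svr_train_fraction = config$svr_train_fraction)
      screen <- suppressWarnings(
        select_dsg(expr, response, d, cells = plan$train,
                   fraction = config$extreme_fraction,
                   r_threshold = config$dsg_r_threshold)
      )
      sel <- screen$gene_id[screen$selected]
      counts[sel] <- counts[sel] + 1L
      if (length(sel) == 0) {
        rows[[p]] <- tibble(drug_id = d, permutation = p, learner = "enr",
                            n_features = 0L, r_pred_obs = NA_real_,
                            mae = NA_real_, degenerate = NA,
                            test_cells = list(plan$test),
                            predicted = list(NULL), observed = list(NULL),
                            n_selected = 0L)
      } else {
        out <- fit_predict(expr, response, d, sel, plan, "enr", config)
        out$n_selected <- length(sel)
        rows[[p]] <- out
      }
    }
    if (all(bind_rows(rows)$n_selected == 0)) {
      warn(sprintf("drug '%s': no drug-specific gene in any permutation", d))
    }
    list(outcomes = bind_rows(rows),
         counts = tibble(drug_id = d, gene_id = genes_all,
                         count = unname(counts),
                         n_permutations = config$n_permutations))
  })
  outcomes <- bind_rows(map(res, "outcomes")) |>
    mutate(degenerate = ifelse(is.na(.data$degenerate), FALSE, .data$degenerate))
  counts <- bind_rows(map(res, "counts"))
  new_eval(outcomes, method, config, selection_counts = counts)
}

#' Drug-unspecific-gene pipeline
#'
#' Evaluates the fixed drug-unspecific gene set for each drug under the
#' 90/10 random-split protocol with the Gaussian-kernel support vector
#' learner (hyperparameters tuned by inner 5-fold cross-validation).
#'
#' @inheritParams run_fixed_pipeline
#' @param dug_genes The drug-unspecific gene set ([select_dug()] result or
#'   gene ids).
#' @export
run_dug_pipeline <- function(expr, response, drugs, dug_genes,
                             config = pipeline_config(), method = "dug_svr") {
  run_fixed_pipeline(expr, response, drugs, dug_genes, learner = "svr",
                     protocol = "svr", config = config, method = method)
}

#' Compare two methods drug by drug
#'
#' Welch's t-test on the per-permutation correlation vectors of each drug,
#' Benjamini-Hochberg adjusted across the drug family; a drug counts as
#' "better" under method `a` when the adjusted p-value clears `alpha` *and*
#' the mean correlation is higher.
#'
#' @param a,b `inforx_eval` objects (or their [tidy()] tibbles) covering the
#'   same drugs. Pair them on identical split plans (same master seed) so
#'   differences are attributable to the features, not the splits.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A tibble `drug_id`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `p_adjusted`, `better`.
#' @export
compare_methods <- function(a, b, alpha = 0.05) {
  ta <- if (inherits(a, "inforx_eval")) tidy(a) else a
  tb <- if (inherits(b, "inforx_eval")) tidy(b) else b
  drugs <- intersect(unique(ta$drug_id), unique(tb$drug_id))
  rows <- map(drugs, function(d) {
    ra <- ta$r_pred_obs[ta$drug_id == d & !is.na(ta$r_pred_obs)]
    rb <- tb$r_pred_obs[tb$drug_id == d & !is.na(tb$r_pred_obs)]
    if (length(ra) < 3 || length(rb) < 3) {
      # too few permutations for a test: report means, no significance call
      return(tibble(drug_id = d, mean_a = mean(ra), mean_b = mean(rb),
                    statistic = NA_real_, p_value = NA_real_))
    }
    ht <- welch_t_test(ra, rb)
    tibble(drug_id = d, mean_a = mean(ra), mean_b = mean(rb),
           statistic = ht$statistic, p_value = ht$p_value)
  }) |> bind_rows()
  rows$p_adjusted <- NA_real_
  tested <- !is.na(rows$p_value)
  rows$p_adjusted[tested] <- bh_adjust(rows$p_value[tested])
  rows$better <- tested & rows$p_adjusted < alpha & rows$mean_a > rows$mean_b
  rows
}
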