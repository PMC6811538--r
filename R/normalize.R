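# Normalization conventions. Two distinct steps:
#  * within-cell-line z-scoring across genes — the panel-wide preprocessing
#    convention applied once to the raw expression matrix;
#  * per-gene standardization estimated on a training block — applied before
#    each penalized fit, training statistics only, so no test leakage.

#' Z-score expression within each cell line
#'
#' Each row (cell line) is transformed to `(x - mean) / sd` across its genes,
#' with the sample (n - 1) standard deviation. This is the panel-wide
#' preprocessing convention; it makes expression comparable across arrays.
#'
#' @param expr Expression table from [read_expression()] or
#'   [generate_cohort()].
#' @return The table with every row standardized and attribute
#'   `normalized = TRUE`.
#' @export
#' @examples
#' expr <- tibble::tibble(cell_line = "c1", g1 = 1, g2 = 2, g3 = 3)
#' zscore_cell_lines(expr)
zscore_cell_lines <- function(expr) {
  ix_assert_sample_table(expr, "expression table")
  m <- ix_values(expr)
  if (anyNA(m) || any(!is.finite(m))) abort("expression values must be finite")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  zero <- which(s == 0)
  if (length(zero) > 0) {
    abort(sprintf("cell line '%s' has constant expression; cannot z-score",
                  rownames(m)[zero[1]]))
  }
  ix_table((m - mu) / s, normalized = TRUE)
}

#' Is an expression table flagged as within-cell-line normalized?
#'
#' @param expr Expression table.
#' @return `TRUE` or `FALSE`.
#' @export
is_normalized <- function(expr) isTRUE(attr(expr, "normalized"))

#' Standardize genes with training-block statistics
#'
#' Per-gene mean and sample standard deviation are estimated on `train` only
#' and applied to `apply_to`, so held-out cells never inform the scaling.
#' Genes constant in the training block cannot be standardized and are
#' dropped from the result with a warning.
#'
#' @param train Expression table restricted to the training cell lines.
#' @param apply_to Expression table to transform (defaults to `train`); its
#'   genes must be a subset of the training genes.
#' @return `apply_to` with each retained gene scaled to training mean 0 and
#'   unit training sd.
#' @export
standardize_genes <- function(train, apply_to = train) {
  ix_assert_sample_table(train, "training expression")
  ix_assert_sample_table(apply_to, "expression to transform")
  tr <- ix_values(train)
  ap <- ix_values(apply_to)
  common <- intersect(colnames(ap), colnames(tr))
  if (length(common) == 0) abort("no gene overlap between training and target table")
  tr <- tr[, common, drop = FALSE]
  ap <- ap[, common, drop = FALSE]
  mu <- colMeans(tr)
  s <- sqrt(col_vars(tr))
  keep <- s > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d gene(s) constant in the training block (e.g. '%s')",
                 sum(!keep), common[!keep][1]))
  }
  scaled <- sweep(sweep(ap[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  ix_table(scaled, normalized = attr(apply_to, "normalized"))
}

#' Assemble the pipeline configuration
#'
#' Central home for every threshold and protocol constant used by the
#' selection and modeling stages, validated on construction.
#'
#' @param extreme_fraction Fraction of training cells taken from each
#'   expression tail in the drug-specific screen (default 0.10).
#' @param dsg_r_threshold Inclusive absolute-correlation threshold for
#'   selecting a drug-specific gene (default 0.4).
#' @param dug_top_n Number of top-variance genes entering the drug-unspecific
#'   set (default 5000, capped at the gene count when applied).
#' @param dug_candidate_sizes Size grid explored for the drug-unspecific set.
#' @param redundancy_r_threshold Absolute-correlation threshold for the
#'   redundancy clustering of top-variance genes (default 0.8).
#' @param string_score_floor Strict lower bound on interaction scores used in
#'   target-neighborhood expansion (default 0.9).
#' @param uniqueness_z_threshold Z-score cutoff of the drug-unique-gene rule
#'   (default 3).
#' @param n_permutations Cell-line permutations per drug for the
#'   split/selection protocols (default 100; large screens use 10000).
#' @param n_random_splits Random 90/10 splits of the drug-unspecific
#'   protocol (default 10).
#' @param enr_fractions Train/test/validation fractions of the elastic-net
#'   protocol (must sum to 1).
#' @param svr_train_fraction Training fraction of the kernel-regression
#'   protocol; the rest is the test block, tuning folds live inside training.
#' @param svr_inner_folds Inner cross-validation folds for kernel tuning.
#' @param enr_alpha_grid Elastic-net mixing-parameter grid.
#' @param svr_cost_grid,svr_gamma_factors,svr_epsilon_grid Kernel-regression
#'   tuning grid: cost values, multipliers of the median-heuristic inverse
#'   squared bandwidth, and epsilon-tube widths.
#' @param rf_num_trees Trees for the random-forest learner.
#' @param min_response_n Minimum non-missing responses for a drug to be
#'   modelable.
#' @param significance_alpha Adjusted-p cutoff for method comparisons.
#' @param master_seed Integer master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @return A list of class `inforx_config`.
#' @export
pipeline_config <- function(extreme_fraction = 0.10,
                            dsg_r_threshold = 0.4,
                            dug_top_n = 5000,
                            dug_candidate_sizes = c(25, 100, 1000, 5000, 10000),
                            redundancy_r_threshold = 0.8,
                            string_score_floor = 0.9,
                            uniqueness_z_threshold = 3,
                            n_permutations = 100,
                            n_random_splits = 10,
                            enr_fractions = c(train = 0.8, test = 0.1, validation = 0.1),
                            svr_train_fraction = 0.9,
                            svr_inner_folds = 5,
                            enr_alpha_grid = seq(0.1, 1, by = 0.1),
                            svr_cost_grid = c(0.1, 1, 10),
                            svr_gamma_factors = c(0.5, 1, 2),
                            svr_epsilon_grid = c(0.01, 0.1),
                            rf_num_trees = 500,
                            min_response_n = 10,
                            significance_alpha = 0.05,
                            master_seed = 1L) {
  stopifnot(
    extreme_fraction > 0, extreme_fraction < 1,
    dsg_r_threshold >= 0, dsg_r_threshold <= 1,
    dug_top_n >= 1,
    redundancy_r_threshold > 0, redundancy_r_threshold <= 1,
    string_score_floor >= 0, string_score_floor <= 1,
    uniqueness_z_threshold > 0,
    n_permutations >= 1, n_random_splits >= 1,
    length(enr_fractions) == 3, all(enr_fractions > 0),
    abs(sum(enr_fractions) - 1) < 1e-9,
    svr_train_fraction > 0, svr_train_fraction < 1,
    svr_inner_folds >= 2,
    all(enr_alpha_grid > 0 & enr_alpha_grid <= 1),
    significance_alpha > 0, significance_alpha < 1
  )
  structure(
    list(
      extreme_fraction = extreme_fraction,
      dsg_r_threshold = dsg_r_threshold,
      dug_top_n = dug_top_n,
      dug_candidate_sizes = dug_candidate_sizes,
      redundancy_r_threshold = redundancy_r_threshold,
      string_score_floor = string_score_floor,
      uniqueness_z_threshold = uniqueness_z_threshold,
      n_permutations = as.integer(n_permutations),
      n_random_splits = as.integer(n_random_splits),
      enr_fractions = enr_fractions,
      svr_train_fraction = svr_train_fraction,
      svr_inner_folds = as.integer(svr_inner_folds),
      enr_alpha_grid = enr_alpha_grid,
      svr_cost_grid = svr_cost_grid,
      svr_gamma_factors = svr_gamma_factors,
      svr_epsilon_grid = svr_epsilon_grid,
      rf_num_trees = as.integer(rf_num_trees),
      min_response_n = as.integer(min_response_n),
      significance_alpha = significance_alpha,
      master_seed = as.integer(master_seed)
    ),
    class = "inforx_config"
  )
}

#' @export
print.inforx_config <- function(x, ...) {
  cat("<inforx pipeline configuration>\n")
  cat(sprintf("  DSG screen: %.0f%% tails, |r| >= %.2f\n",
              100 * x$extreme_fraction, x$dsg_r_threshold))
  cat(sprintf("  DUG: top %d by variance, redundancy |r| >= %.2f\n",
              x$dug_top_n, x$redundancy_r_threshold))
  cat(sprintf("  Protocols: ENR %d permutations (%.0f/%.0f/%.0f), SVR %d splits (%.0f/%.0f)\n",
              x$n_permutations, 100 * x$enr_fractions[1], 100 * x$enr_fractions[2],
              100 * x$enr_fractions[3], x$n_random_splits,
              100 * x$svr_train_fraction, 100 * (1 - x$svr_train_fraction)))
  cat(sprintf("  Master seed: %d\n", x$master_seed))
  invisible(x)
}
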