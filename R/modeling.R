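# Split protocols and learner contracts.
#
# Two permutation protocols:
#  * "enr"  — 80/10/10 train/test/validation; elastic-net mixing and penalty
#    are tuned once per permutation on the validation block;
#  * "svr"  — 90/10 train/test; kernel-regression (and forest)
#    hyperparameters are tuned by 5-fold cross-validation inside training.
# All shuffles derive from (master_seed, drug, protocol, permutation) so
# paired method comparisons can reuse identical splits.

#' Build a train/test(/validation) split plan
#'
#' Cells are shuffled by a seed derived from `(master_seed, drug, protocol,
#' permutation)` and cut into contiguous blocks: first 80% / next 10% / last
#' 10% as train/test/validation under the `"enr"` protocol, first 90% / last
#' 10% as train/test under `"svr"`.
#'
#' @param cells Character vector of usable cell-line ids (non-missing
#'   response for the drug); at least 30.
#' @param protocol `"enr"` or `"svr"`.
#' @param permutation Permutation index (1-based).
#' @param master_seed Integer master seed.
#' @param drug Drug id entering the seed derivation.
#' @param enr_fractions,svr_train_fraction Block fractions (defaults as in
#'   [pipeline_config()]).
#' @return A list of class `inforx_split` with elements `train`, `test`,
#'   `validation` (empty for `"svr"`), `protocol`, `permutation`, `seed`.
#' @export
make_split <- function(cells, protocol = c("enr", "svr"), permutation = 1,
                       master_seed = 1L, drug = "",
                       enr_fractions = c(0.8, 0.1, 0.1),
                       svr_train_fraction = 0.9) {
  protocol <- match.arg(protocol)
  n <- length(cells)
  if (n < 30) abort(sprintf("need at least 30 usable cells, got %d", n))
  seed <- child_seed(master_seed, "split", drug, protocol, permutation)
  shuffled <- with_seed(seed, sample(cells))
  if (protocol == "enr") {
    stopifnot(length(enr_fractions) == 3, abs(sum(enr_fractions) - 1) < 1e-9)
    n_tr <- floor(enr_fractions[1] * n)
    n_te <- floor(enr_fractions[2] * n)
    plan <- list(train = shuffled[seq_len(n_tr)],
                 test = shuffled[n_tr + seq_len(n_te)],
                 validation = shuffled[(n_tr + n_te + 1):n])
  } else {
    n_tr <- floor(svr_train_fraction * n)
    plan <- list(train = shuffled[seq_len(n_tr)],
                 test = shuffled[(n_tr + 1):n],
                 validation = character(0))
  }
  structure(c(plan, list(protocol = protocol, permutation = permutation,
                         seed = seed, drug = drug)),
            class = "inforx_split")
}

# ---- learners (internal) ----------------------------------------------------

# glmnet requires >= 2 columns; pad single-feature problems with an inert
# zero column whose coefficient stays at zero.
pad_features <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

fit_enr <- function(x_tr, y_tr, x_val, y_val, alpha_grid) {
  x_tr <- pad_features(x_tr)
  x_val <- pad_features(x_val)
  best <- NULL
  for (alpha in alpha_grid) {
    fit <- glmnet::glmnet(x_tr, y_tr, alpha = alpha, standardize = FALSE)
    pred <- predict(fit, x_val)
    mse <- colMeans((pred - y_val)^2)
    j <- which.min(mse)
    if (is.null(best) || mse[j] < best$mse) {
      best <- list(fit = fit, alpha = alpha, lambda = fit$lambda[j], mse = mse[j])
    }
  }
  list(
    predict = function(x_new) {
      drop(predict(best$fit, pad_features(x_new), s = best$lambda))
    },
    alpha = best$alpha, lambda = best$lambda,
    coefficients = drop(predict(best$fit, s = best$lambda, type = "coefficients"))
  )
}

# Gaussian-kernel support vector regression tuned by inner k-fold CV on a
# precomputed Gram matrix: the pairwise squared distances are computed once
# per split and re-exponentiated per candidate bandwidth.
fit_svr <- function(x_tr, y_tr, cost_grid, gamma_factors, epsilon_grid,
                    n_folds = 5, fold_seed = 1L) {
  n <- nrow(x_tr)
  d2 <- as.matrix(stats::dist(x_tr))^2
  med <- median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  gammas <- gamma_factors / med
  folds <- with_seed(fold_seed, sample(rep_len(seq_len(n_folds), n)))
  best <- NULL
  for (gamma in gammas) {
    k_full <- exp(-gamma * d2)
    for (cost in cost_grid) {
      for (eps in epsilon_grid) {
        errs <- numeric(n_folds)
        for (f in seq_len(n_folds)) {
          tr <- which(folds != f); va <- which(folds == f)
          m <- kernlab::ksvm(kernlab::as.kernelMatrix(k_full[tr, tr, drop = FALSE]),
                             y_tr[tr], type = "eps-svr", C = cost, epsilon = eps,
                             kernel = "matrix")
          kv <- k_full[va, tr, drop = FALSE][, kernlab::SVindex(m), drop = FALSE]
          pv <- kernlab::predict(m, kernlab::as.kernelMatrix(kv))
          errs[f] <- mean((drop(pv) - y_tr[va])^2)
        }
        mse <- mean(errs)
        if (is.null(best) || mse < best$mse) {
          best <- list(gamma = gamma, cost = cost, epsilon = eps, mse = mse)
        }
      }
    }
  }
  k_best <- exp(-best$gamma * d2)
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(k_best), y_tr,
                         type = "eps-svr", C = best$cost,
                         epsilon = best$epsilon, kernel = "matrix")
  sv <- kernlab::SVindex(model)
  list(
    predict = function(x_new) {
      cross <- outer(rowSums(x_new^2), rowSums(x_tr^2), "+") -
        2 * x_new %*% t(x_tr)
      cross[cross < 0] <- 0
      kx <- exp(-best$gamma * cross)[, sv, drop = FALSE]
      drop(kernlab::predict(model, kernlab::as.kernelMatrix(kx)))
    },
    gamma = best$gamma, cost = best$cost, epsilon = best$epsilon
  )
}

fit_rf <- function(x_tr, y_tr, num_trees = 500, seed = 1L) {
  df <- as.data.frame(x_tr)
  df$.response <- y_tr
  model <- ranger::ranger(
    dependent.variable.name = ".response", data = df,
    num.trees = num_trees, mtry = ceiling(sqrt(ncol(x_tr))), seed = seed
  )
  list(predict = function(x_new) {
    predict(model, data = as.data.frame(x_new))$predictions
  })
}

# ---- fit / predict ----------------------------------------------------------

as_feature_genes <- function(features) {
  if (is.character(features)) return(unique(features))
  if (is.data.frame(features)) {
    if ("genes" %in% names(features)) return(unique(unlist(features$genes)))
    if ("gene_id" %in% names(features)) {
      if ("selected" %in% names(features)) {
        return(unique(features$gene_id[features$selected]))
      }
      return(unique(features$gene_id))
    }
  }
  abort("features must be gene ids or a gene-set / screen tibble")
}

#' Fit a learner on one split and score held-out predictions
#'
#' Features are standardized per gene with training-block statistics, the
#' learner is tuned (elastic net on the validation block; kernel regression
#' by inner cross-validation), fit on the training block, and scored on the
#' test block with the Pearson correlation of predicted versus observed
#' ln IC50 and the mean absolute error.
#'
#' A constant observed test vector makes the correlation undefined: the
#' outcome is flagged `degenerate` and carries `r_pred_obs = NA` so
#' summaries can drop it. A constant *prediction* vector (a null model that
#' selected nothing) scores `r_pred_obs = 0`: no predictive information.
#'
#' @param expr Expression sample table.
#' @param response Response sample table.
#' @param drug Drug id.
#' @param features Gene ids (character), a gene-set tibble row, or a
#'   [select_dsg()] screen.
#' @param plan An [make_split()] plan.
#' @param learner `"enr"`, `"svr"` or `"rf"`.
#' @param config An [pipeline_config()].
#' @return A one-row tibble: `drug_id`, `permutation`, `learner`,
#'   `n_features`, `r_pred_obs`, `mae`, `degenerate`, plus list-columns
#'   `test_cells`, `predicted`, `observed`.
#' @export
fit_predict <- function(expr, response, drug, features, plan,
                        learner = c("enr", "svr", "rf"),
                        config = pipeline_config()) {
  learner <- match.arg(learner)
  genes <- as_feature_genes(features)
  if (length(genes) == 0) abort("empty feature set")
  m <- ix_values(expr)
  missing_genes <- setdiff(genes, colnames(m))
  if (length(missing_genes) > 0) {
    abort(sprintf("feature gene '%s' absent from the expression table",
                  missing_genes[1]))
  }
  if (length(plan$train) < 20) abort("training block must hold at least 20 cells")
  y_all <- setNames(response[[drug]], response$cell_line)

  # training-only standardization, applied to every block
  tr_raw <- m[plan$train, genes, drop = FALSE]
  mu <- colMeans(tr_raw)
  s <- sqrt(col_vars(tr_raw))
  keep <- s > 0
  if (!any(keep)) abort("all features are constant in the training block")
  genes <- genes[keep]
  scale_block <- function(ids) {
    sweep(sweep(m[ids, genes, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  }
  x_tr <- scale_block(plan$train); y_tr <- y_all[plan$train]
  x_te <- scale_block(plan$test);  y_te <- y_all[plan$test]

  model <- switch(
    learner,
    enr = {
      if (length(plan$validation) >= 2) {
        fit_enr(x_tr, y_tr, scale_block(plan$validation),
                y_all[plan$validation], config$enr_alpha_grid)
      } else {
        # no validation block in the plan: tune on an inner 80/20 cut
        n_in <- floor(0.8 * nrow(x_tr))
        fit_enr(x_tr[seq_len(n_in), , drop = FALSE], y_tr[seq_len(n_in)],
                x_tr[-seq_len(n_in), , drop = FALSE], y_tr[-seq_len(n_in)],
                config$enr_alpha_grid)
      }
    },
    svr = fit_svr(x_tr, y_tr, config$svr_cost_grid, config$svr_gamma_factors,
                  config$svr_epsilon_grid, config$svr_inner_folds,
                  fold_seed = child_seed(plan$seed, "folds")),
    rf = fit_rf(x_tr, y_tr, config$rf_num_trees,
                seed = child_seed(plan$seed, "rf"))
  )
  pred <- model$predict(x_te)
  # score on the test cells whose response is observed for this drug
  ok <- !is.na(y_te)
  degenerate <- sum(ok) < 3 || sd(y_te[ok]) == 0
  r <- if (degenerate) NA_real_ else if (sd(pred[ok]) == 0) 0 else cor(pred[ok], y_te[ok])
  tibble(
    drug_id = drug, permutation = plan$permutation, learner = learner,
    n_features = length(genes),
    r_pred_obs = r, mae = mean(abs(pred[ok] - y_te[ok])), degenerate = degenerate,
    test_cells = list(plan$test), predicted = list(unname(pred)),
    observed = list(unname(y_te))
  )
}
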