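# Post-modeling analyses: response binarization and classification metrics,
# drug-unique genes, per-gene contribution, drug similarity (fingerprints and
# IC50 profiles), drug-class leave-one-out transfer, and mutation-response
# association.

#' Binarize a drug's response at its median
#'
#' Cell lines with ln IC50 strictly above the median are labeled
#' `"resistant"`, everything else (including values equal to the median)
#' `"sensitive"`; missing responses stay `NA`.
#'
#' @param values Numeric response vector (optionally named by cell line).
#' @return Character vector of labels, same length and names.
#' @export
#' @examples
#' binarize_by_median(c(1, 2, 3, 4, 5))
binarize_by_median <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) abort("need at least 4 non-missing responses")
  if (max(obs) == min(obs)) abort("degenerate response: all values identical")
  med <- median(obs)
  out <- ifelse(is.na(values), NA_character_,
                ifelse(values > med, "resistant", "sensitive"))
  names(out) <- names(values)
  out
}

#' Confusion-matrix metrics for binarized response
#'
#' `"sensitive"` is the positive class. Precision, recall, specificity and
#' the Matthews correlation coefficient are computed from the confusion
#' counts; any metric with a zero denominator is defined as 0.
#'
#' @param predicted,observed Character vectors of `"sensitive"` /
#'   `"resistant"` labels (missing entries in either are dropped pairwise).
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `specificity`, `mcc`.
#' @export
classification_metrics <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(observed) < 4) abort("need at least 4 labeled pairs")
  lv <- c("sensitive", "resistant")
  if (!all(predicted %in% lv) || !all(observed %in% lv)) {
    abort("labels must be 'sensitive' or 'resistant'")
  }
  if (length(unique(observed)) < 2) abort("observed labels hold a single class")
  tp <- sum(predicted == "sensitive" & observed == "sensitive")
  fp <- sum(predicted == "sensitive" & observed == "resistant")
  fn <- sum(predicted == "resistant" & observed == "sensitive")
  tn <- sum(predicted == "resistant" & observed == "resistant")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  )
}

#' Drug-unique genes from a selection-frequency table
#'
#' For each gene, its per-drug selection counts are z-scored across drugs
#' (sample sd). The gene is "unique" to the top-ranked drug when that drug's
#' z-score reaches `z_threshold` and the runner-up stays below it. Genes
#' whose counts do not vary across drugs are assigned to no drug.
#'
#' @param selection_counts Long tibble `drug_id`, `gene_id`, `count` (e.g.
#'   the `selection_counts` element of [run_dsg_pipeline()]).
#' @param z_threshold Uniqueness cutoff (default 3).
#' @return A tibble `gene_id`, `drug_id`, `z_top`, `z_second` with one row
#'   per unique gene assignment.
#' @export
drug_unique_genes <- function(selection_counts, z_threshold = 3) {
  stopifnot(all(c("drug_id", "gene_id", "count") %in% names(selection_counts)))
  wide <- tidyr::pivot_wider(
    selection_counts[, c("gene_id", "drug_id", "count")],
    names_from = "drug_id", values_from = "count", values_fill = 0L
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  if (ncol(m) < 3) abort("uniqueness z-scores need at least 3 drugs")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  rows <- list()
  for (i in which(s > 0)) {
    z <- (m[i, ] - mu[i]) / s[i]
    ord <- order(-z, colnames(m))
    if (z[ord[1]] >= z_threshold && z[ord[2]] < z_threshold) {
      rows[[length(rows) + 1]] <- tibble(
        gene_id = rownames(m)[i], drug_id = colnames(m)[ord[1]],
        z_top = unname(z[ord[1]]), z_second = unname(z[ord[2]])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(gene_id = character(0), drug_id = character(0),
                  z_top = numeric(0), z_second = numeric(0)))
  }
  bind_rows(rows) |> arrange(.data$drug_id, .data$gene_id)
}

#' Per-gene contribution to a drug's prediction
#'
#' Leave-one-gene-out on a drug-specific set: the full set is evaluated over
#' the configured permutations, then each gene is removed in turn and the
#' *identical* split plans are rerun, so the performance drop
#' `delta_r = mean_r(full) - mean_r(without gene)` is attributable to the
#' gene alone.
#'
#' @param expr,response Sample tables.
#' @param drug Drug id.
#' @param genes The drug's gene set (at least 2 genes).
#' @param config An [pipeline_config()].
#' @return A tibble `gene_id`, `delta_r`, `mean_r_without`, sorted by
#'   decreasing `delta_r`, with attribute `baseline_r`.
#' @export
gene_contribution <- function(expr, response, drug, genes,
                              config = pipeline_config()) {
  genes <- as_feature_genes(genes)
  if (length(genes) < 2) abort("gene contribution needs a set of at least 2 genes")
  base <- run_fixed_pipeline(expr, response, drug, genes, learner = "enr",
                             config = config, method = "full_set")
  base_r <- glance(base)$mean_r
  rows <- map(genes, function(g) {
    red <- run_fixed_pipeline(expr, response, drug, setdiff(genes, g),
                              learner = "enr", config = config,
                              method = "reduced")
    r <- glance(red)$mean_r
    tibble(gene_id = g, delta_r = base_r - r, mean_r_without = r)
  }) |> bind_rows() |> arrange(desc(.data$delta_r))
  attr(rows, "baseline_r") <- base_r
  rows
}

#' IC50-profile similarity of two drugs
#'
#' Pearson correlation, on complete observations, of the two drugs' ln IC50
#' profiles over the cell-line panel.
#'
#' @param response Response sample table.
#' @param drug_a,drug_b Drug ids.
#' @return A list `r`, `n_effective`.
#' @export
ic50_profile_similarity <- function(response, drug_a, drug_b) {
  stopifnot(drug_a %in% names(response), drug_b %in% names(response))
  pearson_complete(response[[drug_a]], response[[drug_b]], return_n = TRUE)
}

#' Fingerprint similarity (Tanimoto / Tversky)
#'
#' Set similarity of two on-bit sets: Tanimoto `|A n B| / |A u B|`; Tversky
#' `|A n B| / (|A n B| + alpha |A \ B| + beta |B \ A|)`. Two empty sets
#' score 0.
#'
#' @param a,b Integer vectors of on-bit positions.
#' @param mode `"tanimoto"` or `"tversky"`.
#' @param alpha,beta Non-negative Tversky weights (alpha = beta = 1 recovers
#'   Tanimoto).
#' @return Similarity in `[0, 1]`.
#' @export
fingerprint_similarity <- function(a, b, mode = c("tanimoto", "tversky"),
                                   alpha = 1, beta = 1) {
  mode <- match.arg(mode)
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  if (mode == "tanimoto") {
    uni <- length(union(a, b))
    if (uni == 0) return(0)
    inter / uni
  } else {
    if (alpha < 0 || beta < 0) abort("tversky weights must be non-negative")
    den <- inter + alpha * length(setdiff(a, b)) + beta * length(setdiff(b, a))
    if (den == 0) return(0)
    inter / den
  }
}

#' Pairwise drug similarity table
#'
#' @param fingerprints Fingerprint tibble ([read_fingerprints()]).
#' @inheritParams fingerprint_similarity
#' @return A tibble `drug_a`, `drug_b`, `similarity` over all unordered
#'   pairs.
#' @export
fingerprint_similarity_matrix <- function(fingerprints,
                                          mode = c("tanimoto", "tversky"),
                                          alpha = 1, beta = 1) {
  mode <- match.arg(mode)
  n <- nrow(fingerprints)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  tibble(
    drug_a = fingerprints$drug_id[pairs[, 1]],
    drug_b = fingerprints$drug_id[pairs[, 2]],
    similarity = map_dbl(seq_len(nrow(pairs)), function(i) {
      fingerprint_similarity(fingerprints$on_bits[[pairs[i, 1]]],
                             fingerprints$on_bits[[pairs[i, 2]]],
                             mode, alpha, beta)
    })
  )
}

#' Drug-class leave-one-out transfer prediction
#'
#' Predicts a held-out drug's response from the drug-specific gene sets of
#' its classmates. Two transfer readings are supported:
#' `"label_transfer"` (default) trains each classmate's elastic net on the
#' classmate's *own* response — the held-out drug is treated as unscreened
#' and its labels are never used for training — and averages the classmate
#' models' per-cell predictions on the held-out drug's test block;
#' `"feature_transfer"` trains on the held-out drug's own training labels
#' but with each classmate's gene set, averaging the predictions.
#'
#' @param expr,response Sample tables.
#' @param annotation Drug annotation tibble with `drug_id`, `class_label`.
#' @param held_out Drug id to predict.
#' @param config An [pipeline_config()].
#' @param mode `"label_transfer"` or `"feature_transfer"`.
#' @param dsg_sets Optional named list mapping drug id to its gene set;
#'   classmates missing from the list get a full-data [select_dsg()] screen.
#' @return An `inforx_eval` for the held-out drug (method
#'   `class_loo_<mode>`).
#' @export
class_loo_predict <- function(expr, response, annotation, held_out,
                              config = pipeline_config(),
                              mode = c("label_transfer", "feature_transfer"),
                              dsg_sets = NULL) {
  mode <- match.arg(mode)
  stopifnot(held_out %in% annotation$drug_id)
  cls <- annotation$class_label[annotation$drug_id == held_out]
  others <- setdiff(annotation$drug_id[annotation$class_label == cls], held_out)
  if (length(others) == 0) abort(sprintf("no classmate for '%s'", held_out))

  get_set <- function(d) {
    if (!is.null(dsg_sets) && d %in% names(dsg_sets)) {
      return(as_feature_genes(dsg_sets[[d]]))
    }
    screen <- suppressWarnings(
      select_dsg(expr, response, d, fraction = config$extreme_fraction,
                 r_threshold = config$dsg_r_threshold))
    screen$gene_id[screen$selected]
  }
  sets <- setNames(map(others, get_set), others)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) abort("no classmate with a drug-specific gene set")

  cells_ho <- usable_cells(response, held_out)
  y_ho <- setNames(response[[held_out]], response$cell_line)
  outcomes <- map(seq_len(config$n_permutations), function(p) {
    plan <- make_split(cells_ho, "enr", p, config$master_seed, held_out,
                       enr_fractions = config$enr_fractions,
                       svr_train_fraction = config$svr_train_fraction)
    preds <- map(names(sets), function(d) {
      if (mode == "label_transfer") {
        # classmate model on its own labels, scored on the held-out test cells
        cells_d <- setdiff(usable_cells(response, d), plan$test)
        plan_d <- make_split(cells_d, "enr", p, config$master_seed,
                             paste0(d, "_transfer"),
                             enr_fractions = config$enr_fractions)
        out <- fit_predict(expr, response, d, sets[[d]],
                           structure(list(train = plan_d$train,
                                          test = plan$test,
                                          validation = plan_d$validation,
                                          protocol = "enr", permutation = p,
                                          seed = plan_d$seed, drug = d),
                                     class = "inforx_split"),
                           "enr", config)
        unlist(out$predicted)
      } else {
        out <- fit_predict(expr, response, held_out, sets[[d]], plan, "enr",
                           config)
        unlist(out$predicted)
      }
    })
    avg <- rowMeans(do.call(cbind, preds))
    obs <- y_ho[plan$test]
    degenerate <- sd(obs) == 0
    r <- if (degenerate) NA_real_ else if (sd(avg) == 0) 0 else cor(avg, obs)
    tibble(drug_id = held_out, permutation = p, learner = "enr",
           n_features = NA_integer_, r_pred_obs = r,
           mae = mean(abs(avg - obs)), degenerate = degenerate,
           test_cells = list(plan$test), predicted = list(unname(avg)),
           observed = list(unname(obs)))
  }) |> bind_rows()
  new_eval(outcomes, paste0("class_loo_", mode), config)
}

#' Mutation-response association
#'
#' Per gene, compares the drug's ln IC50 between mutated and wild-type cell
#' lines with the Mann-Whitney U test, Benjamini-Hochberg adjusted across
#' the tested gene family. Genes mutated (or wild-type) in fewer than 3
#' responding cells are excluded.
#'
#' @param mutations Binary sample table (`cell_line` column plus one 0/1
#'   column per gene).
#' @param response Response sample table.
#' @param drug Drug id.
#' @param genes Optional gene scope (default: every mutation column).
#' @return A tibble `gene_id`, `n_mutated`, `n_wildtype`, `statistic`,
#'   `p_value`, `p_adjusted`; zero rows (with a warning) when no gene
#'   passes the filter.
#' @export
mutation_association <- function(mutations, response, drug, genes = NULL) {
  ix_assert_sample_table(mutations, "mutation table")
  y <- setNames(response[[drug]], response$cell_line)
  y <- y[!is.na(y)]
  m <- ix_values(mutations)
  common <- intersect(names(y), rownames(m))
  y <- y[common]; m <- m[common, , drop = FALSE]
  genes <- genes %||% colnames(m)
  rows <- list()
  for (g in intersect(genes, colnames(m))) {
    mut <- m[, g] == 1
    if (sum(mut) < 3 || sum(!mut) < 3) next
    ht <- mann_whitney_u(y[mut], y[!mut])
    rows[[g]] <- tibble(gene_id = g, n_mutated = sum(mut),
                        n_wildtype = sum(!mut),
                        statistic = ht$statistic, p_value = ht$p_value)
  }
  if (length(rows) == 0) {
    warn("no gene passes the >= 3 mutated / >= 3 wild-type filter")
    return(tibble(gene_id = character(0), n_mutated = integer(0),
                  n_wildtype = integer(0), statistic = numeric(0),
                  p_value = numeric(0), p_adjusted = numeric(0)))
  }
  out <- bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
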