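# Synthetic pharmacogenomics cohorts with planted ground truth.
#
# The generative model is linear-Gaussian: latent expression is i.i.d.
# standard normal per (cell, gene); each drug's ln IC50 is a weighted sum of
# its k planted causal genes plus Gaussian noise, with a missing mask applied
# afterwards. Within-cell-line z-scoring runs after response generation so
# the response depends on raw expression, mirroring the real flow where
# normalization is a preprocessing artifact. Drugs in the same class share a
# causal core; the rest of each drug's causal set is private.

#' Simulation configuration for synthetic cohorts
#'
#' @param n_cell_lines Number of cell lines (C).
#' @param n_genes Number of latent genes (G) before duplicates.
#' @param n_drugs Number of screened drugs (D).
#' @param causal_per_drug Planted causal genes per drug (k); 0 gives a pure
#'   null drug panel.
#' @param weight_scale Common magnitude of the causal weights.
#' @param weights Optional explicit weight vector of length
#'   `causal_per_drug`, applied to every drug (overrides `weight_scale`);
#'   used e.g. to concentrate signal on one dominant gene.
#' @param noise_sd Standard deviation of the response noise (> 0). See
#'   [calibrate_noise_sd()] to derive it from a target per-causal-gene
#'   correlation.
#' @param missing_response_fraction Bernoulli rate of unscreened
#'   (missing) IC50 entries.
#' @param n_duplicate_genes Exact copies of randomly chosen genes appended
#'   to the matrix (for redundancy-clustering checks).
#' @param n_classes Number of drug classes; drugs are assigned round-robin.
#' @param class_overlap Fraction of the causal set shared within a class
#'   (`ceiling(class_overlap * k)` core genes); 1 makes classmates clones,
#'   0 makes their causal sets disjoint.
#' @param seed Master seed for the cohort; all draws derive from it via
#'   [child_seed()], so adding drugs does not shift earlier draws.
#' @return A list of class `inforx_sim_config`.
#' @export
simulation_config <- function(n_cell_lines = 200,
                              n_genes = 1000,
                              n_drugs = 6,
                              causal_per_drug = 10,
                              weight_scale = 1,
                              weights = NULL,
                              noise_sd = 1,
                              missing_response_fraction = 0.05,
                              n_duplicate_genes = 0,
                              n_classes = 2,
                              class_overlap = 0.5,
                              seed = 1L) {
  stopifnot(
    n_cell_lines >= 4, n_genes >= 2, n_drugs >= 1,
    causal_per_drug >= 0, causal_per_drug < n_genes,
    noise_sd > 0,
    missing_response_fraction >= 0, missing_response_fraction < 1,
    n_duplicate_genes >= 0,
    n_classes >= 1, n_classes <= n_drugs,
    class_overlap >= 0, class_overlap <= 1
  )
  if (!is.null(weights)) {
    stopifnot(length(weights) == causal_per_drug, all(is.finite(weights)))
    if (causal_per_drug > 0 && all(weights == 0)) abort("weights must not all be zero")
  }
  structure(
    list(n_cell_lines = as.integer(n_cell_lines), n_genes = as.integer(n_genes),
         n_drugs = as.integer(n_drugs), causal_per_drug = as.integer(causal_per_drug),
         weight_scale = weight_scale, weights = weights, noise_sd = noise_sd,
         missing_response_fraction = missing_response_fraction,
         n_duplicate_genes = as.integer(n_duplicate_genes),
         n_classes = as.integer(n_classes), class_overlap = class_overlap,
         seed = as.integer(seed)),
    class = "inforx_sim_config"
  )
}

#' Noise level for a target per-causal-gene correlation
#'
#' Under the linear-Gaussian model with k independent causal genes of equal
#' weight w, the population correlation of each causal gene with the response
#' is `rho = w / sqrt(k w^2 + sigma^2)`. Solving for sigma gives
#' `sigma = w * sqrt(1 / rho^2 - k)`, which exists only for
#' `rho <= 1 / sqrt(k)`: the squared per-gene correlations of independent
#' causal genes can sum to at most 1. For an infeasible target the function
#' warns, reports the attainable maximum, and returns a small positive floor
#' (the closest admissible regime, effectively noiseless).
#'
#' @param k Number of causal genes.
#' @param rho Target per-causal-gene population correlation (0 < rho < 1).
#' @param weight_scale Causal weight magnitude w.
#' @return The noise standard deviation.
#' @export
#' @examples
#' calibrate_noise_sd(k = 5, rho = 0.3)
calibrate_noise_sd <- function(k, rho, weight_scale = 1) {
  stopifnot(k >= 1, rho > 0, rho < 1, weight_scale > 0)
  rho_max <- 1 / sqrt(k)
  if (rho >= rho_max) {
    warn(sprintf(paste0("target per-gene correlation %.3f is unattainable with ",
                        "k = %d independent causal genes (maximum %.3f); ",
                        "returning the near-noiseless floor"), rho, k, rho_max))
    return(weight_scale * 1e-3)
  }
  weight_scale * sqrt(1 / rho^2 - k)
}

ix_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate a synthetic pharmacogenomics cohort
#'
#' Draws the latent expression matrix, appends duplicate genes, plants each
#' drug's causal set (with the within-class shared core), generates noisy
#' linear ln IC50 responses, applies the missing mask, and finally z-scores
#' expression within each cell line. Fully reproducible from `cfg$seed`.
#'
#' @param cfg An [simulation_config()] object.
#' @return A list of class `inforx_cohort` with elements `expression`
#'   (z-scored sample table), `response` (sample table of ln IC50 with
#'   `NA` for unscreened pairs), `annotation` (drug annotation tibble with
#'   targets and class labels), `truth` (tibble `drug_id`, `causal_genes`,
#'   `weights`, `noise_sd`, `class_label`), and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "inforx_sim_config"))
  C <- cfg$n_cell_lines; G <- cfg$n_genes; D <- cfg$n_drugs
  k <- cfg$causal_per_drug
  cells <- ix_ids("c", C)
  genes <- ix_ids("g", G)
  drugs <- sprintf("drug_%02d", seq_len(D))
  classes <- sprintf("class_%02d", ((seq_len(D) - 1L) %% cfg$n_classes) + 1L)

  x <- with_seed(child_seed(cfg$seed, "expression"),
                 matrix(rnorm(C * G), nrow = C, dimnames = list(cells, genes)))

  if (cfg$n_duplicate_genes > 0) {
    src <- with_seed(child_seed(cfg$seed, "duplicates"),
                     sample(genes, cfg$n_duplicate_genes, replace = TRUE))
    dup <- x[, src, drop = FALSE]
    colnames(dup) <- sprintf("%s_dup%02d", src, seq_along(src))
    x <- cbind(x, dup)
  }

  # Causal assignment: one shared core per class, private remainder per drug,
  # all sampled without replacement from the original gene universe so the
  # planted sets of distinct drugs never collide by accident.
  n_core <- if (k > 0) as.integer(ceiling(cfg$class_overlap * k)) else 0L
  n_core <- min(n_core, k)
  pool <- genes
  core_by_class <- list()
  for (cl in unique(classes)) {
    core <- if (n_core > 0) {
      picked <- with_seed(child_seed(cfg$seed, "core", cl), sample(pool, n_core))
      pool <- setdiff(pool, picked)
      picked
    } else character(0)
    core_by_class[[cl]] <- core
  }
  weights <- if (!is.null(cfg$weights)) cfg$weights else rep(cfg$weight_scale, k)

  truth <- vector("list", D)
  resp <- matrix(NA_real_, nrow = C, ncol = D, dimnames = list(cells, drugs))
  for (i in seq_len(D)) {
    n_priv <- k - n_core
    priv <- if (n_priv > 0) {
      picked <- with_seed(child_seed(cfg$seed, "private", drugs[i]),
                          sample(pool, n_priv))
      pool <- setdiff(pool, picked)
      picked
    } else character(0)
    causal <- c(core_by_class[[classes[i]]], priv)
    y <- if (k > 0) drop(x[, causal, drop = FALSE] %*% weights) else rep(0, C)
    y <- y + with_seed(child_seed(cfg$seed, "noise", drugs[i]),
                       rnorm(C, 0, cfg$noise_sd))
    if (cfg$missing_response_fraction > 0) {
      miss <- with_seed(child_seed(cfg$seed, "missing", drugs[i]),
                        runif(C) < cfg$missing_response_fraction)
      y[miss] <- NA_real_
    }
    resp[, i] <- y
    truth[[i]] <- tibble(drug_id = drugs[i], causal_genes = list(causal),
                         weights = list(weights[seq_len(k)]),
                         noise_sd = cfg$noise_sd, class_label = classes[i])
  }
  truth <- bind_rows(truth)

  annotation <- tibble(
    drug_id = drugs,
    targets = map(truth$causal_genes, function(g) utils::head(g, 1)),
    class_label = classes,
    fingerprint_id = drugs
  )

  structure(
    list(expression = zscore_cell_lines(ix_table(x, normalized = FALSE)),
         response = ix_table(resp),
         annotation = annotation,
         truth = truth,
         config = cfg),
    class = "inforx_cohort"
  )
}

#' @export
print.inforx_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<inforx synthetic cohort> %d cell lines x %d genes, %d drugs (%d classes)\n",
              cfg$n_cell_lines, ncol(x$expression) - 1L, cfg$n_drugs, cfg$n_classes))
  cat(sprintf("  %d causal genes/drug, noise sd %.3g, %.0f%% responses missing, seed %d\n",
              cfg$causal_per_drug, cfg$noise_sd,
              100 * cfg$missing_response_fraction, cfg$seed))
  invisible(x)
}

#' Generate network, pathway and fingerprint fixtures for a cohort
#'
#' Builds the context inputs the target-neighborhood and similarity stages
#' consume, wired to the cohort's ground truth: each drug's nominal target is
#' connected, at controlled depths, to a mix of its causal and of unrelated
#' genes with interaction scores straddling the 0.9 floor; each target sits
#' in a pathway holding a configurable fraction of the drug's causal genes
#' plus decoys; fingerprints share a per-class bit core so within-class
#' similarity exceeds between-class similarity.
#'
#' @param cohort An [generate_cohort()] result.
#' @param causal_fraction Fraction of each drug's causal genes placed in its
#'   target's pathway.
#' @param n_decoy_genes Unrelated genes added per pathway and per
#'   neighborhood depth.
#' @return A list `network` (edge tibble), `pathways` (GMT-style tibble),
#'   `fingerprints` (bitset tibble).
#' @export
generate_context_fixtures <- function(cohort, causal_fraction = 0.5,
                                      n_decoy_genes = 2) {
  stopifnot(inherits(cohort, "inforx_cohort"))
  cfg <- cohort$config
  truth <- cohort$truth
  genes <- setdiff(names(cohort$expression), "cell_line")
  seed <- child_seed(cfg$seed, "context")

  edges <- list(); pws <- list(); fps <- list()
  class_ids <- unique(truth$class_label)
  with_seed(seed, {
    for (i in seq_len(nrow(truth))) {
      d <- truth$drug_id[i]
      causal <- truth$causal_genes[[i]]
      if (length(causal) == 0) next
      target <- causal[1]
      others <- setdiff(causal, target)
      noncausal <- sample(setdiff(genes, causal), 3 * n_decoy_genes + 3)
      # depth 1: causal + decoys above the floor, one edge just below it
      d1 <- c(utils::head(others, 2), noncausal[seq_len(n_decoy_genes)])
      e <- tibble(gene_a = target, gene_b = d1, score = 0.95)
      e <- bind_rows(e, tibble(gene_a = target, gene_b = noncausal[n_decoy_genes + 1],
                               score = 0.85))
      # depth 2 and 3 chains hanging off the first depth-1 neighbor
      if (length(d1) > 0) {
        hop2 <- c(utils::head(others[-(1:2)], 1), noncausal[n_decoy_genes + 2])
        hop2 <- hop2[!is.na(hop2)]
        e <- bind_rows(e, tibble(gene_a = d1[1], gene_b = hop2, score = 0.95))
        if (length(hop2) > 0) {
          hop3 <- noncausal[n_decoy_genes + 3]
          e <- bind_rows(e, tibble(gene_a = hop2[1], gene_b = hop3, score = 0.92))
        }
      }
      edges[[d]] <- e
      n_in <- max(1L, as.integer(round(causal_fraction * length(causal))))
      pw_genes <- unique(c(target, utils::head(causal, n_in),
                           noncausal[2 * n_decoy_genes + 1 + seq_len(n_decoy_genes)]))
      pws[[d]] <- tibble(pathway_id = paste0("pw_", d),
                         pathway_name = paste0("response pathway of ", d),
                         genes = list(pw_genes))
    }
    for (i in seq_len(nrow(truth))) {
      cl_idx <- match(truth$class_label[i], class_ids)
      core_bits <- (cl_idx - 1L) * 100L + 0:29
      priv_bits <- (cl_idx - 1L) * 100L + 30L + sample(0:69, 10)
      fps[[truth$drug_id[i]]] <- tibble(drug_id = truth$drug_id[i],
                                        on_bits = list(sort(unique(c(core_bits, priv_bits)))))
    }
  })
  list(network = as_interaction_network(bind_rows(edges)),
       pathways = bind_rows(pws),
       fingerprints = bind_rows(fps))
}
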