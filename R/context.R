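# Gene sets around known drug targets: interactome neighborhoods (P1/P2/P3),
# pathway memberships (F1/F2), and size-matched random controls.
#
# Gene-set tables share one shape across the package: one row per set with
# columns label, provenance, drug_id and a `genes` list-column.

gene_set_row <- function(label, provenance, genes, drug_id = NA_character_,
                         degenerate = FALSE) {
  tibble(label = label, provenance = provenance, drug_id = drug_id,
         genes = list(unique(genes)), n_genes = length(unique(genes)),
         degenerate = degenerate)
}

#' Interactome neighborhood of a drug's targets
#'
#' Breadth-first expansion from all targets jointly over edges whose score is
#' strictly above `score_floor`, collecting every gene at shortest-path
#' distance at most `degree`. The targets themselves are included (drop them
#' with `include_targets = FALSE`).
#'
#' @param network Interaction edge tibble ([read_network()] /
#'   [as_interaction_network()]).
#' @param targets Character vector of target gene ids.
#' @param degree Neighborhood depth, 1, 2 or 3 (provenance P1/P2/P3).
#' @param score_floor Strict lower bound on edge scores (default 0.9).
#' @param drug_id Optional owning drug recorded in the output.
#' @param include_targets Keep the targets in the set (default `TRUE`).
#' @return A one-row gene-set tibble; when no target appears in the filtered
#'   network the set is empty and flagged `degenerate` with a warning.
#' @export
neighborhood_set <- function(network, targets, degree, score_floor = 0.9,
                             drug_id = NA_character_, include_targets = TRUE) {
  stopifnot(length(targets) > 0, degree %in% 1:3)
  prov <- paste0("P", degree)
  kept <- network[network$score > score_floor, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  seeds <- intersect(targets, igraph::V(g)$name)
  if (length(seeds) == 0) {
    warn(sprintf("no target of %s present in the score-filtered network",
                 drug_id %||% "drug"))
    return(gene_set_row(paste0(prov, "_", drug_id), prov, character(0), drug_id,
                        degenerate = TRUE))
  }
  dmat <- igraph::distances(g, v = seeds)
  reach <- colnames(dmat)[apply(dmat, 2, min) <= degree]
  genes <- union(targets, reach)
  if (!include_targets) genes <- setdiff(genes, targets)
  gene_set_row(paste0(prov, "_", drug_id), prov, genes, drug_id)
}

#' Pathway gene sets containing a drug's targets
#'
#' F1 mode returns one gene set per pathway that contains any target; F2
#' returns their union as a single merged set.
#'
#' @param pathways Pathway catalog tibble ([read_gmt()]).
#' @param targets Character vector of target gene ids.
#' @param mode `"F1"` or `"F2"`.
#' @param drug_id Optional owning drug.
#' @return A gene-set tibble: zero or more rows for F1 (empty when no pathway
#'   contains a target), exactly one row for F2 (flagged degenerate when
#'   empty).
#' @export
pathway_sets <- function(pathways, targets, mode = c("F1", "F2"),
                         drug_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(targets) > 0)
  hit <- map_lgl(pathways$genes, function(g) any(targets %in% g))
  hits <- pathways[hit, , drop = FALSE]
  if (mode == "F1") {
    if (nrow(hits) == 0) return(gene_set_row(character(0), character(0),
                                             character(0))[0, ])
    bind_rows(map(seq_len(nrow(hits)), function(i) {
      gene_set_row(paste0("F1_", hits$pathway_id[i]), "F1",
                   hits$genes[[i]], drug_id)
    }))
  } else {
    merged <- unique(unlist(hits$genes))
    gene_set_row(paste0("F2_", drug_id), "F2", merged, drug_id,
                 degenerate = length(merged) == 0)
  }
}

#' Size-matched random control gene set
#'
#' Uniform sample without replacement from the gene universe, reproducible
#' from `seed`; the control arm for the target-context comparisons.
#'
#' @param universe Character vector of candidate gene ids.
#' @param size Number of genes to draw (1 to `length(universe)`).
#' @param seed Integer seed.
#' @param drug_id Optional owning drug.
#' @return A one-row gene-set tibble with provenance `RANDOM`.
#' @export
random_control_set <- function(universe, size, seed, drug_id = NA_character_) {
  if (size < 1) abort("a gene set must be non-empty")
  if (size > length(universe)) abort("size exceeds the gene universe")
  genes <- with_seed(seed, sample(universe, size))
  gene_set_row(paste0("RANDOM_", size), "RANDOM", genes, drug_id)
}
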