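# The two informative-gene selection procedures.
#
# Drug-Unspecific Genes (DUG): rank genes by expression variance over the
# training cell lines, keep the top n, then collapse redundancy: genes whose
# expression profiles correlate at |r| >= 0.8 are clustered (single-linkage
# connected components) and each cluster is represented by its
# highest-variance member. One set serves every drug.
#
# Drug-Specific Genes (DSG): per drug and per training split, sort the cells
# by each gene's expression, keep the top and bottom 10%, and correlate the
# gene's expression with ln IC50 on those extreme cells only; genes with
# |r| >= 0.4 (inclusive) are selected. The screen runs inside each training
# block, never on held-out cells.

#' Rank genes by expression variance
#'
#' Per-gene sample variance over the chosen cell lines, in decreasing order;
#' ties broken by gene id so the ranking is order-independent.
#'
#' @param expr Expression sample table.
#' @param cell_lines Optional character vector restricting the cells used
#'   (e.g. a training block); default all.
#' @return A tibble `gene_id`, `variance`, `rank`.
#' @export
rank_by_variance <- function(expr, cell_lines = NULL) {
  ix_assert_sample_table(expr, "expression table")
  m <- ix_values(expr)
  if (!is.null(cell_lines)) {
    missing_cells <- setdiff(cell_lines, rownames(m))
    if (length(missing_cells) > 0) {
      abort(sprintf("unknown cell line '%s'", missing_cells[1]))
    }
    m <- m[cell_lines, , drop = FALSE]
  }
  if (nrow(m) < 3) abort("need at least 3 cell lines to rank variances")
  v <- col_vars(m)
  ord <- order(-v, colnames(m))
  tibble(gene_id = colnames(m)[ord], variance = unname(v[ord]),
         rank = seq_along(v))
}

#' Select the drug-unspecific gene set
#'
#' Top `top_n` genes by training variance, then redundancy clustering: build
#' a graph on the candidates with an edge wherever the absolute (or signed)
#' Pearson correlation of the two expression profiles reaches
#' `redundancy_r`, and keep the highest-variance gene of each connected
#' component.
#'
#' @inheritParams rank_by_variance
#' @param top_n Number of top-variance candidates (capped at the gene
#'   count).
#' @param redundancy_r Correlation threshold for a redundancy edge
#'   (inclusive).
#' @param signed Use signed correlation `r >= redundancy_r` instead of
#'   `|r| >= redundancy_r` for redundancy edges.
#' @return A tibble `gene_id`, `variance`, `component` (cluster id of each
#'   retained representative), ordered by decreasing variance, with
#'   attributes `provenance = "DUG"` and `n_candidates`.
#' @export
select_dug <- function(expr, cell_lines = NULL, top_n = 5000,
                       redundancy_r = 0.8, signed = FALSE) {
  if (top_n <= 0) abort("top_n must be positive")
  ranking <- rank_by_variance(expr, cell_lines)
  top_n <- min(top_n, nrow(ranking))
  cand <- ranking$gene_id[seq_len(top_n)]
  m <- ix_values(expr)
  if (!is.null(cell_lines)) m <- m[cell_lines, , drop = FALSE]
  m <- m[, cand, drop = FALSE]
  cm <- suppressWarnings(cor(m))
  cm[!is.finite(cm)] <- 0
  val <- if (signed) cm else abs(cm)
  adj <- val >= redundancy_r
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  vars <- setNames(ranking$variance[seq_len(top_n)], cand)
  keep <- vapply(split(names(comp), comp), function(members) {
    members[order(-vars[members], members)][1]
  }, character(1))
  out <- ranking[ranking$gene_id %in% keep, c("gene_id", "variance")]
  out$component <- unname(comp[out$gene_id])
  attr(out, "provenance") <- "DUG"
  attr(out, "n_candidates") <- top_n
  out
}

#' Extreme-expression cell subset for one gene
#'
#' Sorts the cells by the gene's expression and returns the bottom and top
#' `fraction` of them, `k = max(2, floor(fraction * n))` per tail, with ties
#' broken by cell-line id so the subset is deterministic.
#'
#' @param gene_values Named numeric vector: expression of one gene over the
#'   training cells (names are cell-line ids).
#' @param fraction Tail fraction (default 0.10).
#' @return Character vector of `2k` cell-line ids (bottom tail then top
#'   tail).
#' @export
dsg_extreme_cells <- function(gene_values, fraction = 0.10) {
  n <- length(gene_values)
  if (n < 20) abort("insufficient cell lines for extreme-decile screening (need >= 20)")
  if (is.null(names(gene_values))) abort("gene_values must be named by cell line")
  k <- max(2L, as.integer(floor(fraction * n)))
  ord <- order(gene_values, names(gene_values))
  ids <- names(gene_values)[ord]
  c(utils::head(ids, k), utils::tail(ids, k))
}

#' Screen drug-specific genes by extreme-decile correlation
#'
#' For each gene, restrict to the cells with the highest and lowest
#' expression of that gene (among `cells`, which must already exclude cells
#' with missing response for the drug, the default) and correlate its
#' expression with ln IC50 there. Genes reaching `|r| >= r_threshold`
#' (inclusive) are selected. Genes whose extreme-subset expression or
#' response is constant are skipped.
#'
#' @param expr Expression sample table.
#' @param response Response sample table.
#' @param drug Drug id (a column of `response`).
#' @param cells Optional training cell-line ids; defaults to every cell with
#'   a non-missing response for the drug. Cells with missing response are
#'   always excluded first.
#' @param fraction Tail fraction per side (default 0.10).
#' @param r_threshold Inclusive absolute-correlation selection threshold
#'   (default 0.4).
#' @return A tibble `gene_id`, `r`, `selected` with attributes `drug_id`,
#'   `n_extreme` (subset size) and `n_training`. Selected genes carry
#'   provenance DSG for the drug.
#' @export
select_dsg <- function(expr, response, drug, cells = NULL,
                       fraction = 0.10, r_threshold = 0.4) {
  ix_assert_sample_table(expr, "expression table")
  ix_assert_sample_table(response, "response table")
  if (!drug %in% names(response)) abort(sprintf("unknown drug '%s'", drug))
  y_all <- setNames(response[[drug]], response$cell_line)
  usable <- names(y_all)[!is.na(y_all)]
  cells <- if (is.null(cells)) usable else intersect(cells, usable)
  n <- length(cells)
  if (n < 20) abort("insufficient cell lines for extreme-decile screening (need >= 20)")
  m <- ix_values(expr)[cells, , drop = FALSE]
  y <- y_all[cells]
  k <- max(2L, as.integer(floor(fraction * n)))

  # Vectorized screen: per gene, order cells by expression (ties by id),
  # take both tails, correlate expression with response on those cells.
  id_rank <- rank(cells) # lexicographic tiebreak via secondary key
  r <- vapply(seq_len(ncol(m)), function(j) {
    ord <- order(m[, j], id_rank)
    idx <- c(utils::head(ord, k), utils::tail(ord, k))
    xe <- m[idx, j]; ye <- y[idx]
    if (sd(xe) == 0 || sd(ye) == 0) return(NA_real_)
    cor(xe, ye)
  }, numeric(1))

  out <- tibble(gene_id = colnames(m), r = r,
                selected = !is.na(r) & abs(r) >= r_threshold)
  attr(out, "drug_id") <- drug
  attr(out, "n_extreme") <- 2L * k
  attr(out, "n_training") <- n
  if (!any(out$selected)) {
    warn(sprintf("no drug-specific gene found for '%s'", drug))
  }
  out
}

#' Selected genes of a DSG screen as a gene-set row
#'
#' @param screen A [select_dsg()] result.
#' @return A one-row gene-set tibble (provenance DSG), flagged degenerate
#'   when the screen selected nothing.
#' @export
dsg_gene_set <- function(screen) {
  drug <- attr(screen, "drug_id")
  genes <- screen$gene_id[screen$selected]
  gene_set_row(paste0("DSG_", drug), "DSG", genes, drug,
               degenerate = length(genes) == 0)
}
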