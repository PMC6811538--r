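# Readers and writers for the package's plain-text interchange formats:
# TSV matrices (cell lines x genes / drugs), 3-column interaction edge lists,
# GMT pathway catalogs, fingerprint bitset tables and drug annotations.

read_tsv_matrix <- function(path, transpose = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) abort("matrix TSV needs a row-id column plus at least one data column")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate row id: '%s'", ids[duplicated(ids)][1]))
  }
  cols <- names(raw)[-1]
  if (anyDuplicated(cols)) {
    abort(sprintf("duplicate column id: '%s'", cols[duplicated(cols)][1]))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  missing_mask <- cells == "" | toupper(cells) == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                  cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], cols[bad[1, 2]]))
  }
  num[missing_mask] <- NA_real_
  dimnames(num) <- list(ids, cols)
  if (transpose) num <- t(num)
  num
}

#' Read a cell-line by gene expression matrix from TSV
#'
#' The file carries one header row of gene ids and a first column of cell-line
#' ids; values are tab-separated numbers. Expression files must be complete:
#' empty cells or `NA` are rejected.
#'
#' @param path Path to a TSV file.
#' @param transpose Set `TRUE` when the file stores genes as rows.
#' @return A tibble with a `cell_line` column followed by one numeric column
#'   per gene; attribute `normalized` is `FALSE`.
#' @export
read_expression <- function(path, transpose = FALSE) {
  m <- read_tsv_matrix(path, transpose)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing expression value at cell line '%s', gene '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  ix_table(m, normalized = FALSE)
}

#' Read a cell-line by drug ln(IC50) response matrix from TSV
#'
#' Same layout as [read_expression()]; empty cells or `NA` (case-insensitive)
#' mark unscreened cell-line/drug pairs and are preserved as `NA`.
#'
#' @inheritParams read_expression
#' @return A tibble with a `cell_line` column followed by one numeric column
#'   per drug, `NA` where the response is missing.
#' @export
read_response <- function(path, transpose = FALSE) {
  ix_table(read_tsv_matrix(path, transpose))
}

#' Write a sample table back to TSV
#'
#' Inverse of [read_expression()] / [read_response()]: numbers are written
#' with six significant digits, missing entries as `NA`.
#'
#' @param tbl A sample table (leading `cell_line` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(tbl, path) {
  ix_assert_sample_table(tbl)
  m <- ix_values(tbl)
  out <- cbind(cell_line = rownames(m),
               as.data.frame(apply(m, 2, function(x) {
                 ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
               }, simplify = FALSE)))
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Read a scored protein-protein interaction edge list
#'
#' Expects a 3-column TSV `gene_a`, `gene_b`, `score` (header optional,
#' detected). Self-loops are dropped (with a message of the count) and
#' duplicate undirected edges collapsed keeping the maximum score.
#'
#' @param path Path to the edge-list TSV.
#' @return A tibble `gene_a`, `gene_b`, `score` with `gene_a < gene_b`,
#'   scores in `[0, 1]`, one row per undirected edge.
#' @export
read_network <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  raw <- readr::read_tsv(path, col_names = c("gene_a", "gene_b", "score"),
                         skip = as.integer(has_header),
                         col_types = "ccd", progress = FALSE)
  as_interaction_network(raw)
}

#' Coerce an edge data frame to the canonical interaction-network form
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score`.
#' @return A tibble as described in [read_network()].
#' @export
as_interaction_network <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  if (any(!is.finite(edges$score)) || any(edges$score < 0 | edges$score > 1)) {
    abort("interaction scores must lie in [0, 1]")
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  lo <- pmin(edges$gene_a, edges$gene_b)
  hi <- pmax(edges$gene_a, edges$gene_b)
  tibble(gene_a = lo, gene_b = hi, score = edges$score) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(score = max(.data$score), .groups = "drop")
}

#' Read a pathway catalog in GMT format
#'
#' Standard GMT: one pathway per line, `id<TAB>description<TAB>gene1<TAB>...`.
#' A line with no gene is an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble `pathway_id`, `pathway_name`, `genes` (list-column of
#'   unique gene-id character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d ('%s') has no gene", short[1],
                  parts[[short[1]]][1]))
  }
  ids <- map_chr(parts, 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate pathway id: '%s'", ids[duplicated(ids)][1]))
  }
  tibble(
    pathway_id = ids,
    pathway_name = map_chr(parts, 2),
    genes = map(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Read drug fingerprints as bit-position sets
#'
#' Format: `drug_id<TAB>comma-separated on-bit positions` (non-negative
#' integers), one drug per line.
#'
#' @param path Path to the fingerprint TSV.
#' @return A tibble `drug_id`, `on_bits` (list-column of sorted unique
#'   integer vectors).
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- map_chr(parts, 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate fingerprint drug id: '%s'", ids[duplicated(ids)][1]))
  }
  bits <- map(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) return(integer(0))
    b <- suppressWarnings(as.integer(strsplit(p[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(b) || any(b < 0)) abort(sprintf("invalid bit positions for '%s'", p[1]))
    sort(unique(b))
  })
  tibble(drug_id = ids, on_bits = bits)
}

#' Read a drug annotation table
#'
#' TSV with header `drug_id`, `targets` (comma-separated gene ids, may be
#' empty), `class_label`, and optionally `fingerprint_id`.
#'
#' @param path Path to the annotation TSV.
#' @param classes Optional character vector: the allowed class vocabulary;
#'   when supplied, unknown labels are an error.
#' @return A tibble `drug_id`, `targets` (list-column), `class_label`,
#'   `fingerprint_id`.
#' @export
read_drug_annotation <- function(path, classes = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("drug_id", "targets", "class_label") %in% names(raw)))
  if (anyDuplicated(raw$drug_id)) {
    abort(sprintf("duplicate drug id: '%s'", raw$drug_id[duplicated(raw$drug_id)][1]))
  }
  if (!is.null(classes)) {
    bad <- setdiff(unique(raw$class_label), classes)
    if (length(bad) > 0) abort(sprintf("unknown drug class: '%s'", bad[1]))
  }
  tibble(
    drug_id = raw$drug_id,
    targets = map(raw$targets, function(t) {
      if (is.na(t) || !nzchar(t)) character(0) else strsplit(t, ",", fixed = TRUE)[[1]]
    }),
    class_label = raw$class_label,
    fingerprint_id = if ("fingerprint_id" %in% names(raw)) raw$fingerprint_id else NA_character_
  )
}
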