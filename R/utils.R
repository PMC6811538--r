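# Internal helpers shared across modules.

# Tabular convention used throughout: a "sample table" is a tibble whose first
# column is `cell_line` (character, unique) and whose remaining columns are
# numeric measurements (genes for expression, drugs for response). Internally
# computations run on the matrix view.

#' Extract the numeric matrix view of a sample table
#'
#' @param tbl A tibble whose first column is `cell_line` and whose remaining
#'   columns are numeric.
#' @return A numeric matrix with cell-line row names.
#' @keywords internal
#' @noRd
ix_values <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "cell_line")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("all measurement columns must be numeric")
  rownames(m) <- tbl$cell_line
  m
}

# Rebuild a sample table from a matrix, preserving extra attributes.
ix_table <- function(m, normalized = NULL) {
  out <- tibble(cell_line = rownames(m))
  out <- dplyr::bind_cols(out, as_tibble(m))
  if (!is.null(normalized)) attr(out, "normalized") <- normalized
  out
}

ix_assert_sample_table <- function(tbl, what = "matrix table") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2 || names(tbl)[1] != "cell_line") {
    abort(sprintf("%s must be a data frame with a leading `cell_line` column", what))
  }
  if (anyDuplicated(tbl$cell_line)) {
    dup <- tbl$cell_line[duplicated(tbl$cell_line)][1]
    abort(sprintf("duplicate cell line id: '%s'", dup))
  }
  if (anyDuplicated(names(tbl))) {
    dup <- names(tbl)[duplicated(names(tbl))][1]
    abort(sprintf("duplicate column id: '%s'", dup))
  }
  invisible(tbl)
}

#' Derive a child seed from a master seed and a context label
#'
#' Counter-based derivation: the child is a deterministic arithmetic hash of
#' the master seed and the context strings, so adding drugs or stages never
#' shifts the stream of an existing one.
#'
#' @param master Integer master seed.
#' @param ... Context labels (stage name, drug id, permutation index, ...);
#'   coerced to character.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, "split", "drug_01", 3)
child_seed <- function(master, ...) {
  parts <- vapply(list(...), function(x) paste0(as.character(x), collapse = ","),
                  character(1))
  key <- paste(c(as.character(as.integer(master)), parts), collapse = "|")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Run an expression under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sample variance along columns of a matrix (n - 1 denominator).
col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2) abort("need at least 2 rows to compute a sample variance")
  ctr <- sweep(m, 2, colMeans(m))
  colSums(ctr^2) / (n - 1)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
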