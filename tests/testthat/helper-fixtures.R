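# Shared fixture builders. Everything is generated in code at test time.

# A small planted cohort reused by several modeling tests.
tiny_cohort <- function(seed = 11, C = 80, G = 120, D = 4, k = 5,
                        noise_sd = 1, overlap = 0.5, n_classes = 2,
                        missing = 0.05, dup = 0, weights = NULL) {
  generate_cohort(simulation_config(
    n_cell_lines = C, n_genes = G, n_drugs = D, causal_per_drug = k,
    noise_sd = noise_sd, missing_response_fraction = missing,
    n_duplicate_genes = dup, n_classes = n_classes, class_overlap = overlap,
    weights = weights, seed = seed
  ))
}

# Sample table from a bare matrix.
as_sample_table <- function(m, normalized = NULL) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  tbl <- tibble::as_tibble(as.data.frame(m), rownames = NA)
  out <- tibble::tibble(cell_line = rownames(m))
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(m)))
  if (!is.null(normalized)) attr(out, "normalized") <- normalized
  out
}

random_sample_table <- function(n, p, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("%s%03d", prefix, 1:p)))
  as_sample_table(m, normalized = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent oracle: Pearson correlation by the direct sum-of-products
# formula on centered vectors.
oracle_pearson <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# Independent oracle: exact two-sided Mann-Whitney p by full enumeration of
# group assignments (no ties assumed).
oracle_mw_exact <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n_a * (n_a + 1) / 2
  }
  u_obs <- u_stat(seq_len(n_a))
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, u_stat)
  mu <- n_a * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Independent oracle: Benjamini-Hochberg by the sorted step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    cummin_rev <- min(cummin_rev, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, cummin_rev)
  }
  adj
}

# Independent oracle: genes within `degree` of any target by exhaustive
# shortest-path filtering (igraph-free: Floyd-Warshall on a small graph).
oracle_neighborhood <- function(edges, targets, degree, floor) {
  keep <- edges[edges$score > floor, , drop = FALSE]
  nodes <- sort(unique(c(keep$gene_a, keep$gene_b, targets)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(keep))) {
    a <- keep$gene_a[i]; b <- keep$gene_b[i]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in nodes) for (i in nodes) for (j in nodes) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  present <- intersect(targets, nodes)
  if (length(present) == 0) return(character(0))
  reach <- nodes[apply(d[present, , drop = FALSE], 2, min) <= degree]
  sort(union(targets, reach))
}

# Independent oracle for the drug-specific screen: per gene, sort cells,
# slice both tails, correlate.
oracle_dsg <- function(expr_m, y, fraction, r_threshold) {
  cells <- rownames(expr_m)[!is.na(y[rownames(expr_m)])]
  m <- expr_m[cells, , drop = FALSE]
  yy <- y[cells]
  k <- max(2, floor(fraction * length(cells)))
  res <- sapply(colnames(m), function(g) {
    ord <- order(m[, g], rank(cells))
    idx <- c(head(ord, k), tail(ord, k))
    if (sd(m[idx, g]) == 0 || sd(yy[idx]) == 0) return(NA_real_)
    cor(m[idx, g], yy[idx])
  })
  names(res)[!is.na(res) & abs(res) >= r_threshold]
}
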