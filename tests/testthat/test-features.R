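test_that("variance ranking is descending with deterministic ties", {
  m <- cbind(g1 = c(1, 1.1, 0.9, 1), g2 = c(0, 5, -5, 2), g3 = c(0, 2, -2, 1))
  rownames(m) <- sprintf("c%d", 1:4)
  rk <- rank_by_variance(as_sample_table(m))
  expect_equal(rk$gene_id, c("g2", "g3", "g1"))
  expect_equal(rk$variance, unname(apply(m, 2, var))[c(2, 3, 1)])
  # duplicated columns tie and sort by gene id
  m2 <- cbind(b_copy = m[, "g2"], a_copy = m[, "g2"], low = m[, "g1"])
  rk2 <- rank_by_variance(as_sample_table(m2))
  expect_equal(rk2$gene_id[1:2], c("a_copy", "b_copy"))
})

test_that("redundancy clustering collapses duplicate triplets to one representative", {
  set.seed(5)
  m <- matrix(rnorm(30 * 7), 30, dimnames = list(sprintf("c%02d", 1:30),
                                                 sprintf("g%02d", 1:7)))
  m <- cbind(m, g08 = m[, "g01"], g09 = m[, "g01"], g10 = m[, "g02"])
  dug <- select_dug(as_sample_table(m), top_n = 10, redundancy_r = 0.8)
  # 10 candidates, {g01,g08,g09} and {g02,g10} collapse -> 7 representatives
  expect_equal(nrow(dug), 7)
  expect_equal(sum(c("g01", "g08", "g09") %in% dug$gene_id), 1)
  expect_equal(sum(c("g02", "g10") %in% dug$gene_id), 1)
})

test_that("the retained set is independent of gene order", {
  set.seed(6)
  m <- matrix(rnorm(25 * 8), 25, dimnames = list(sprintf("c%02d", 1:25),
                                                 sprintf("g%02d", 1:8)))
  m <- cbind(m, g09 = m[, "g03"])
  tbl <- as_sample_table(m)
  perm <- tbl[, c("cell_line", sample(setdiff(names(tbl), "cell_line")))]
  a <- select_dug(tbl, top_n = 9, redundancy_r = 0.8)
  b <- select_dug(perm, top_n = 9, redundancy_r = 0.8)
  expect_setequal(a$gene_id, b$gene_id)
})

test_that("without correlated genes the whole top-n survives clustering", {
  tbl <- random_sample_table(60, 30, seed = 9)
  dug <- select_dug(tbl, top_n = 30, redundancy_r = 1.0)
  expect_equal(nrow(dug), 30)
  expect_error(select_dug(tbl, top_n = 0), "positive")
})

test_that("extreme-tail sizing follows the floor rule with a minimum of two", {
  v20 <- setNames(seq_len(20), sprintf("c%02d", 1:20))
  expect_equal(dsg_extreme_cells(v20, 0.1),
               c("c01", "c02", "c19", "c20"))
  v25 <- setNames(seq_len(25), sprintf("c%02d", 1:25))
  expect_length(dsg_extreme_cells(v25, 0.1), 4) # floor(2.5) = 2 per tail
  v30 <- setNames(seq_len(30), sprintf("c%02d", 1:30))
  expect_length(dsg_extreme_cells(v30, 0.1), 6)
  expect_error(dsg_extreme_cells(setNames(1:19, sprintf("c%d", 1:19))),
               "insufficient cell lines")
})

test_that("expression ties in tail selection break by cell-line id", {
  v <- setNames(c(0, 0, 0, 0, 1, 1, rep(0.5, 14)), sprintf("c%02d", 20:1))
  picked <- dsg_extreme_cells(v, 0.1)
  low <- sort(names(v)[v == 0])[1:2]
  expect_true(all(low %in% picked))
})

test_that("a gene mirroring the response is always selected", {
  co <- tiny_cohort(seed = 30, C = 60, G = 40, missing = 0)
  expr <- co$expression
  y <- expr$g0001 * 2 + 1 # perfectly collinear with gene g0001
  resp <- tibble::tibble(cell_line = expr$cell_line, mirror = y)
  screen <- select_dsg(expr, resp, "mirror")
  expect_true(screen$selected[screen$gene_id == "g0001"])
  expect_equal(screen$r[screen$gene_id == "g0001"], 1)
})

test_that("the screen matches the brute-force sort-slice-correlate oracle", {
  set.seed(77)
  for (rep in 1:5) {
    tbl <- random_sample_table(30, 50, seed = 700 + rep)
    m <- as.matrix(tbl[, -1]); rownames(m) <- tbl$cell_line
    y <- setNames(rnorm(30), tbl$cell_line)
    y[sample(30, 2)] <- NA
    resp <- tibble::tibble(cell_line = tbl$cell_line, d = unname(y[tbl$cell_line]))
    screen <- select_dsg(tbl, resp, "d", r_threshold = 0.3)
    expect_setequal(screen$gene_id[screen$selected],
                    oracle_dsg(m, y, 0.1, 0.3))
  }
})

test_that("selection uses training cells only: test-cell values are irrelevant", {
  co <- tiny_cohort(seed = 31, C = 100, G = 60, missing = 0)
  cells <- co$expression$cell_line
  train <- cells[1:70]
  screen1 <- select_dsg(co$expression, co$response, "drug_01", cells = train)
  tampered <- co$expression
  idx <- tampered$cell_line %in% cells[71:100]
  tampered[idx, -1] <- tampered[idx, -1] + 100
  screen2 <- select_dsg(tampered, co$response, "drug_01", cells = train)
  expect_identical(screen1$r, screen2$r)
  expect_identical(screen1$selected, screen2$selected)
})

test_that("lowering the threshold never drops a selected gene", {
  co <- tiny_cohort(seed = 32, C = 80, G = 50, missing = 0)
  hi <- select_dsg(co$expression, co$response, "drug_01", r_threshold = 0.5)
  lo <- select_dsg(co$expression, co$response, "drug_01", r_threshold = 0.3)
  expect_true(all(hi$gene_id[hi$selected] %in% lo$gene_id[lo$selected]))
})
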