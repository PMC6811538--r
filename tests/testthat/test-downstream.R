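test_that("median binarization labels follow the strict-above rule", {
  lab4 <- binarize_by_median(c(1, 2, 3, 4))
  expect_equal(unname(lab4), c("sensitive", "sensitive", "resistant", "resistant"))
  lab5 <- binarize_by_median(c(1, 2, 3, 4, 5))
  expect_equal(sum(lab5 == "sensitive"), 3) # the median value itself is sensitive
  expect_equal(sum(lab5 == "resistant"), 2)
  with_na <- binarize_by_median(c(1, 2, NA, 3, 4))
  expect_true(is.na(with_na[3]))
  expect_error(binarize_by_median(rep(2, 6)), "degenerate")
  expect_error(binarize_by_median(c(1, 2, 3)), "at least 4")
})

test_that("binarized class sizes differ by at most the number of median ties", {
  set.seed(2)
  for (i in 1:20) {
    v <- sample(1:8, 12, replace = TRUE)
    lab <- binarize_by_median(v)
    ties <- sum(v == median(v))
    # with t median-tied values the split can be off by up to 2t - 1
    expect_lte(abs(sum(lab == "sensitive") - sum(lab == "resistant")),
               max(0, 2 * ties - 1))
  }
})

test_that("classification metrics reproduce hand-computed confusion tables", {
  perfect <- classification_metrics(rep(c("sensitive", "resistant"), each = 5),
                                    rep(c("sensitive", "resistant"), each = 5))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)
  inverted <- classification_metrics(
    rep(c("resistant", "sensitive"), each = 5),
    rep(c("sensitive", "resistant"), each = 5))
  expect_equal(inverted$mcc, -1)
  # tp=3 fp=1 fn=2 tn=4
  pred <- c(rep("sensitive", 3), rep("resistant", 2), "sensitive", rep("resistant", 4))
  obs <- c(rep("sensitive", 5), rep("resistant", 5))
  m <- classification_metrics(pred, obs)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 2); expect_equal(m$tn, 4)
  expect_equal(m$mcc, 10 / sqrt(600))
  all_pos <- classification_metrics(rep("sensitive", 10), obs)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$mcc, 0)
  expect_error(classification_metrics(pred, rep("sensitive", 10)), "single class")
})

test_that("MCC equals the Pearson correlation of the binary label vectors", {
  set.seed(14)
  done <- 0
  while (done < 200) {
    n <- sample(6:30, 1)
    pred <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    obs <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    if (length(unique(obs)) < 2 || length(unique(pred)) < 2) next
    m <- classification_metrics(pred, obs)
    r <- pearson_complete(as.numeric(pred == "sensitive"),
                          as.numeric(obs == "sensitive"))
    expect_equal(m$mcc, r, tolerance = 1e-12)
    done <- done + 1
  }
})

test_that("drug-unique genes require a dominant top drug and a subcritical runner-up", {
  # a lone spike among m drugs has z = (m - 1) / sqrt(m) at most, so at
  # least 11 drugs are needed before the z >= 3 rule can fire at all
  drugs <- sprintf("d%02d", 1:12)
  base <- tidyr::expand_grid(gene_id = c("gA", "gB", "gC"), drug_id = drugs)
  base$count <- 50L
  # gA: one dominant drug -> unique; z_top of [9000, 50 x 11] clears 3
  base$count[base$gene_id == "gA" & base$drug_id == "d01"] <- 9000L
  z <- (9000 - mean(c(9000, rep(50, 11)))) / sd(c(9000, rep(50, 11)))
  expect_gte(z, 3)
  # gB: two tied dominant drugs -> not unique
  base$count[base$gene_id == "gB" & base$drug_id %in% c("d01", "d02")] <- 9000L
  # gC: flat counts -> no assignment
  out <- drug_unique_genes(base, z_threshold = 3)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$drug_id, "d01")
  expect_error(drug_unique_genes(base[base$drug_id %in% drugs[1:2], ]),
               "at least 3 drugs")
})

test_that("drug-unique assignment is stable under drug-column permutation", {
  set.seed(4)
  drugs <- sprintf("d%02d", 1:6)
  tab <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:8), drug_id = drugs)
  tab$count <- rpois(nrow(tab), 20)
  tab$count[tab$gene_id == "g01" & tab$drug_id == "d03"] <- 500L
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(drug_unique_genes(tab), drug_unique_genes(shuffled))
})

test_that("fingerprint similarity follows set arithmetic", {
  expect_equal(fingerprint_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fingerprint_similarity(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(fingerprint_similarity(integer(0), integer(0)), 0)
  expect_equal(fingerprint_similarity(c(1, 2), c(3, 4)), 0)
  expect_error(fingerprint_similarity(1:3, 2:4, "tversky", alpha = -1), "non-negative")
  set.seed(31)
  for (i in 1:100) {
    a <- sample(0:40, sample(0:15, 1))
    b <- sample(0:40, sample(1:15, 1))
    tan <- fingerprint_similarity(a, b, "tanimoto")
    tve <- fingerprint_similarity(a, b, "tversky", alpha = 1, beta = 1)
    expect_equal(tan, tve)
    expect_equal(fingerprint_similarity(b, a, "tanimoto"), tan)
  }
})

test_that("IC50 profile similarity delegates to complete-observation correlation", {
  co <- tiny_cohort(seed = 61, D = 2, k = 4, n_classes = 1, overlap = 1,
                    noise_sd = 0.3)
  self <- ic50_profile_similarity(co$response, "drug_01", "drug_01")
  expect_equal(self$r, 1)
  pair <- ic50_profile_similarity(co$response, "drug_01", "drug_02")
  expect_gt(pair$r, 0.8) # clone drugs, low noise
  expect_lte(pair$n_effective, nrow(co$response))
})

test_that("mutation association flags a clean split and ignores tiny groups", {
  set.seed(9)
  cells <- sprintf("c%03d", 1:30)
  y <- sort(rnorm(30))
  resp <- tibble::tibble(cell_line = cells, d = y)
  mut <- matrix(0L, 30, 3, dimnames = list(cells, c("gSplit", "gRand", "gRare")))
  mut[16:30, "gSplit"] <- 1L # mutated cells are exactly the high-IC50 half
  mut[sample(30, 14), "gRand"] <- 1L
  mut[1:2, "gRare"] <- 1L
  out <- mutation_association(as_sample_table(mut), resp, "d")
  expect_false("gRare" %in% out$gene_id)
  expect_lt(out$p_adjusted[out$gene_id == "gSplit"], 0.01)
  none <- suppressWarnings(mutation_association(
    as_sample_table(mut[, "gRare", drop = FALSE]), resp, "d"))
  expect_equal(nrow(none), 0)
})

test_that("random mutation labels rarely survive adjustment", {
  set.seed(10)
  cells <- sprintf("c%03d", 1:60)
  resp <- tibble::tibble(cell_line = cells, d = rnorm(60))
  mut <- matrix(rbinom(60 * 100, 1, 0.4), 60, 100,
                dimnames = list(cells, sprintf("g%03d", 1:100)))
  out <- mutation_association(as_sample_table(mut), resp, "d")
  expect_lt(mean(out$p_value < 0.05), 0.12) # ~5% raw hits
  expect_equal(sum(out$p_adjusted < 0.05), 0)
})
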