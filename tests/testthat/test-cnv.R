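test_that("cnv_score is the mean of squares", {
  expect_equal(cnv_score(c(0.5, -0.5, 1, 0)), 0.375)
  expect_equal(cnv_score(rep(0, 10)), 0)
  expect_equal(cnv_score(c(1, -1, 1)), 1)
  expect_error(cnv_score(numeric(0)), "empty")
  set.seed(2)
  for (i in 1:50) {
    v <- runif(sample(1:30, 1), -1, 1)
    expect_equal(cnv_score(v), sum(v^2) / length(v), tolerance = 1e-15)
  }
})

test_that("scale_standardize maps into [-1, 1] with the documented guards", {
  z <- scale_standardize(matrix(0, 4, 5))
  expect_true(all(z == 0))
  set.seed(4)
  m <- matrix(rnorm(60), 6, 10)
  z <- scale_standardize(m)
  expect_equal(max(abs(z)), 1)
  expect_true(all(abs(z) <= 1))
  # invariant to positive rescaling of the input
  expect_equal(scale_standardize(3.7 * m), z, tolerance = 1e-12)
})

test_that("relative expression reduces to plain differences at window 1", {
  set.seed(5)
  ng <- 30
  ids <- sprintf("g%02d", 1:ng)
  g <- tibble::tibble(gene_id = ids, symbol = ids,
                      chromosome = rep(c("chr1", "chr2"), each = 15),
                      start = rep(1:15, 2) * 1000L, is_mito = FALSE)
  ref <- matrix(rnorm(ng * 25, 5), ng, 25,
                dimnames = list(ids, sprintf("r%02d", 1:25)))
  q <- matrix(rnorm(ng * 4, 5), ng, 4,
              dimnames = list(ids, sprintf("q%02d", 1:4)))
  re <- relative_expression(q, ref, g, window = 1, clip_sd = 1e6)
  ord <- order(g$chromosome, g$start, g$gene_id)
  expect_equal(re$values, (q - rowMeans(ref))[ord, ], tolerance = 1e-12)
  # a query equal to the reference mean gives all-zero values
  q0 <- matrix(rowMeans(ref), ng, 3,
               dimnames = list(ids, c("a", "b", "c")))
  re0 <- relative_expression(q0, ref, g, window = 5)
  expect_true(all(abs(re0$values) < 1e-12))
  expect_error(relative_expression(q, ref, g, window = 4), "odd")
  expect_error(relative_expression(q, ref[, 1:10], g, window = 1), "20")
})

test_that("an injected gain elevates windowed values over the gained block", {
  p <- tiny_params(n_patients = 1, cells_per_sample = 300,
                   malignant_frac = 0.5, lambda = 1e-6, doublet_rate = 0)
  coh <- generate_cohort(p, seed = 21)
  truth <- coh$truth$cells
  nrm <- normalize_counts(coh$counts)
  epi <- truth$level1 == "Epithelial"
  qbc <- truth$barcode[epi & truth$tissue == "Tumor" &
                         truth$method == "nucleus"]
  rbc <- truth$barcode[epi & truth$tissue == "Normal" &
                         truth$method == "nucleus"]
  re <- relative_expression(nrm[, qbc], nrm[, rbc], coh$genes, window = 21)
  gt <- coh$truth$genes
  gain <- gt$cnv_state[match(re$genes$gene_id, gt$gene_id)] == "gain"
  neutral <- gt$cnv_state[match(re$genes$gene_id, gt$gene_id)] == "neutral"
  mal <- truth$malignant[match(qbc, truth$barcode)]
  delta <- colMeans(re$values[gain, , drop = FALSE]) -
    colMeans(re$values[neutral, , drop = FALSE])
  expect_gte(mean(delta[mal] > 0), 0.95)
})

test_that("the quintile rule flags the anti-ranked toy exactly", {
  sc <- tibble::tibble(barcode = sprintf("c%02d", 1:10),
                       cnv_score = 1:10 / 10,
                       annotation_score = 10:1 / 10,
                       epithelial = TRUE, patient = "P1", method = "cell")
  out <- classify_malignant(sc)
  expect_equal(which(out$malignant), c(9, 10))
  # non-epithelial cells are never malignant
  sc2 <- sc; sc2$epithelial[9:10] <- FALSE
  out2 <- classify_malignant(sc2)
  expect_false(any(out2$malignant[9:10]))
  # strata under 5 epithelial cells are skipped with a warning
  sc4 <- sc[1:4, ]
  expect_warning(out4 <- classify_malignant(sc4), "skipped")
  expect_false(any(out4$malignant))
  # degenerate all-tied scores flag everything under the >=/<= rule
  sc3 <- sc; sc3$cnv_score <- 0.5; sc3$annotation_score <- 0.5
  expect_true(all(classify_malignant(sc3)$malignant))
})

test_that("diploid cells score stochastically below aneuploid cells", {
  p <- tiny_params(n_patients = 1, cells_per_sample = 400,
                   malignant_frac = 0.5, doublet_rate = 0)
  coh <- generate_cohort(p, seed = 31)
  truth <- coh$truth$cells
  nrm <- normalize_counts(coh$counts)
  epi <- truth$level1 == "Epithelial"
  qbc <- truth$barcode[epi & truth$tissue == "Tumor" &
                         truth$method == "nucleus"]
  rbc <- truth$barcode[epi & truth$tissue == "Normal" &
                         truth$method == "nucleus"]
  qm <- tibble::tibble(barcode = qbc, patient = "P1", method = "nucleus",
                       annotation_score = 1)
  cc <- cnv_call(nrm[, qbc], nrm[, rbc], coh$genes, qm, window = 51)
  mal <- truth$malignant[match(cc$barcode, truth$barcode)]
  wt <- wilcox.test(cc$cnv_score[!mal], cc$cnv_score[mal],
                    alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
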