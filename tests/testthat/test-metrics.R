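ann_fixture <- function() {
  tibble::tibble(barcode = sprintf("b%03d", 1:100),
                 level = 1,
                 label = c(rep("Immune", 80), rep("Epithelial", 20)),
                 score = 0.9, unclassified = FALSE)
}

cells_fixture <- function() {
  tibble::tibble(barcode = sprintf("b%03d", 1:100), patient = "P1",
                 tissue = "Normal", method = "cell")
}

test_that("composition tables count and normalize per dataset", {
  comp <- composition_table(ann_fixture(), cells_fixture())
  expect_equal(comp$proportion[comp$label == "Immune"], 0.8)
  expect_equal(comp$proportion[comp$label == "Epithelial"], 0.2)
  expect_equal(sum(comp$proportion), 1)
  one <- ann_fixture(); one$label <- "Immune"
  expect_equal(composition_table(one, cells_fixture())$proportion, 1)
  expect_error(composition_table(ann_fixture()[0, ], cells_fixture()),
               "empty")
})

test_that("transition ratios follow the declared conventions", {
  cn <- tibble::tibble(patient = "P1", method = "cell",
                       label = c("AT1", "AT2"), n = c(10, 10),
                       proportion = c(0.1, 0.9))
  ct <- tibble::tibble(patient = "P1", method = "cell",
                       label = c("AT1", "Secretory"), n = c(20, 10),
                       proportion = c(0.2, 0.8))
  tr <- transition_ratio(ct, cn)
  expect_equal(tr$ratio[tr$label == "AT1"], 2)
  # absent from Normal -> missing, never infinite
  expect_true(is.na(tr$ratio[tr$label == "Secretory"]))
  same <- transition_ratio(cn, cn)
  expect_true(all(same$ratio == 1))
})

test_that("Fisher contrasts match enumeration and invert under row swap", {
  r <- unclassified_contrast(5, 100, 5, 100)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r$p, 1)
  r2 <- unclassified_contrast(8, 10, 1, 10)
  expect_equal(r2$p, oracle_fisher_p(matrix(c(8, 2, 1, 9), 2, byrow = TRUE)),
               tolerance = 1e-9)
  r3 <- unclassified_contrast(1, 10, 8, 10)
  expect_equal(r2$odds_ratio, 1 / r3$odds_ratio, tolerance = 1e-6)
  z <- unclassified_contrast(0, 10, 0, 10)
  expect_true(is.na(z$odds_ratio))
  expect_equal(z$p, 1)
  expect_error(unclassified_contrast(11, 10, 1, 10), "exceed")
})

test_that("silhouette matches the O(n^2) oracle and handles edge cases", {
  set.seed(80)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    labs <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    emb <- tibble::tibble(barcode = as.character(1:n),
                          dim1 = x[, 1], dim2 = x[, 2])
    got <- silhouette_by_label(emb, labs)$cells$s
    expect_equal(got, oracle_silhouette(x, labs), tolerance = 1e-10)
  }
  # two tight far-separated blobs
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 10, 0.05), 20, 2))
  emb <- tibble::tibble(barcode = as.character(1:40),
                        dim1 = x[, 1], dim2 = x[, 2])
  labs <- rep(c("a", "b"), each = 20)
  expect_gt(median(silhouette_by_label(emb, labs)$cells$s), 0.95)
  # duplicating every point leaves widths unchanged
  emb2 <- dplyr::bind_rows(emb, dplyr::mutate(emb, barcode = paste0(barcode, "d")))
  s2 <- silhouette_by_label(emb2, rep(labs, 2))$cells$s
  expect_equal(s2[1:40], silhouette_by_label(emb, labs)$cells$s,
               tolerance = 0.02)
  # singleton labels score zero and are flagged
  labs3 <- labs; labs3[1] <- "solo"
  s3 <- silhouette_by_label(emb, labs3)
  expect_equal(s3$cells$s[1], 0)
  expect_true(s3$cells$singleton[1])
  expect_error(silhouette_by_label(emb, rep("a", 40)), "2 labels")
})

test_that("signature fractions use the intersected denominator", {
  genes <- sprintf("g%04d", 1:600)
  m <- Matrix::sparseMatrix(i = 1:100, j = rep(1, 100), x = 1,
                            dims = c(600, 2))
  dimnames(m) <- list(genes, c("c1", "c2"))
  sig <- c(genes[1:482], "absent1", "absent2")
  sf <- signature_fraction(m, sig)
  expect_equal(sf$n_signature, 482)
  expect_equal(sf$cells$fraction[1], 100 / 482, tolerance = 1e-12)
  expect_equal(sf$cells$fraction[2], 0)
  full <- Matrix::Matrix(matrix(1, 600, 1,
                                dimnames = list(genes, "c1")), sparse = TRUE)
  expect_equal(signature_fraction(full, genes[1:10])$cells$fraction, 1)
  expect_error(signature_fraction(m, c("nope")), "intersect")
})

test_that("raw mitochondrial fractions equal the QC metric formula", {
  m <- toy_counts(nr = 8, nc = 5, seed = 81)
  g <- toy_gene_table(rownames(m), mito = rownames(m)[1:2])
  mf <- mito_fraction_raw(m, g)
  met <- compute_cell_metrics(m, g)
  expect_equal(mf$cells$percent_mt, met$percent_mt)
})

test_that("two-way ANOVA matches the balanced closed form", {
  # balanced 2x2 with n=5 per cell and known cell means
  set.seed(82)
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                   rep = 1:5, stringsAsFactors = FALSE)
  mu <- c(a1b1 = 0, a2b1 = 2, a1b2 = 1, a2b2 = 3)
  d$y <- mu[paste0(d$a, d$b)] + rnorm(nrow(d), 0, 0.5)
  got <- two_way_anova(d, "y", "a", "b")
  # closed form for the balanced main-effects model
  fit <- lm(y ~ a + b, d)
  an <- anova(fit)                       # Type I == Type II when balanced
  expect_equal(got$F, an[c("a", "b"), "F value"], tolerance = 1e-9)
  expect_equal(got$p, an[c("a", "b"), "Pr(>F)"], tolerance = 1e-9)
  # constant response
  d0 <- d; d0$y <- 7
  g0 <- two_way_anova(d0, "y", "a", "b")
  expect_equal(g0$F, c(0, 0))
  expect_equal(g0$p, c(1, 1))
  # joint permutation of rows leaves F unchanged
  perm <- sample(nrow(d))
  gp <- two_way_anova(d[perm, ], "y", "a", "b")
  expect_equal(gp$F, got$F, tolerance = 1e-10)
  expect_error(two_way_anova(d[d$a == "a1", ], "y", "a", "b"), "levels")
})
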