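test_that("per-cell metrics follow the definitions", {
  m <- Matrix::Matrix(matrix(c(5, 0, 7,    # cell 1 (column)
                               0, 0, 0,    # all-zero cell
                               2, 2, 0), nrow = 3),
                      sparse = TRUE)
  dimnames(m) <- list(c("g1", "g2", "g3"), c("c1", "c2", "c3"))
  g <- toy_gene_table(c("g1", "g2", "g3"), mito = "g1")
  met <- compute_cell_metrics(m, g)
  expect_equal(met$nCount, c(12L, 0L, 4L))
  expect_equal(met$nFeatures, c(2L, 0L, 2L))
  expect_equal(met$percent_mt[1], 100 * 5 / 12, tolerance = 1e-10)
  expect_true(is.na(met$percent_mt[2]))
  expect_true(met$zero_count[2])
  # all counts on mitochondrial genes -> 100%
  m2 <- m; m2["g2", ] <- 0; m2["g3", ] <- 0; m2["g1", 2] <- 3
  expect_equal(compute_cell_metrics(m2, g)$percent_mt, rep(100, 3))
})

test_that("MAD filter handles the documented edge cases", {
  f <- mad_outlier_filter(c(1, 1, 1, 1, 100), nmads = 3)
  expect_equal(f$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_warning(fc <- mad_outlier_filter(rep(5, 10)), "identical")
  expect_true(all(fc$keep))
  # cap binds: median 20, MAD 5 => min(35, 25) = 25
  v <- 20 + c(-1, -1, 0, 1, 1) * 5 / 1.4826
  fm <- mad_outlier_filter(v, nmads = 3, cap = 25, type = "upper")
  expect_equal(fm$upper, 25, tolerance = 1e-9)
  expect_equal(fm$lower, -Inf)
  expect_error(mad_outlier_filter(c(1, 2)), "3 finite")
})

test_that("MAD filter agrees exactly with the brute-force oracle", {
  set.seed(99)
  for (i in 1:250) {
    n <- sample(3:40, 1)
    v <- round(rexp(n, 0.05), 2)
    nm <- sample(c(1, 2, 3), 1)
    lg <- sample(c(TRUE, FALSE), 1)
    tp <- sample(c("both", "upper", "lower"), 1)
    cp <- if (runif(1) < 0.3) runif(1, 5, 50) else NULL
    got <- suppressWarnings(
      mad_outlier_filter(v, nm, log_scale = lg, cap = cp, type = tp))
    expect_identical(got$keep, oracle_mad_filter(v, nm, lg, cp, tp))
  }
})

test_that("filtering with frozen thresholds is idempotent", {
  set.seed(3)
  v <- rlnorm(200, 7, 0.6)
  f <- mad_outlier_filter(v, 3, log_scale = TRUE)
  kept <- v[f$keep]
  expect_true(all(kept >= f$lower & kept <= f$upper))
})

test_that("qc_filter freezes per-sample thresholds and respects the cap", {
  set.seed(8)
  met <- tibble::tibble(
    barcode = sprintf("b%03d", 1:120),
    sample = rep(c("s1", "s2"), each = 60),
    nCount = round(rlnorm(120, 7, 0.5)),
    nFeatures = round(rlnorm(120, 6, 0.4)),
    percent_mt = c(runif(60, 0, 60), runif(60, 0, 10)),
    zero_count = FALSE)
  qf <- qc_filter(met, nmads = 3, mito_cap = 25)
  thr <- qf$thresholds
  expect_true(all(thr$upper[thr$metric == "percent_mt"] <= 25))
  expect_equal(nrow(thr), 6)
  expect_true(all(qf$cells$qc_pass ==
                    (qf$cells$pass_ncount & qf$cells$pass_nfeatures &
                       qf$cells$pass_mito)))
})

test_that("doublet detection flags the contracted count and finds spikes", {
  p <- tiny_params(n_patients = 1, cells_per_sample = 800, doublet_rate = 0)
  coh <- generate_cohort(p, seed = 4)
  bc <- coh$cells$barcode[coh$cells$sample == coh$cells$sample[1]]
  m <- coh$counts[, bc]
  truth <- coh$truth$cells[match(bc, coh$truth$cells$barcode), ]
  tree <- p$tree
  rec <- c()
  for (sd in 1:2) {
    set.seed(sd)
    sp <- spike_doublets(m, truth, 0.08)
    dd <- detect_doublets(sp$counts, expected_rate = 0.08, seed = sd)
    expect_equal(sum(dd$doublet), round(0.08 * ncol(sp$counts)))
    t2 <- sp$truth
    cross <- t2$doublet &
      tree$level1[match(t2$level3, tree$level3)] !=
        tree$level1[match(t2$level3_parent2, tree$level3)]
    cross[is.na(cross)] <- FALSE
    rec <- c(rec, mean(dd$doublet[match(t2$barcode[cross], dd$barcode)]))
  }
  # cross-compartment doublet recall (clearly separated parents)
  expect_gte(mean(rec), 0.6)
  expect_error(detect_doublets(m, 0.05, k = 10000), "k larger")
  # barcode labels do not influence scores
  m2 <- sp$counts
  colnames(m2) <- sprintf("renamed%04d", seq_len(ncol(m2)))
  dd2 <- detect_doublets(m2, expected_rate = 0.08, seed = 2)
  expect_equal(detect_doublets(sp$counts, expected_rate = 0.08,
                               seed = 2)$doublet_score,
               dd2$doublet_score)
})

test_that("normalization matches its closed form and OLS removes percent_mt", {
  m <- toy_counts(nr = 30, nc = 21, seed = 10)
  nrm <- normalize_counts(m)
  nc <- Matrix::colSums(m)
  med_cell <- which(nc == median(nc))[1]
  expect_equal(as.numeric(nrm[, med_cell]),
               log1p(as.numeric(m[, med_cell])), tolerance = 1e-12)
  # doubling all counts only changes the global median factor
  expect_equal(unname(as.matrix(normalize_counts(2 * m))),
               unname(as.matrix(log1p(2 * (m %*% Matrix::Diagonal(
                 x = median(nc) / nc))))), tolerance = 1e-12)
  pm <- runif(21, 0, 30)
  res <- normalize_counts(m, regress_mt = TRUE, percent_mt = pm)
  cors <- apply(res, 1, function(r) if (sd(r) > 0) cor(r, pm) else 0)
  expect_lt(max(abs(cors)), 1e-8)
})
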