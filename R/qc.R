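#' Per-cell quality-control metrics
#'
#' Computes, for every barcode, `nCount` (total UMIs), `nFeatures` (genes
#' detected) and `percent_mt` (percentage of UMIs on mitochondrial genes).
#' Cells with `nCount = 0` get `percent_mt = NA` and are flagged so they can
#' be excluded from threshold estimation.
#'
#' @param counts Sparse gene x cell count matrix.
#' @param genes Gene table covering all matrix genes (needs `is_mito`).
#' @return A tibble: `barcode`, `nCount`, `nFeatures`, `percent_mt`,
#'   `zero_count`.
#' @export
compute_cell_metrics <- function(counts, genes) {
  counts <- validate_counts(counts)
  genes <- validate_gene_table(genes)
  miss <- setdiff(rownames(counts), genes$gene_id)
  if (length(miss)) stop("gene table does not cover matrix genes: ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  mito <- genes$gene_id[genes$is_mito]
  n_count <- Matrix::colSums(counts)
  n_feat <- Matrix::colSums(counts > 0)
  mt <- if (length(mito)) {
    Matrix::colSums(counts[rownames(counts) %in% mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  pct <- ifelse(n_count > 0, 100 * mt / n_count, NA_real_)
  tibble::tibble(barcode = colnames(counts),
                 nCount = as.integer(unname(n_count)),
                 nFeatures = as.integer(unname(n_feat)),
                 percent_mt = unname(pct),
                 zero_count = unname(n_count == 0))
}

#' MAD-based outlier filter for a QC metric
#'
#' Thresholds are `median +/- nmads * MAD` (MAD with the 1.4826 normal
#' consistency constant, so `nmads` reads as a robust z-score), optionally
#' computed on the `log1p` scale. For an upper-only metric such as
#' `percent_mt`, pass `type = "upper"` and an absolute `cap`; the upper
#' threshold is then `min(median + nmads * MAD, cap)`. When the MAD is zero
#' because all values are identical no value is removed (a warning is
#' raised); with a zero MAD but unequal values, only values equal to the
#' median survive, which is the literal reading of the rule.
#'
#' @param values Numeric vector (>= 3 finite values).
#' @param nmads Positive multiplier (default 3).
#' @param log_scale Estimate thresholds on `log1p(values)`?
#' @param cap Optional absolute upper cap (applied after MAD), e.g. 25 for
#'   `percent_mt`.
#' @param type `"both"` (default), `"upper"` or `"lower"` tails.
#' @return A list: logical `keep`, numeric `lower`/`upper` thresholds on the
#'   original scale, and the `median`/`mad` used (on the estimation scale).
#' @examples
#' mad_outlier_filter(c(1, 1, 1, 1, 100), nmads = 3)$keep
#' @export
mad_outlier_filter <- function(values, nmads = 3, log_scale = FALSE,
                               cap = NULL, type = c("both", "upper", "lower")) {
  type <- match.arg(type)
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("need at least 3 finite values", call. = FALSE)
  v <- if (log_scale) log1p(values) else values
  med <- stats::median(v[ok])
  md <- stats::mad(v[ok])          # constant = 1.4826
  if (md == 0 && length(unique(v[ok])) == 1)
    warning("all values identical (MAD = 0): nothing filtered", call. = FALSE)
  lo <- med - nmads * md
  hi <- med + nmads * md
  if (log_scale) { lo <- expm1(lo); hi <- expm1(hi) }
  if (type == "upper") lo <- -Inf
  if (type == "lower") hi <- Inf
  if (!is.null(cap) && type != "lower") hi <- min(hi, cap)
  keep <- values >= lo & values <= hi
  keep[!ok] <- FALSE
  list(keep = keep, lower = lo, upper = hi,
       median = med, mad = md)
}

#' Per-sample MAD quality-control filtering
#'
#' Applies [mad_outlier_filter()] per sample: two-sided on `log1p(nCount)`
#' and `log1p(nFeatures)`, upper-only on `percent_mt` with an absolute cap
#' (default 25%). Thresholds are estimated once per sample and frozen.
#'
#' @param metrics Output of [compute_cell_metrics()] joined with sample
#'   identity columns (anything in `sample_by`).
#' @param nmads MAD multiplier.
#' @param mito_cap Absolute `percent_mt` upper cap.
#' @param sample_by Character columns defining a sample (default `"sample"`).
#' @return A list with `cells` (input plus `qc_pass` and per-metric pass
#'   flags) and `thresholds` (per sample x metric lower/upper bounds).
#' @export
qc_filter <- function(metrics, nmads = 3, mito_cap = 25,
                      sample_by = "sample") {
  miss <- setdiff(sample_by, names(metrics))
  if (length(miss)) stop("missing sample columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- interaction(metrics[sample_by], drop = TRUE)
  out <- vector("list", nlevels(key))
  thr <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    s <- levels(key)[i]
    rows <- metrics[key == s, , drop = FALSE]
    fc <- mad_outlier_filter(rows$nCount, nmads, log_scale = TRUE)
    ff <- mad_outlier_filter(rows$nFeatures, nmads, log_scale = TRUE)
    fm <- mad_outlier_filter(rows$percent_mt, nmads, log_scale = FALSE,
                             cap = mito_cap, type = "upper")
    rows$pass_ncount <- fc$keep
    rows$pass_nfeatures <- ff$keep
    rows$pass_mito <- fm$keep
    rows$qc_pass <- fc$keep & ff$keep & fm$keep & !rows$zero_count
    out[[i]] <- rows
    thr[[i]] <- tibble::tibble(
      sample = s,
      metric = c("nCount", "nFeatures", "percent_mt"),
      lower = c(fc$lower, ff$lower, fm$lower),
      upper = c(fc$upper, ff$upper, fm$upper))
  }
  list(cells = dplyr::bind_rows(out), thresholds = dplyr::bind_rows(thr))
}

#' Artificial-nearest-neighbour doublet detection
#'
#' Builds `pN * n` artificial doublets by summing the counts of two random
#' real cells (after library normalization a sum and a mean are the same
#' profile), embeds real and artificial cells in a joint PC space, and scores each
#' real cell by the fraction of its `k` nearest neighbours that are
#' artificial. The top `round(expected_rate * n)` scores are flagged, ties
#' broken by barcode (column) order. Only the 5% expected-rate contract is
#' taken from droplet practice; the scheme is intentionally minimal.
#'
#' @param counts Sparse count matrix for one sample.
#' @param expected_rate Expected doublet proportion in (0, 0.5).
#' @param pN Artificial-doublet proportion (default 0.25).
#' @param k Neighbours (default 30).
#' @param n_pcs PCs for the joint embedding (default 20).
#' @param seed Optional seed for the artificial-pair draw.
#' @return A tibble: `barcode`, `doublet_score`, `doublet`.
#' @export
detect_doublets <- function(counts, expected_rate = 0.05, pN = 0.25,
                            k = 30, n_pcs = 20, seed = NULL) {
  if (expected_rate <= 0 || expected_rate >= 0.5)
    stop("expected_rate must be in (0, 0.5)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(counts)
  n_art <- max(2L, round(pN * n))
  if (k >= n + n_art) stop("k larger than the joint population", call. = FALSE)
  a1 <- sample.int(n, n_art, replace = TRUE)
  a2 <- vapply(a1, function(i) sample(setdiff(seq_len(n), i), 1L), 1L)
  # mix in count space (a droplet doublet is a sum of two cells' counts;
  # library normalization makes sum and mean equivalent), then normalize
  # real and artificial columns jointly
  art <- counts[, a1, drop = FALSE] + counts[, a2, drop = FALSE]
  colnames(art) <- sprintf(".art%05d", seq_len(n_art))
  norm <- normalize_counts(cbind(counts, art))
  joint <- t(norm)
  fit <- pca_fit(joint, n_pcs)
  nn <- knn_search(fit$scores[seq_len(n), , drop = FALSE], fit$scores, k + 1L)
  # drop each real cell's self-neighbour (distance 0, first column)
  is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
  score <- vapply(seq_len(n), function(i) {
    nb <- nn$index[i, ]
    nb <- nb[nb != i][seq_len(k)]
    mean(is_art[nb])
  }, 0)
  n_flag <- round(expected_rate * n)
  ord <- order(-score, seq_len(n))
  flag <- logical(n)
  flag[ord[seq_len(n_flag)]] <- TRUE
  tibble::tibble(barcode = colnames(counts), doublet_score = score,
                 doublet = flag)
}

#' Median-scaled log-normalization
#'
#' Scales each cell to the median library size and applies `log1p`:
#' `x = log1p(count * median(nCount) / nCount)`. With `regress_mt = TRUE`
#' each gene is replaced by the residuals of an ordinary least-squares fit
#' on `percent_mt`, plus the gene mean (this densifies the matrix and is
#' intended for modest subsets).
#'
#' @param counts Sparse count matrix (QC-passing cells).
#' @param regress_mt Residualize on `percent_mt`?
#' @param percent_mt Per-cell percentages, required when `regress_mt`.
#' @return A genes x cells matrix of normalized expression (sparse unless
#'   `regress_mt`).
#' @export
normalize_counts <- function(counts, regress_mt = FALSE, percent_mt = NULL) {
  n_count <- Matrix::colSums(counts)
  med <- stats::median(n_count[n_count > 0])
  if (!length(med) || is.na(med) || med == 0)
    stop("zero median library size", call. = FALSE)
  sf <- ifelse(n_count > 0, med / n_count, 0)
  norm <- counts %*% Matrix::Diagonal(x = sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  if (!regress_mt) return(methods::as(norm, "generalMatrix"))
  if (is.null(percent_mt) || length(percent_mt) != ncol(counts))
    stop("percent_mt (one value per cell) required when regress_mt",
         call. = FALSE)
  x <- cbind(1, percent_mt)
  dense <- as.matrix(norm)
  beta <- solve(crossprod(x), crossprod(x, t(dense)))
  resid <- t(dense) - x %*% beta
  out <- t(resid) + rowMeans(dense)
  dimnames(out) <- dimnames(counts)
  out
}
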