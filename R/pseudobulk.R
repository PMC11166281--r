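#' Aggregate counts to pseudobulk groups
#'
#' Sums raw counts over cells within each (cell type, patient, tissue,
#' method) group, using QC-passing, non-doublet, classified cells. Groups
#' with fewer than `min_cells` cells are dropped with a warning. Column
#' sums are exactly conserved versus the member cells.
#'
#' @param counts Sparse gene x cell count matrix.
#' @param cells Tibble with `barcode`, `patient`, `tissue`, `method` and a
#'   `celltype` column (the level being aggregated).
#' @param min_cells Minimum cells per group (default 10).
#' @return A list of class `pairseq_pseudobulk`: `matrix` (genes x groups)
#'   and `groups` (tibble with the group key and `n_cells`).
#' @export
aggregate_pseudobulk <- function(counts, cells, min_cells = 10) {
  need <- c("barcode", "celltype", "patient", "tissue", "method")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cells <- cells[cells$barcode %in% colnames(counts), , drop = FALSE]
  key <- interaction(cells$celltype, cells$patient, cells$tissue,
                     cells$method, drop = TRUE, sep = "|")
  tab <- table(key)
  keep_groups <- names(tab)[tab >= min_cells]
  if (!length(keep_groups)) stop("no pseudobulk group reaches min_cells",
                                 call. = FALSE)
  if (length(keep_groups) < length(tab))
    warning(length(tab) - length(keep_groups),
            " pseudobulk group(s) below min_cells dropped", call. = FALSE)
  keep <- key %in% keep_groups
  cells <- cells[keep, , drop = FALSE]
  key <- droplevels(key[keep])
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)),
                              j = as.integer(key),
                              x = 1, dims = c(nrow(cells), nlevels(key)))
  pb <- as.matrix(counts[, cells$barcode, drop = FALSE] %*% ind)
  colnames(pb) <- levels(key)
  parts <- do.call(rbind, strsplit(levels(key), "|", fixed = TRUE))
  groups <- tibble::tibble(group = levels(key),
                           celltype = parts[, 1], patient = parts[, 2],
                           tissue = parts[, 3], method = parts[, 4],
                           n_cells = as.integer(tab[levels(key)]))
  structure(list(matrix = pb, groups = groups),
            class = "pairseq_pseudobulk")
}

#' @export
print.pairseq_pseudobulk <- function(x, ...) {
  cat("<pairseq_pseudobulk> ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " groups\n", sep = "")
  invisible(x)
}

#' Log-normalize pseudobulk columns
#'
#' `log1p` of counts scaled to the median column sum; the normalization used
#' for clustering, variable-gene ranking and PCA on pseudobulk profiles.
#'
#' @param pb A `pairseq_pseudobulk` or a plain genes x samples matrix.
#' @return A genes x samples matrix.
#' @export
normalize_pseudobulk <- function(pb) {
  m <- if (inherits(pb, "pairseq_pseudobulk")) pb$matrix else as.matrix(pb)
  cs <- colSums(m)
  med <- stats::median(cs[cs > 0])
  log1p(sweep(m, 2, ifelse(cs > 0, med / cs, 0), "*"))
}

#' Negative-binomial pseudobulk differential expression
#'
#' Per gene, fits a negative-binomial log-linear model with library-size
#' offsets (log column sums). The per-gene dispersion is estimated by
#' moment matching on the Poisson-fit residuals (floored at 1e-8), then
#' shrunk halfway (on the log scale) toward a lowess mean-dispersion trend;
#' the contrast coefficient is tested with a Wald t statistic on the
#' residual degrees of freedom and p-values are BH-adjusted across tested
#' genes. All-zero genes are excluded.
#'
#' @param pb A `pairseq_pseudobulk` object.
#' @param contrast Character triple `c(factor, levelA, levelB)`: the tested
#'   factor and the two levels (log2 fold-change is A over B).
#' @param covariates Character vector of group columns entered as fixed
#'   covariates (e.g. `"patient"` for a paired design).
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return A tibble of class `pairseq_de`: `gene`, `base_mean`, `log2fc`,
#'   `p`, `padj`, `significant`, `direction`.
#' @export
nb_differential_expression <- function(pb, contrast, covariates = character(),
                                       alpha = 0.05) {
  stopifnot(inherits(pb, "pairseq_pseudobulk"), length(contrast) == 3)
  g <- pb$groups
  fac <- contrast[1]
  if (!fac %in% names(g)) stop("unknown contrast factor: ", fac, call. = FALSE)
  sel <- g[[fac]] %in% contrast[2:3]
  g <- g[sel, , drop = FALSE]
  y <- pb$matrix[, sel, drop = FALSE]
  if (sum(g[[fac]] == contrast[2]) < 2 || sum(g[[fac]] == contrast[3]) < 2)
    stop("need >= 2 samples per contrast level", call. = FALSE)
  g$..contrast <- factor(g[[fac]], levels = c(contrast[3], contrast[2]))
  fml <- stats::as.formula(paste(
    "~", paste(c(covariates, "..contrast"), collapse = " + ")))
  x <- stats::model.matrix(fml, data = g)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("collinear design; aliased: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  off <- log(colSums(y))
  nonzero <- rowSums(y) > 0
  yy <- y[nonzero, , drop = FALSE]
  res <- nb_fit_genes(yy, x, off)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$padj) & res$padj < alpha
  res$direction <- ifelse(res$log2fc > 0, "up", ifelse(res$log2fc < 0,
                                                       "down", "none"))
  out <- tibble::as_tibble(res)
  attr(out, "contrast") <- contrast
  attr(out, "n_samples") <- nrow(g)
  class(out) <- c("pairseq_de", class(out))
  out
}

# Vectorised per-gene NB fitting machinery.
nb_fit_genes <- function(y, x, off) {
  n <- ncol(y); p <- ncol(x)
  ngene <- nrow(y)
  disp_mom <- numeric(ngene)
  mu_p <- matrix(0, ngene, n)
  # Poisson fits for moment dispersion
  for (i in seq_len(ngene)) {
    f <- suppressWarnings(stats::glm.fit(x, y[i, ], offset = off,
                                         family = stats::poisson()))
    mu <- f$fitted.values
    mu_p[i, ] <- mu
    a <- sum((y[i, ] - mu)^2 - mu) / sum(mu^2)
    disp_mom[i] <- max(a * n / max(n - p, 1), 1e-8)
  }
  base_mean <- rowMeans(sweep(y, 2, exp(off - mean(off)), "/"))
  lx <- log(base_mean + 1e-8)
  trend <- stats::lowess(lx, log(disp_mom), f = 0.5)
  tr <- stats::approx(trend$x, trend$y, xout = lx, rule = 2)$y
  disp <- exp((log(disp_mom) + tr) / 2)   # halfway shrink, log scale
  disp <- pmax(disp, 1e-8)
  coef_j <- ncol(x)                        # contrast is the last column
  est <- se <- pval <- numeric(ngene)
  df <- max(n - p, 1)
  for (i in seq_len(ngene)) {
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    f <- suppressWarnings(stats::glm.fit(x, y[i, ], offset = off,
                                         family = fam,
                                         mustart = pmax(mu_p[i, ], 1e-4)))
    b <- f$coefficients[coef_j]
    # Wald: covariance from the weighted design
    wx <- sqrt(f$weights) * x
    xtx_inv <- tryCatch(chol2inv(chol(crossprod(wx))), error = function(e) NULL)
    if (is.null(xtx_inv) || !is.finite(b)) {
      est[i] <- 0; se[i] <- NA; pval[i] <- 1
      next
    }
    s <- sqrt(xtx_inv[coef_j, coef_j])
    est[i] <- b
    se[i] <- s
    tstat <- b / s
    pval[i] <- 2 * stats::pt(-abs(tstat), df = df)
  }
  data.frame(gene = rownames(y), base_mean = base_mean,
             log2fc = est / log(2), se = se / log(2),
             dispersion = disp, p = pval)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @method tidy pairseq_de
#' @export
tidy.pairseq_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in%
    c("gene", "base_mean", "log2fc", "se", "p", "padj", "significant",
      "direction")])
}

#' @method glance pairseq_de
#' @export
glance.pairseq_de <- function(x, ...) {
  tibble::tibble(contrast = paste(attr(x, "contrast"), collapse = ":"),
                 n_genes = nrow(x),
                 n_samples = attr(x, "n_samples"),
                 n_significant = sum(x$significant),
                 n_up = sum(x$significant & x$direction == "up"),
                 n_down = sum(x$significant & x$direction == "down"))
}

#' DEG-overlap concordance against a null expectation
#'
#' The expected chance overlap of two DEG lists is
#' `(|A|/n_A) * (|B|/n_B) * |universe|`; the enrichment ratio is
#' observed / expected.
#'
#' @param degs_a,degs_b Character gene sets (subsets of `universe`).
#' @param n_a,n_b Number of genes tested in each comparison.
#' @param universe Character vector: the shared gene universe.
#' @return A tibble: `observed`, `expected`, `ratio`.
#' @examples
#' deg_overlap_concordance(paste0("g", 1:10), 100, paste0("g", 6:25), 100,
#'                         paste0("g", 1:100))
#' @export
deg_overlap_concordance <- function(degs_a, n_a, degs_b, n_b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (n_a < 1 || n_b < 1) stop("n_a and n_b must be >= 1", call. = FALSE)
  degs_a <- intersect(degs_a, universe)
  degs_b <- intersect(degs_b, universe)
  obs <- length(intersect(degs_a, degs_b))
  exp_ <- (length(degs_a) / n_a) * (length(degs_b) / n_b) * length(universe)
  tibble::tibble(observed = obs, expected = exp_,
                 ratio = if (exp_ > 0) obs / exp_ else NA_real_)
}

#' Top variable genes of a pseudobulk matrix
#'
#' Ranks genes by the variance of their log-normalized pseudobulk
#' expression and returns the top `ceiling(fraction * n)`, ties broken by
#' gene ID.
#'
#' @param pb A `pairseq_pseudobulk` or plain matrix.
#' @param fraction Fraction in (0, 1\] (default 0.05).
#' @return Character vector of gene IDs.
#' @export
top_variable_genes <- function(pb, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  m <- normalize_pseudobulk(pb)
  if (nrow(m) < 20) stop("need >= 20 genes", call. = FALSE)
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord[seq_len(ceiling(fraction * nrow(m)))]]
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Ward linkage (`ward.D2`) on Euclidean
#' distances between sample profiles.
#'
#' @param x Samples x genes numeric matrix (>= 2 samples, no NaN).
#' @return An `hclust` object.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' PCA on the level-1 marker panel
#'
#' Centred PCA of normalized pseudobulk profiles restricted to the 39-gene
#' level-1 marker panel (>= 30 panel genes must be present); loadings are
#' sign-fixed for determinism.
#'
#' @param pb_norm Genes x samples normalized pseudobulk matrix.
#' @param panel Character vector of panel gene IDs.
#' @param n_pcs Components to keep (default 4).
#' @return A list: `scores`, `loadings`, `variance_fraction`.
#' @export
marker_gene_pca <- function(pb_norm, panel, n_pcs = 4) {
  if (ncol(pb_norm) < 3) stop("need >= 3 samples", call. = FALSE)
  found <- intersect(panel, rownames(pb_norm))
  if (length(found) < 30)
    stop("fewer than 30 panel genes present (", length(found), ")",
         call. = FALSE)
  if (length(found) < length(panel))
    message(length(panel) - length(found), " panel gene(s) missing")
  x <- t(pb_norm[found, , drop = FALSE])
  fit <- pca_fit(x, min(n_pcs, nrow(x) - 1L, ncol(x)))
  tot <- sum(apply(x, 2, stats::var))
  list(scores = fit$scores, loadings = fit$rotation,
       variance_fraction = fit$sdev^2 / tot)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric tail test per set, BH-adjusted across sets.
#' Sets are intersected with the universe first; empty sets are skipped
#' with a warning.
#'
#' @param degs Character DEG set.
#' @param universe Character gene universe.
#' @param sets Named list of character gene sets.
#' @return A tibble: `set`, `n_set`, `n_overlap`, `p`, `padj`.
#' @export
gene_set_enrichment <- function(degs, universe, sets) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  degs <- intersect(degs, universe)
  out <- purrr::imap(sets, function(s, nm) {
    s <- intersect(s, universe)
    if (!length(s)) {
      warning("set ", nm, " empty after intersection: skipped", call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(degs, s))
    tibble::tibble(set = nm, n_set = length(s), n_overlap = k,
                   p = stats::phyper(k - 1, length(s),
                                     length(universe) - length(s),
                                     length(degs), lower.tail = FALSE))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res$padj <- stats::p.adjust(res$p, method = "BH")
  res
}
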