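#' Genome-ordered windowed relative expression against a reference
#'
#' For every query cell, computes per-gene residuals versus the mean log
#' expression of a non-cancerous reference (matched Normal epithelial cells
#' in practice), smooths them with a centred moving average of odd width
#' `window` within each chromosome (truncated at chromosome edges), and
#' clips the result at `clip_sd` robust standard deviations of the
#' reference's own smoothed residual distribution. `window = 1` reproduces
#' the unsmoothed per-gene differences.
#'
#' @param query Normalized genes x cells matrix (query cells).
#' @param reference Normalized genes x cells matrix (>= 20 reference cells).
#' @param genes Gene table with `chromosome` and `start`.
#' @param window Odd positive smoothing width in genes (default 101).
#' @param clip_sd Robust-SD clip multiple (default 3).
#' @return A list: `values` (genes x query cells, genome order), `genes`
#'   (the ordered gene tibble used), `clip` (the absolute clip bound), and
#'   the reference's per-window smoothed-residual moments
#'   `ref_window_mean` / `ref_window_sd` for [scale_standardize()].
#' @export
relative_expression <- function(query, reference, genes, window = 101,
                                clip_sd = 3) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd", call. = FALSE)
  if (ncol(reference) < 20)
    stop("need at least 20 reference cells", call. = FALSE)
  genes <- validate_gene_table(genes)
  genes <- genes[genes$gene_id %in% rownames(query) &
                   genes$gene_id %in% rownames(reference), , drop = FALSE]
  tab <- table(genes$chromosome)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("excluding chromosome(s) with < 3 genes: ",
            paste(small, collapse = ", "), call. = FALSE)
    genes <- genes[!genes$chromosome %in% small, , drop = FALSE]
  }
  ord <- order(genes$chromosome, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  q <- as.matrix(query[genes$gene_id, , drop = FALSE])
  r <- as.matrix(reference[genes$gene_id, , drop = FALSE])
  ref_mean <- rowMeans(r)
  smooth_by_chrom <- function(m) {
    out <- m
    for (ch in unique(genes$chromosome)) {
      idx <- which(genes$chromosome == ch)
      out[idx, ] <- running_mean(m[idx, , drop = FALSE], window)
    }
    out
  }
  qs <- smooth_by_chrom(q - ref_mean)
  rs <- smooth_by_chrom(r - ref_mean)
  rsd <- stats::mad(as.vector(rs))
  clip <- if (rsd > 0) clip_sd * rsd else Inf
  qs[qs > clip] <- clip
  qs[qs < -clip] <- -clip
  ref_mean <- rowMeans(rs)
  ref_sd <- sqrt(rowVars_fast(rs))
  list(values = qs, genes = genes, clip = clip,
       ref_window_mean = ref_mean, ref_window_sd = ref_sd)
}

# Centred moving average down columns with truncated edge windows.
running_mean <- function(m, window) {
  n <- nrow(m)
  if (window == 1 || n == 1) return(m)
  h <- (window - 1) / 2
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Standardize windowed values and scale into \[-1, 1\]
#'
#' Values are z-standardized per gene-window, then divided by the global
#' maximum absolute standardized value, so the output lies in \[-1, 1\] with
#' at least one entry at +/-1 unless the input is constant (all zeros are
#' then returned). By default the per-window moments come from the cells of
#' `values` themselves; passing the non-cancerous reference's window
#' moments (`center`, `scale`, as returned by [relative_expression()])
#' standardizes each fold-change against the reference's own spread, which
#' is what [cnv_call()] uses so that an aberrant cell's deviation is not
#' divided away by other aberrant cells.
#'
#' @param values Genes x cells matrix of windowed relative expression.
#' @param center,scale Optional per-window reference moments.
#' @return A matrix of the same shape in \[-1, 1\].
#' @export
scale_standardize <- function(values, center = NULL, scale = NULL) {
  if (!length(values)) stop("empty input", call. = FALSE)
  values <- as.matrix(values)
  mu <- center %||% rowMeans(values)
  sd <- scale %||% sqrt(rowVars_fast(values))
  z <- (values - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  mx <- max(abs(z))
  if (mx == 0) return(z)
  z / mx
}

#' Per-cell CNV score
#'
#' The mean of squared scaled windowed values: a cell with no copy-number
#' signal scores 0, a cell at the clip everywhere scores 1.
#'
#' @param values Numeric vector in \[-1, 1\], or a genes x cells matrix
#'   (scores are computed per column).
#' @return A non-negative scalar (or per-cell named vector) in \[0, 1\].
#' @examples
#' cnv_score(c(0.5, -0.5, 1, 0))  # 0.375
#' @export
cnv_score <- function(values) {
  if (!length(values)) stop("empty CNV profile", call. = FALSE)
  if (is.matrix(values)) return(colMeans(values^2))
  mean(values^2)
}

#' Quintile-rule malignant cell classification
#'
#' A cell is flagged malignant when it is epithelial, its CNV score reaches
#' the top quintile (>= 80th percentile) and its annotation score falls in
#' the bottom quintile (<= 20th percentile), with percentiles computed over
#' the epithelial Tumor cells of the same patient and method
#' (nearest-rank definition; boundary cells are kept by the >=/<= rule).
#' Strata with fewer than 5 epithelial cells are skipped with a warning.
#'
#' @param scores Tibble with `barcode`, `cnv_score`, `annotation_score`,
#'   `epithelial` (logical), `patient`, `method`.
#' @return The input with `malignant` (logical) appended.
#' @export
classify_malignant <- function(scores) {
  need <- c("barcode", "cnv_score", "annotation_score", "epithelial",
            "patient", "method")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  scores$malignant <- FALSE
  epi <- which(scores$epithelial)
  key <- interaction(scores$patient[epi], scores$method[epi], drop = TRUE)
  for (s in levels(key)) {
    idx <- epi[key == s]
    if (length(idx) < 5) {
      warning("stratum ", s, " has < 5 epithelial cells: skipped",
              call. = FALSE)
      next
    }
    hi_cnv <- nearest_rank(scores$cnv_score[idx], 0.8)
    lo_ann <- nearest_rank(scores$annotation_score[idx], 0.2)
    scores$malignant[idx] <- scores$cnv_score[idx] >= hi_cnv &
      scores$annotation_score[idx] <= lo_ann
  }
  scores
}

#' End-to-end CNV profiling and malignancy calling
#'
#' Convenience wrapper: computes windowed relative expression for Tumor
#' epithelial query cells against matched Normal epithelial reference cells,
#' scales, scores and applies the quintile malignancy rule per
#' patient x method stratum.
#'
#' @inheritParams relative_expression
#' @param query_meta Tibble (`barcode`, `patient`, `method`,
#'   `annotation_score`) aligned with the query columns.
#' @return A tibble: `barcode`, `patient`, `method`, `cnv_score`,
#'   `annotation_score`, `malignant`.
#' @export
cnv_call <- function(query, reference, genes, query_meta, window = 101,
                     clip_sd = 3) {
  re <- relative_expression(query, reference, genes, window, clip_sd)
  # per-cell centering removes library-depth-driven global shifts before
  # standardizing each window against the reference spread
  v <- sweep(re$values, 2, colMeans(re$values))
  sc <- cnv_score(scale_standardize(v, center = 0 * re$ref_window_mean,
                                    scale = re$ref_window_sd))
  tab <- tibble::tibble(barcode = colnames(query), cnv_score = as.numeric(sc))
  tab <- dplyr::left_join(tab, query_meta, by = "barcode")
  tab$epithelial <- TRUE
  classify_malignant(tab)[, c("barcode", "patient", "method", "cnv_score",
                              "annotation_score", "malignant")]
}
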