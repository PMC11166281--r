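# Internal numerical helpers shared across modules.

#' @importFrom Matrix colSums rowSums t readMM sparseMatrix
#' @importFrom methods as is
#' @import tibble
NULL

# Principal components computed from whichever Gram matrix is smaller.
# x: observations x features (dense or sparse). Returns scores, rotation,
# center and sdev; rotation columns are sign-fixed so the largest-magnitude
# loading is positive (deterministic orientation).
pca_fit <- function(x, n_pcs) {
  sparse <- methods::is(x, "sparseMatrix")
  n <- nrow(x)
  p <- ncol(x)
  ctr <- if (sparse) Matrix::colMeans(x) else colMeans(x <- as.matrix(x))
  n_pcs <- min(n_pcs, n - 1L, p)
  if (n_pcs < 1L) stop("too few observations or features for PCA", call. = FALSE)
  if (n <= p && !sparse) {
    xc <- sweep(x, 2, ctr)
    g <- tcrossprod(xc)                       # n x n
    eg <- eigen(g, symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(n_pcs)], 0)
    d <- sqrt(ev)
    u <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    rot <- crossprod(xc, u)                   # p x k, columns = V * d
    rot <- sweep(rot, 2, ifelse(d > 0, d, 1), "/")
  } else {
    # feature-side Gram of the centred matrix, without densifying x
    g <- as.matrix(Matrix::crossprod(x)) - n * outer(ctr, ctr)
    eg <- eigen(g, symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(n_pcs)], 0)
    d <- sqrt(ev)
    rot <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
  }
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  fit <- list(rotation = rot, center = ctr,
              sdev = d / sqrt(max(n - 1, 1)))
  fit$scores <- pca_project(x, fit)
  fit
}

# Project observations (rows) into an existing PC space without
# densifying a sparse input.
pca_project <- function(x, fit) {
  s <- as.matrix(x %*% fit$rotation)
  sweep(s, 2, as.vector(fit$center %*% fit$rotation))
}

# Blocked brute-force k nearest neighbours (Euclidean).
# Returns list(index, dist) of n_query x k matrices.
knn_search <- function(query, ref, k, block = 2000L) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (k > nrow(ref)) stop("k exceeds the number of reference points", call. = FALSE)
  rn2 <- rowSums(ref^2)
  n <- nrow(query)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(d2))) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, dist = dst)
}

# Nearest-rank percentile: smallest value with at least p*n observations <= it.
nearest_rank <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

# Dirichlet draw via gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Fixed-format numeric TSV writer: 6 significant digits, byte-stable.
write_num_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(signif(df[[j]], 6), digits = 6, format = "g")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
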