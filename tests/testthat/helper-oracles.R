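# Independent brute-force oracles and tiny fixture builders.

# Literal median/MAD filter: recompute thresholds from first principles.
oracle_mad_filter <- function(values, nmads = 3, log_scale = FALSE,
                              cap = NULL, type = "both") {
  v <- if (log_scale) log1p(values) else values
  ok <- is.finite(v)
  med <- median(v[ok])
  md <- 1.4826 * median(abs(v[ok] - med))
  lo <- med - nmads * md
  hi <- med + nmads * md
  if (log_scale) { lo <- expm1(lo); hi <- expm1(hi) }
  if (type == "upper") lo <- -Inf
  if (type == "lower") hi <- Inf
  if (!is.null(cap) && type != "lower") hi <- min(hi, cap)
  keep <- values >= lo & values <= hi
  keep[!is.finite(values)] <- FALSE
  keep
}

# O(n^2) textbook silhouette.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p by enumerating all tables with fixed margins.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by enumeration.
oracle_hyper_p <- function(k, K, N, n) {
  support <- max(0, n - (N - K)):min(n, K)
  sum(dhyper(support[support >= k], K, N - K, n))
}

# Small simulation parameters for fast unit tests.
tiny_params <- function(...) {
  defaults <- list(
    n_patients = 2, cells_per_sample = 300, n_genes = 600,
    n_mito = 10, stress_n = 20,
    cnv_segments = list(
      list(chromosome = "chr2", start = 6, length = 40, fold = 2),
      list(chromosome = "chr5", start = 6, length = 40, fold = 0.5)))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_params, defaults)
}

# Tiny deterministic count matrix with dimnames.
toy_counts <- function(nr = 6, nc = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, 3), nr, nc,
              dimnames = list(sprintf("g%02d", seq_len(nr)),
                              sprintf("bc%02d", seq_len(nc))))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
}

toy_gene_table <- function(ids, mito = character(0)) {
  tibble::tibble(gene_id = ids, symbol = ids,
                 chromosome = "chr1",
                 start = seq_along(ids) * 100L,
                 is_mito = ids %in% mito)
}
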