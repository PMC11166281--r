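#' Ligand-receptor pair database
#'
#' Validates a ligand-receptor table. Multi-subunit ligands or receptors
#' list their subunits semicolon-separated; subunit expression combines with
#' a geometric mean (AND logic).
#'
#' @param pairs Tibble with `ligand`, `receptor`, `pathway` columns.
#' @return The validated tibble with a `pair` identifier column.
#' @export
lr_database <- function(pairs) {
  need <- c("ligand", "receptor", "pathway")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stop("ligand/receptor entries must be non-empty", call. = FALSE)
  if (any(!nzchar(pairs$pathway)))
    stop("pathway labels must be non-empty", call. = FALSE)
  pairs <- tibble::as_tibble(pairs)
  pairs$pair <- paste(pairs$ligand, pairs$receptor, sep = "->")
  pairs
}

#' Level-3 cell types eligible for interactome analysis
#'
#' Keeps classified level-3 labels with at least `min_cells` cells across
#' the compared datasets; unclassified cells never count.
#'
#' @param annot [annotate_cells()] output (or any tibble with `level`,
#'   `label`, `unclassified`).
#' @param level Annotation level (default 3).
#' @param min_cells Minimum total cells (default 500).
#' @return Character vector of eligible type labels (sorted).
#' @export
eligible_celltypes <- function(annot, level = 3, min_cells = 500) {
  a <- annot[annot$level == level & !annot$unclassified, , drop = FALSE]
  tab <- table(a$label)
  out <- sort(names(tab)[tab >= min_cells])
  if (length(out) < 2)
    stop("fewer than 2 eligible cell types", call. = FALSE)
  out
}

# Mean normalized expression of each needed gene in each type; genes absent
# from the matrix get NA. Returns genes x types matrix.
type_mean_expr <- function(expr, types, genes_needed) {
  lv <- sort(unique(types))
  ind <- Matrix::sparseMatrix(i = seq_along(types),
                              j = match(types, lv), x = 1,
                              dims = c(length(types), length(lv)))
  ind <- sweep(as.matrix(ind), 2, table(types)[lv], "/")
  present <- intersect(genes_needed, rownames(expr))
  mm <- as.matrix(expr[present, , drop = FALSE] %*% ind)
  out <- matrix(NA_real_, length(genes_needed), length(lv),
                dimnames = list(genes_needed, lv))
  out[present, ] <- mm
  out
}

# Geometric-mean complex expression; NA (absent subunit) -> NA.
complex_mean <- function(mean_mat, complex_str) {
  subs <- strsplit(complex_str, ";", fixed = TRUE)[[1]]
  if (!all(subs %in% rownames(mean_mat))) return(rep(NA_real_, ncol(mean_mat)))
  m <- mean_mat[subs, , drop = FALSE]
  exp(colMeans(log(pmax(m, 0) + 1e-300)))
}

#' Ligand-receptor interaction strengths between cell types
#'
#' For every ordered (sender, receiver) type pair and every
#' ligand-receptor pair, strength = mean ligand expression in the sender
#' times mean receptor expression in the receiver (geometric means over
#' subunits). Pairs with an absent subunit are skipped with a warning and a
#' strength of 0.
#'
#' @param expr Normalized genes x cells matrix.
#' @param types Character vector: the cell type of each column of `expr`.
#' @param lrdb A [lr_database()] table.
#' @param eligible Character vector of types to include (default: all in
#'   `types`).
#' @return A tibble of class `pairseq_interactome` edges: `sender`,
#'   `receiver`, `pair`, `pathway`, `strength`.
#' @export
interaction_strength <- function(expr, types, lrdb, eligible = NULL) {
  lrdb <- lr_database(lrdb)
  eligible <- eligible %||% sort(unique(types))
  keep <- types %in% eligible
  expr <- expr[, keep, drop = FALSE]
  types <- types[keep]
  genes_needed <- unique(unlist(strsplit(c(lrdb$ligand, lrdb$receptor), ";")))
  mm <- type_mean_expr(expr, types, genes_needed)
  lv <- colnames(mm)
  edges <- vector("list", nrow(lrdb))
  for (i in seq_len(nrow(lrdb))) {
    lmean <- complex_mean(mm, lrdb$ligand[i])
    rmean <- complex_mean(mm, lrdb$receptor[i])
    if (all(is.na(lmean)) || all(is.na(rmean))) {
      warning("pair ", lrdb$pair[i], " has no gene present: skipped",
              call. = FALSE)
      next
    }
    lmean[is.na(lmean)] <- 0
    rmean[is.na(rmean)] <- 0
    s <- outer(lmean, rmean)       # sender x receiver
    edges[[i]] <- tibble::tibble(
      sender = rep(lv, times = length(lv)),
      receiver = rep(lv, each = length(lv)),
      pair = lrdb$pair[i], pathway = lrdb$pathway[i],
      strength = as.vector(s))
  }
  out <- dplyr::bind_rows(edges)
  class(out) <- c("pairseq_interactome", class(out))
  out
}

#' Permutation significance of interactome edges
#'
#' Null strengths are generated by shuffling the cell type labels across
#' cells (within the dataset) `n_perm` times and recomputing every edge.
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; an edge is significant
#' when `p < alpha` and its strength is positive.
#'
#' @inheritParams interaction_strength
#' @param edges Output of [interaction_strength()].
#' @param n_perm Number of permutations (>= 20; default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional permutation seed.
#' @return `edges` with `p` and `significant` columns added.
#' @export
permutation_significance <- function(edges, expr, types, lrdb,
                                     n_perm = 200, alpha = 0.05,
                                     seed = NULL) {
  if (n_perm < 20) stop("n_perm must be >= 20", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lrdb <- lr_database(lrdb)
  eligible <- sort(unique(c(edges$sender, edges$receiver)))
  keep <- types %in% eligible
  expr <- expr[, keep, drop = FALSE]
  types <- types[keep]
  genes_needed <- unique(unlist(strsplit(c(lrdb$ligand, lrdb$receptor), ";")))
  lr_used <- lrdb[lrdb$pair %in% unique(edges$pair), , drop = FALSE]
  count_ge <- numeric(nrow(edges))
  obs <- edges$strength
  edge_key <- paste(edges$pair, edges$sender, edges$receiver)
  for (b in seq_len(n_perm)) {
    pt <- sample(types)
    mm <- type_mean_expr(expr, pt, genes_needed)
    lv <- colnames(mm)
    null_edges <- vector("list", nrow(lr_used))
    for (i in seq_len(nrow(lr_used))) {
      lmean <- complex_mean(mm, lr_used$ligand[i])
      rmean <- complex_mean(mm, lr_used$receptor[i])
      lmean[is.na(lmean)] <- 0
      rmean[is.na(rmean)] <- 0
      s <- outer(lmean, rmean)
      null_edges[[i]] <- tibble::tibble(
        key = paste(lr_used$pair[i], rep(lv, times = length(lv)),
                    rep(lv, each = length(lv))),
        strength = as.vector(s))
    }
    nl <- dplyr::bind_rows(null_edges)
    null_s <- nl$strength[match(edge_key, nl$key)]
    count_ge <- count_ge + (null_s >= obs)
  }
  edges$p <- (1 + count_ge) / (1 + n_perm)
  edges$significant <- edges$p < alpha & edges$strength > 0
  edges
}

#' Incoming and outgoing significant-edge counts per cell type
#'
#' `out(T)` counts significant edges with sender `T`; `in(T)` with receiver
#' `T`. Self-loops count once in each direction, so both column sums equal
#' the total number of significant edges.
#'
#' @param edges Interactome edges with a `significant` column.
#' @return A tibble: `celltype`, `incoming`, `outgoing`.
#' @export
inout_counts <- function(edges) {
  types <- sort(unique(c(edges$sender, edges$receiver)))
  sig <- edges[isTRUE_vec(edges$significant), , drop = FALSE]
  tibble::tibble(
    celltype = types,
    incoming = vapply(types, function(t) sum(sig$receiver == t), 0L,
                      USE.NAMES = FALSE),
    outgoing = vapply(types, function(t) sum(sig$sender == t), 0L,
                      USE.NAMES = FALSE))
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Pathway-level aggregation of interactome edges
#'
#' @param edges Interactome edges (with or without significance).
#' @param significant_only Restrict to significant edges?
#' @return A tibble: `pathway`, `n_edges`, `total_strength`.
#' @export
pathway_aggregate <- function(edges, significant_only = FALSE) {
  e <- edges
  if (significant_only) e <- e[isTRUE_vec(e$significant), , drop = FALSE]
  e |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(n_edges = dplyr::n(),
                     total_strength = sum(.data$strength),
                     .groups = "drop")
}

#' @method tidy pairseq_interactome
#' @export
tidy.pairseq_interactome <- function(x, ...) tibble::as_tibble(unclass(x))
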