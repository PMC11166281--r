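#' Cell-type composition table
#'
#' Counts and proportions of each cell-type label per dataset grouping
#' (tissue x method by default, optionally per patient). Unclassified cells
#' form their own category.
#'
#' @param annot [annotate_cells()] output for one level (or filtered to
#'   one), joined or joinable with `cells` by barcode.
#' @param cells Cell metadata (`barcode`, `patient`, `tissue`, `method`).
#' @param level Annotation level to tabulate.
#' @param by Grouping columns (default `c("tissue", "method")`).
#' @param collapse_below Optional proportion under which labels are
#'   collapsed into `"others"` (display convenience; default `NULL`).
#' @return A tibble: groups, `label`, `n`, `proportion` (sums to 1 per
#'   group).
#' @export
composition_table <- function(annot, cells, level = 1,
                              by = c("tissue", "method"),
                              collapse_below = NULL) {
  a <- annot[annot$level == level, c("barcode", "label", "unclassified")]
  a$label[a$unclassified] <- "unclassified"
  d <- dplyr::inner_join(a, cells, by = "barcode")
  if (!nrow(d)) stop("empty dataset", call. = FALSE)
  out <- d |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), .data$label, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  if (!is.null(collapse_below)) {
    out$label[out$proportion < collapse_below &
                out$label != "unclassified"] <- "others"
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "label")))) |>
      dplyr::summarise(n = sum(.data$n), proportion = sum(.data$proportion),
                       .groups = "drop")
  }
  out
}

#' Tumor / Normal composition transition ratios
#'
#' Ratio of a type's Tumor proportion to its Normal proportion, per
#' matching group (e.g. patient x method). Types absent from Normal get a
#' missing ratio rather than infinity.
#'
#' @param comp_tumor,comp_normal [composition_table()] outputs at the same
#'   level over the same groups.
#' @param by Columns identifying matching groups (default
#'   `c("method", "patient")` intersected with available columns).
#' @return A tibble: groups, `label`, `prop_tumor`, `prop_normal`, `ratio`.
#' @export
transition_ratio <- function(comp_tumor, comp_normal, by = NULL) {
  by <- by %||% setdiff(intersect(names(comp_tumor), names(comp_normal)),
                        c("label", "n", "proportion", "tissue"))
  t_ <- comp_tumor[, c(by, "label", "proportion")]
  n_ <- comp_normal[, c(by, "label", "proportion")]
  names(t_)[names(t_) == "proportion"] <- "prop_tumor"
  names(n_)[names(n_) == "proportion"] <- "prop_normal"
  d <- dplyr::full_join(t_, n_, by = c(by, "label"))
  d$prop_tumor[is.na(d$prop_tumor)] <- 0
  d$ratio <- ifelse(!is.na(d$prop_normal) & d$prop_normal > 0,
                    d$prop_tumor / d$prop_normal, NA_real_)
  d
}

#' Fisher exact contrast of unclassified fractions
#'
#' Two-sided Fisher exact test of the 2x2 table of unclassified versus
#' classified counts in two datasets, with the conditional-MLE odds ratio.
#' Zero-margin tables return `p = 1` and a missing odds ratio.
#'
#' @param a_unclassified,a_total Counts for dataset A.
#' @param b_unclassified,b_total Counts for dataset B.
#' @return A tibble: `odds_ratio`, `p`.
#' @export
unclassified_contrast <- function(a_unclassified, a_total,
                                  b_unclassified, b_total) {
  if (a_unclassified > a_total || b_unclassified > b_total)
    stop("counts exceed totals", call. = FALSE)
  tab <- matrix(c(a_unclassified, a_total - a_unclassified,
                  b_unclassified, b_total - b_unclassified),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(tibble::tibble(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(tab)
  tibble::tibble(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Silhouette widths of annotation labels on an embedding
#'
#' Textbook silhouette with Euclidean distance. Unclassified cells must be
#' excluded by the caller; cells whose label is a singleton get `s = 0` and
#' are flagged.
#'
#' @param embedding Tibble with `barcode`, `dim1`, `dim2` (or a numeric
#'   matrix with rownames).
#' @param labels Character vector aligned with the embedding rows.
#' @return A list: `cells` (tibble `barcode`, `label`, `s`, `singleton`) and
#'   `groups` (per-label `median_s`).
#' @export
silhouette_by_label <- function(embedding, labels) {
  if (is.data.frame(embedding)) {
    bc <- embedding$barcode
    x <- as.matrix(embedding[, c("dim1", "dim2")])
  } else {
    x <- as.matrix(embedding)
    bc <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  if (length(labels) != nrow(x)) stop("labels misaligned", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("need at least 2 labels", call. = FALSE)
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), stats::dist(x))
  s <- sil[, "sil_width"]
  singleton <- labels %in% names(which(table(labels) == 1))
  s[singleton] <- 0
  cells <- tibble::tibble(barcode = bc, label = labels, s = s,
                          singleton = singleton)
  groups <- cells |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), median_s = stats::median(.data$s),
                     .groups = "drop")
  list(cells = cells, groups = groups)
}

#' Per-cell stress-signature expression fraction
#'
#' Fraction of signature genes detected (count > 0) per cell, using the
#' intersection of the signature with the matrix genes as denominator, plus
#' per-sample means.
#'
#' @param counts Sparse count matrix.
#' @param signature Character vector of signature gene IDs.
#' @param cells Optional metadata (`barcode` plus grouping columns) for the
#'   per-group summary.
#' @param by Grouping columns (default `c("method", "tissue")`).
#' @return A list: `cells` (per-cell `fraction`), `groups` (per-group mean),
#'   and `n_signature` (intersection size).
#' @export
signature_fraction <- function(counts, signature, cells = NULL,
                               by = c("method", "tissue")) {
  sig <- intersect(signature, rownames(counts))
  if (!length(sig)) stop("signature does not intersect matrix genes",
                         call. = FALSE)
  frac <- Matrix::colSums(counts[sig, , drop = FALSE] > 0) / length(sig)
  per_cell <- tibble::tibble(barcode = colnames(counts),
                             fraction = as.numeric(frac))
  groups <- NULL
  if (!is.null(cells)) {
    groups <- dplyr::inner_join(per_cell, cells, by = "barcode") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(mean_fraction = mean(.data$fraction),
                       n = dplyr::n(), .groups = "drop")
  }
  list(cells = per_cell, groups = groups, n_signature = length(sig))
}

#' Raw per-cell mitochondrial UMI percentage
#'
#' The same formula as [compute_cell_metrics()]'s `percent_mt`, but
#' contractually applied to the unfiltered matrix (quality signal prior to
#' any QC). Zero-count cells are excluded from group means.
#'
#' @inheritParams signature_fraction
#' @param genes Gene table with `is_mito`.
#' @return A list: `cells` (per-cell `percent_mt`), `groups` (per-group
#'   means over non-empty cells).
#' @export
mito_fraction_raw <- function(counts, genes, cells = NULL,
                              by = c("method", "tissue")) {
  m <- compute_cell_metrics(counts, genes)
  per_cell <- m[, c("barcode", "percent_mt", "zero_count")]
  groups <- NULL
  if (!is.null(cells)) {
    groups <- dplyr::inner_join(per_cell, cells, by = "barcode") |>
      dplyr::filter(!.data$zero_count) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(mean_percent_mt = mean(.data$percent_mt),
                       n = dplyr::n(), .groups = "drop")
  }
  list(cells = per_cell, groups = groups)
}

#' Two-way main-effects ANOVA (Type II)
#'
#' Main-effect F statistics and p-values for two crossed factors, using
#' Type II sums of squares without an interaction term (valid for balanced
#' and unbalanced layouts). A constant response returns `F = 0, p = 1` for
#' both factors.
#'
#' @param data A data frame.
#' @param value Response column name.
#' @param factor_a,factor_b Factor column names (>= 2 levels each).
#' @return A tibble: `term`, `F`, `p`.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  y <- data[[value]]
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need >= 2 levels", call. = FALSE)
  if (stats::var(y) == 0)
    return(tibble::tibble(term = c(factor_a, factor_b), F = c(0, 0),
                          p = c(1, 1)))
  d <- data.frame(y = y, a = fa, b = fb)
  fit <- stats::lm(y ~ a + b, data = d)
  an <- car::Anova(fit, type = 2)
  tibble::tibble(term = c(factor_a, factor_b),
                 F = an[c("a", "b"), "F value"],
                 p = an[c("a", "b"), "Pr(>F)"])
}
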