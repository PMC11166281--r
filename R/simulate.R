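#' Simulation parameters for a paired cell/nucleus cohort
#'
#' Builds the parameter list for [generate_cohort()]. Defaults describe a
#' desk-scale paired lung cohort: four patients, Normal and Tumor tissue,
#' three capture methods (`cell`, `nucleus`, `immune_depleted`), 2,000 genes
#' and ~2,000 cells per sample. The defaults encode the qualitative
#' structures the analysis assumes: strong immune capture bias in whole-cell
#' data versus epithelial dominance in nuclei, near-zero mitochondrial
#' content in nuclei, method-ordered dissociation-stress activation, a
#' nuclear transcript composition shift, a malignant epithelial subclone
#' carrying segmental copy-number changes with partial identity loss, 5%
#' doublets, and patient-level composition noise.
#'
#' @param n_patients Number of patients (each contributes tissue x method samples).
#' @param n_genes Total genes, including `n_mito` mitochondrial genes.
#' @param n_mito Mitochondrial genes (placed on chromosome `MT`).
#' @param cells_per_sample Target cells per (patient x tissue x method) sample.
#' @param markers_per_type,marker_fold Marker genes per leaf type and their
#'   mean fold elevation over other types.
#' @param baseline_props Named list `Normal`/`Tumor` of per-leaf proportions
#'   (each summing to 1). `NULL` for defaults.
#' @param method_bias Named list per method of level-1 capture multipliers.
#' @param libsize_lognormal Named list per method of `c(meanlog, sdlog)`.
#' @param mito_frac Named vector: mean mitochondrial UMI fraction per method.
#' @param stress_activation Named vector: probability a cell activates the
#'   stress program, per method.
#' @param stress_n,stress_fold Stress-program size and fold activation.
#' @param nuclear_shift_sd SD of the per-gene log2 fold-change applied to
#'   nucleus-method cells.
#' @param malignant_frac Fraction of Tumor epithelial cells that are malignant.
#' @param cnv_segments List of `list(chromosome, start, length, fold)` blocks
#'   (`start`/`length` in within-chromosome gene order, `fold > 0`).
#' @param lambda Identity-loss mixing weight for malignant cells (their
#'   expression profile is `(1-lambda)` type + `lambda` flat).
#' @param lambda_spread Relative half-width of the per-cell uniform
#'   heterogeneity around `lambda` (default 0.25).
#' @param tumor_heterogeneity Mean of the mild per-cell identity diffusion
#'   applied to every Tumor cell (uniform on `[0, 2x]`; default 0.15),
#'   emulating the overall heterogeneity increase of tumor tissue.
#' @param doublet_rate Doublet proportion in `[0, 0.5)`.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal hyperparameters of
#'   the per-gene negative-binomial dispersion.
#' @param dirichlet_conc Dirichlet concentration for patient-level
#'   composition noise (larger = less variation between patients).
#' @param patient_effect_sd SD of the per-patient, per-gene log-normal
#'   expression factor.
#' @param n_ref_per_type Reference cells per leaf type for [make_reference()].
#' @param seed Integer seed recorded in the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 4,
                       n_genes = 2000,
                       n_mito = 20,
                       cells_per_sample = 2000,
                       markers_per_type = 12,
                       marker_fold = 8,
                       baseline_props = NULL,
                       method_bias = NULL,
                       libsize_lognormal = NULL,
                       mito_frac = c(cell = 0.112, nucleus = 0.026,
                                     immune_depleted = 0.152),
                       stress_activation = c(cell = 0.20, nucleus = 0.05,
                                             immune_depleted = 0.50),
                       stress_n = 40,
                       stress_fold = 6,
                       nuclear_shift_sd = 0.7,
                       malignant_frac = 0.3,
                       cnv_segments = NULL,
                       lambda = 0.7,
                       lambda_spread = 0.25,
                       tumor_heterogeneity = 0.15,
                       doublet_rate = 0.05,
                       dispersion_meanlog = log(0.3),
                       dispersion_sdlog = 0.25,
                       dirichlet_conc = 50,
                       patient_effect_sd = 0.08,
                       n_ref_per_type = 100,
                       seed = 1L) {
  tree <- celltype_tree()
  leaves <- tree$level3
  if (is.null(baseline_props)) baseline_props <- default_baseline_props()
  if (is.null(method_bias)) {
    method_bias <- list(
      cell = c(Immune = 30, Epithelial = 1, Endothelial = 2, Stroma = 2),
      nucleus = c(Immune = 0.6, Epithelial = 1.3, Endothelial = 1, Stroma = 1),
      immune_depleted = c(Immune = 0.05, Epithelial = 1, Endothelial = 1.6,
                          Stroma = 1.8))
  }
  if (is.null(libsize_lognormal)) {
    libsize_lognormal <- list(cell = c(log(3500), 0.45),
                              nucleus = c(log(2800), 0.45),
                              immune_depleted = c(log(3500), 0.45))
  }
  if (is.null(cnv_segments)) {
    cnv_segments <- list(
      list(chromosome = "chr2", start = 26, length = 150, fold = 2),
      list(chromosome = "chr5", start = 26, length = 150, fold = 0.5))
  }
  p <- list(n_patients = n_patients, n_genes = n_genes, n_mito = n_mito,
            cells_per_sample = cells_per_sample, tree = tree,
            markers_per_type = markers_per_type, marker_fold = marker_fold,
            baseline_props = baseline_props, method_bias = method_bias,
            libsize_lognormal = libsize_lognormal, mito_frac = mito_frac,
            stress_activation = stress_activation, stress_n = stress_n,
            stress_fold = stress_fold, nuclear_shift_sd = nuclear_shift_sd,
            malignant_frac = malignant_frac, cnv_segments = cnv_segments,
            lambda = lambda, lambda_spread = lambda_spread,
            tumor_heterogeneity = tumor_heterogeneity,
            doublet_rate = doublet_rate,
            dispersion_meanlog = dispersion_meanlog,
            dispersion_sdlog = dispersion_sdlog,
            dirichlet_conc = dirichlet_conc,
            patient_effect_sd = patient_effect_sd,
            n_ref_per_type = n_ref_per_type, seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

#' @rdname sim_params
#' @param params A `sim_params` object to validate.
#' @export
validate_sim_params <- function(params) {
  for (tis in c("Normal", "Tumor")) {
    pr <- params$baseline_props[[tis]]
    if (is.null(pr)) stop("baseline_props must name tissue ", tis, call. = FALSE)
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("baseline_props[", tis, "] must be non-negative and sum to 1",
           call. = FALSE)
    if (!setequal(names(pr), params$tree$level3))
      stop("baseline_props[", tis, "] must cover every leaf type", call. = FALSE)
  }
  if (params$doublet_rate < 0 || params$doublet_rate >= 0.5)
    stop("doublet_rate must be in [0, 0.5)", call. = FALSE)
  if (params$malignant_frac < 0 || params$malignant_frac > 1)
    stop("malignant_frac must be in [0, 1]", call. = FALSE)
  n_per_chrom <- ceiling((params$n_genes - params$n_mito) / 10)
  for (seg in params$cnv_segments) {
    if (seg$fold <= 0) stop("cnv segment fold-changes must be > 0", call. = FALSE)
    if (seg$start < 1 || seg$start + seg$length - 1 > n_per_chrom)
      stop("cnv segment exceeds the genes available on ", seg$chromosome,
           call. = FALSE)
  }
  for (m in c("cell", "nucleus", "immune_depleted")) {
    if (is.na(params$mito_frac[m]) || params$mito_frac[m] < 0 ||
        params$mito_frac[m] > 1)
      stop("mito_frac must give a proportion for method ", m, call. = FALSE)
  }
  params
}

#' The default three-level cell-type hierarchy
#'
#' Twelve leaf types under the four coarse lung compartments
#' (Immune, Epithelial, Endothelial, Stroma).
#'
#' @return A tibble with columns `level1`, `level2`, `level3` (leaf).
#' @export
celltype_tree <- function() {
  tibble::tribble(
    ~level1,       ~level2,              ~level3,
    "Immune",      "Lymphoid",           "T_cell",
    "Immune",      "Lymphoid",           "B_cell",
    "Immune",      "Lymphoid",           "NK_cell",
    "Immune",      "Myeloid",            "Macrophage",
    "Epithelial",  "Alveolar",           "AT1",
    "Epithelial",  "Alveolar",           "AT2",
    "Epithelial",  "Airway",             "Multiciliated",
    "Epithelial",  "Airway",             "Secretory",
    "Endothelial", "Vascular",           "Capillary",
    "Endothelial", "Lymphatic_vessel",   "Lymphatic_EC",
    "Stroma",      "Fibroblast_lineage", "Fibroblast",
    "Stroma",      "Muscle",             "Smooth_muscle")
}

default_baseline_props <- function() {
  list(
    Normal = c(T_cell = 0.06, B_cell = 0.02, NK_cell = 0.02, Macrophage = 0.05,
               AT1 = 0.22, AT2 = 0.22, Multiciliated = 0.10, Secretory = 0.06,
               Capillary = 0.10, Lymphatic_EC = 0.03,
               Fibroblast = 0.09, Smooth_muscle = 0.03),
    Tumor = c(T_cell = 0.10, B_cell = 0.04, NK_cell = 0.01, Macrophage = 0.05,
              AT1 = 0.10, AT2 = 0.08, Multiciliated = 0.08, Secretory = 0.36,
              Capillary = 0.06, Lymphatic_EC = 0.02,
              Fibroblast = 0.08, Smooth_muscle = 0.02))
}

# Gene-level scaffolding shared by cohort and reference generation: gene
# table, per-type expression profiles, dispersions, stress set, shifts.
sim_gene_model <- function(params) {
  tree <- params$tree
  leaves <- tree$level3
  n_nuc <- params$n_genes - params$n_mito
  n_per_chrom <- ceiling(n_nuc / 10)
  chrom <- rep(paste0("chr", 1:10), each = n_per_chrom)[seq_len(n_nuc)]
  genes <- tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(params$n_genes)),
    symbol = sprintf("G%04d", seq_len(params$n_genes)),
    chromosome = c(chrom, rep("MT", params$n_mito)),
    start = c(unlist(lapply(split(seq_len(n_nuc), chrom),
                            function(i) seq_along(i) * 10000L),
                     use.names = FALSE)[order(order(chrom))],
              seq_len(params$n_mito) * 100L),
    is_mito = c(rep(FALSE, n_nuc), rep(TRUE, params$n_mito)))
  # recompute start deterministically in file order
  genes$start <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                            FUN = seq_along) * 10000L

  nuc_idx <- which(!genes$is_mito)
  base <- stats::rgamma(params$n_genes, shape = 0.6, rate = 0.6)
  base <- pmax(base, 1e-4)

  # marker assignment: disjoint random blocks of non-mito genes per leaf
  n_mark <- params$markers_per_type * length(leaves)
  marker_pool <- sample(nuc_idx, n_mark)
  marker_of <- rep(NA_character_, params$n_genes)
  marker_list <- split(marker_pool,
                       rep(leaves, each = params$markers_per_type))
  for (lv in leaves) marker_of[marker_list[[lv]]] <- lv

  # stress genes: non-mito, non-marker; quiescent baseline until induced
  stress_idx <- sample(setdiff(nuc_idx, marker_pool), params$stress_n)
  base[stress_idx] <- base[stress_idx] * 0.3

  # per-leaf expression profiles over non-mito genes (normalised later)
  prof <- matrix(base, nrow = params$n_genes, ncol = length(leaves),
                 dimnames = list(genes$gene_id, leaves))
  for (lv in leaves) prof[marker_list[[lv]], lv] <-
    prof[marker_list[[lv]], lv] * params$marker_fold
  # mild correlated structure within level-1 lineages: sibling leaves share
  # a quarter of each other's marker elevation
  for (l1 in unique(tree$level1)) {
    sibs <- tree$level3[tree$level1 == l1]
    if (length(sibs) > 1) {
      for (lv in sibs) {
        others <- setdiff(sibs, lv)
        for (o in others) prof[marker_list[[o]], lv] <-
          prof[marker_list[[o]], lv] * (1 + (params$marker_fold - 1) / 4)
      }
    }
  }
  mito_shape <- stats::rgamma(params$n_mito, shape = 2, rate = 1) + 0.1

  nuclear_shift <- stats::rnorm(params$n_genes, 0, params$nuclear_shift_sd)
  nuclear_shift[genes$is_mito] <- 0

  disp <- stats::rlnorm(params$n_genes, params$dispersion_meanlog,
                        params$dispersion_sdlog)

  cnv_mult <- rep(1, params$n_genes)
  cnv_state <- rep("neutral", params$n_genes)
  for (seg in params$cnv_segments) {
    on_chr <- which(genes$chromosome == seg$chromosome)
    seg_idx <- on_chr[seq(seg$start, seg$start + seg$length - 1)]
    cnv_mult[seg_idx] <- cnv_mult[seg_idx] * seg$fold
    cnv_state[seg_idx] <- ifelse(seg$fold > 1, "gain",
                                 ifelse(seg$fold < 1, "loss", "neutral"))
  }

  gene_truth <- tibble::tibble(
    gene_id = genes$gene_id, marker_of = marker_of,
    stress_set = seq_len(params$n_genes) %in% stress_idx,
    nuclear_shift = nuclear_shift, cnv_state = cnv_state,
    cnv_mult = cnv_mult)

  list(genes = genes, profiles = prof, mito_shape = mito_shape,
       dispersion = disp, gene_truth = gene_truth,
       stress_idx = stress_idx, marker_list = marker_list)
}

# Build the per-cell relative-expression profile matrix for one homogeneous
# group and draw NB counts. mu = libsize * profile.
draw_counts <- function(profile, libsizes, dispersion) {
  draw_counts_mu(profile %o% libsizes, dispersion)
}

draw_counts_mu <- function(mu, dispersion) {
  k <- ncol(mu)
  cnt <- stats::rnbinom(length(mu), size = rep(1 / dispersion, k),
                        mu = as.vector(mu))
  matrix(cnt, nrow = nrow(mu), ncol = k)
}

# Normalise a profile so mito genes sum to mito_frac and the rest to 1-mito.
profile_with_mito <- function(p, is_mito, mito_shape, mito_frac) {
  out <- p
  out[is_mito] <- mito_shape / sum(mito_shape) * mito_frac
  nm <- !is_mito
  out[nm] <- p[nm] / sum(p[nm]) * (1 - mito_frac)
  out
}

#' Generate a paired multi-sample synthetic cohort with ground truth
#'
#' Draws, for every (patient x tissue x method) sample, cell-type counts from
#' a Dirichlet-multinomial (baseline tissue proportions, perturbed per
#' patient, reweighted by method capture bias), log-normal library sizes,
#' and per-gene negative-binomial counts around type-specific expression
#' profiles. Nucleus cells receive the per-gene nuclear shift and the
#' method's mitochondrial fraction; stress-active cells upregulate the
#' stress program; malignant Tumor epithelial cells mix their type profile
#' with a flat profile (identity loss `lambda`) and carry the segmental CNV
#' fold-changes; doublets are spiked per sample at `doublet_rate`.
#'
#' @param params A [sim_params()] object.
#' @param seed Seed; defaults to `params$seed`.
#' @return A list with `counts` (sparse gene x cell matrix), `cells`
#'   (metadata tibble), `genes` (gene table), and `truth` (list with
#'   per-cell `cells`, per-gene `genes`, and per-sample expected proportions
#'   `sample_props`).
#' @export
generate_cohort <- function(params, seed = params$seed) {
  validate_sim_params(params)
  # the gene universe (markers, dispersions, CNV blocks, shifts) is a
  # property of the parameters, so cohort and reference always share it
  set.seed(params$seed)
  gm <- sim_gene_model(params)
  set.seed(seed)
  tree <- params$tree
  leaves <- tree$level3
  methods_ <- c("cell", "nucleus", "immune_depleted")
  patients <- paste0("P", seq_len(params$n_patients))
  is_mito <- gm$genes$is_mito

  pat_fx <- matrix(stats::rlnorm(params$n_patients * params$n_genes, 0,
                                 params$patient_effect_sd),
                   nrow = params$n_genes,
                   dimnames = list(gm$genes$gene_id, patients))

  # patient-level tissue composition (shared across methods)
  pat_props <- list()
  for (pt in patients) for (tis in c("Normal", "Tumor")) {
    bp <- params$baseline_props[[tis]][leaves]
    pat_props[[paste(pt, tis)]] <- rdirichlet1(params$dirichlet_conc * bp)
  }

  flat <- rowMeans(gm$profiles)
  mats <- list(); cell_rows <- list(); prop_rows <- list()
  for (pt in patients) for (tis in c("Normal", "Tumor")) for (mth in methods_) {
    sample_id <- paste(pt, tis, mth, sep = "_")
    bias <- params$method_bias[[mth]][tree$level1]
    w <- pat_props[[paste(pt, tis)]] * bias
    w <- w / sum(w)
    names(w) <- leaves
    n_cells <- params$cells_per_sample
    type_counts <- as.vector(stats::rmultinom(1, n_cells, w))
    names(type_counts) <- leaves
    prop_rows[[sample_id]] <- tibble::tibble(
      sample = sample_id, patient = pt, tissue = tis, method = mth,
      level3 = leaves, expected_prop = as.numeric(w),
      n_drawn = as.integer(type_counts))

    ls_par <- params$libsize_lognormal[[mth]]
    mf <- params$mito_frac[[mth]]
    sub <- list(); meta <- list()
    ci <- 0L
    for (lv in leaves) {
      k <- type_counts[[lv]]
      if (k == 0) next
      l1 <- tree$level1[tree$level3 == lv]
      base_p <- gm$profiles[, lv] * pat_fx[, pt]
      if (mth == "nucleus") base_p <- base_p * 2^gm$gene_truth$nuclear_shift
      stress_on <- stats::runif(k) < params$stress_activation[[mth]]
      malig <- rep(FALSE, k)
      if (tis == "Tumor" && l1 == "Epithelial" && params$malignant_frac > 0)
        malig <- stats::runif(k) < params$malignant_frac
      # per-cell identity-loss severity: malignant cells vary around
      # lambda; every Tumor cell additionally carries a mild identity
      # diffusion (overall tumor heterogeneity)
      sp <- params$lambda_spread
      lam <- ifelse(malig,
                    pmin(params$lambda * stats::runif(k, 1 - sp, 1 + sp),
                         0.95), 0)
      if (tis == "Tumor" && params$tumor_heterogeneity > 0)
        lam <- pmin(lam + stats::runif(k, 0,
                                       2 * params$tumor_heterogeneity), 0.95)
      libs <- stats::rlnorm(k, ls_par[1], ls_par[2])
      mixed <- lam > 0
      for (grp in split(seq_len(k),
                        interaction(stress_on, malig, mixed, drop = TRUE))) {
        p <- base_p
        if (stress_on[grp[1]])
          p[gm$stress_idx] <- p[gm$stress_idx] * params$stress_fold
        if (mixed[grp[1]]) {
          pm <- outer(p, 1 - lam[grp]) + outer(flat, lam[grp])
          if (malig[grp[1]]) pm <- pm * gm$gene_truth$cnv_mult
          pm <- apply(pm, 2, profile_with_mito, is_mito = is_mito,
                      mito_shape = gm$mito_shape, mito_frac = mf)
          sub[[length(sub) + 1L]] <- draw_counts_mu(
            pm * rep(libs[grp], each = nrow(pm)), gm$dispersion)
        } else {
          p <- profile_with_mito(p, is_mito, gm$mito_shape, mf)
          sub[[length(sub) + 1L]] <- draw_counts(p, libs[grp], gm$dispersion)
        }
        meta[[length(meta) + 1L]] <- tibble::tibble(
          level3 = lv, stress = stress_on[grp], malignant = malig[grp],
          lambda = lam[grp])
      }
      ci <- ci + k
    }
    m <- do.call(cbind, sub)
    md <- dplyr::bind_rows(meta)
    bc <- sprintf("%s.c%05d", sample_id, seq_len(ncol(m)))
    dimnames(m) <- list(gm$genes$gene_id, bc)
    md$barcode <- bc
    md$patient <- pt; md$tissue <- tis; md$method <- mth
    md$sample <- sample_id
    md$doublet <- FALSE
    md$parent1 <- NA_character_; md$parent2 <- NA_character_
    sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
    if (params$doublet_rate > 0) {
      sp <- spike_doublets(sm, md, params$doublet_rate)
      sm <- sp$counts; md <- sp$truth
    }
    mats[[sample_id]] <- sm
    cell_rows[[sample_id]] <- md
  }

  counts <- do.call(cbind, mats)
  rm(mats); invisible(gc(FALSE))
  truth_cells <- dplyr::bind_rows(cell_rows)
  truth_cells <- dplyr::left_join(truth_cells,
                                  tree[, c("level3", "level2", "level1")],
                                  by = "level3")
  cells <- truth_cells[, c("barcode", "patient", "tissue", "method", "sample")]
  list(counts = validate_counts(counts), cells = cells, genes = gm$genes,
       truth = list(cells = truth_cells, genes = gm$gene_truth,
                    sample_props = dplyr::bind_rows(prop_rows)))
}

#' Spike synthetic doublets into a count matrix
#'
#' Appends `round(rate * n / (1 - rate))` new barcodes, each the entrywise
#' sum of two distinct, uniformly chosen real cells, so that doublets make
#' up `rate` of the resulting matrix. Original columns are untouched.
#'
#' @param counts Sparse count matrix (genes x cells).
#' @param truth Per-cell truth/metadata tibble with a `barcode` column
#'   matching `counts` columns.
#' @param rate Doublet proportion in `[0, 0.5)`.
#' @return A list with the augmented `counts` and `truth` (spiked rows have
#'   `doublet = TRUE` and record both parents).
#' @export
spike_doublets <- function(counts, truth, rate) {
  if (rate < 0 || rate >= 0.5)
    stop("doublet rate must be in [0, 0.5)", call. = FALSE)
  n <- ncol(counts)
  n_dbl <- round(rate * n / (1 - rate))
  if (n_dbl == 0) return(list(counts = counts, truth = truth))
  p1 <- sample.int(n, n_dbl, replace = TRUE)
  p2 <- vapply(p1, function(i) sample(setdiff(seq_len(n), i), 1L), 1L)
  dbl <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  bc <- sprintf("%s.dbl%04d", sub("\\.c[0-9]+$", "", colnames(counts)[1]),
                seq_len(n_dbl))
  colnames(dbl) <- bc
  new_rows <- truth[p1, , drop = FALSE]
  new_rows$barcode <- bc
  new_rows$doublet <- TRUE
  new_rows$parent1 <- colnames(counts)[p1]
  new_rows$parent2 <- colnames(counts)[p2]
  # a doublet's recorded type is its first parent's; second parent kept too
  new_rows$level3_parent2 <- truth$level3[p2]
  if (!"level3_parent2" %in% names(truth)) truth$level3_parent2 <- NA_character_
  list(counts = cbind(counts, dbl), truth = dplyr::bind_rows(truth, new_rows))
}

#' Build a hierarchical reference atlas from the generative model
#'
#' Reference cells are drawn from the same type-specific expression model as
#' [generate_cohort()] but with no method bias, stress activation, CNVs or
#' nuclear shift. Per-type markers are the genes with the largest mean log
#' fold-change versus all other types; the level-1 panel collects the top
#' markers of the four coarse compartments (39 genes).
#'
#' @param params A [sim_params()] object.
#' @param n_ref_per_type Reference cells per leaf type.
#' @param seed Seed; defaults to `params$seed + 1000` so reference cells are
#'   not the query cells.
#' @return A `reference_atlas`: list with normalized `profiles`
#'   (genes x reference cells), `labels` tibble, the label `tree`, per-type
#'   `markers`, and the 39-gene level-1 `panel`.
#' @export
make_reference <- function(params, n_ref_per_type = params$n_ref_per_type,
                           seed = params$seed + 1000L) {
  if (n_ref_per_type < 1) stop("n_ref_per_type must be >= 1", call. = FALSE)
  validate_sim_params(params)
  set.seed(params$seed)           # same gene model as the cohort
  gm <- sim_gene_model(params)
  set.seed(seed)
  tree <- params$tree
  leaves <- tree$level3
  ls_par <- params$libsize_lognormal[["cell"]]
  mf <- params$mito_frac[["cell"]]
  mats <- list(); labs <- list()
  for (lv in leaves) {
    p <- profile_with_mito(gm$profiles[, lv], gm$genes$is_mito,
                           gm$mito_shape, mf)
    libs <- stats::rlnorm(n_ref_per_type, ls_par[1], ls_par[2])
    m <- draw_counts(p, libs, gm$dispersion)
    bc <- sprintf("ref_%s_%04d", lv, seq_len(n_ref_per_type))
    dimnames(m) <- list(gm$genes$gene_id, bc)
    mats[[lv]] <- Matrix::Matrix(m, sparse = TRUE)
    labs[[lv]] <- tibble::tibble(barcode = bc, level3 = lv)
  }
  counts <- methods::as(do.call(cbind, mats), "generalMatrix")
  labels <- dplyr::left_join(dplyr::bind_rows(labs),
                             tree[, c("level3", "level2", "level1")],
                             by = "level3")
  norm <- normalize_counts(counts)

  # markers: largest mean log fold-change vs all other types
  # (normalize_counts is already on the log1p scale)
  lm <- t(as.matrix(norm))
  type_means <- rowsum(lm, labels$level3) / as.vector(table(labels$level3)[
    sort(unique(labels$level3))])
  type_means <- t(type_means)     # genes x types
  markers <- list()
  for (lv in leaves) {
    lfc <- type_means[, lv] - rowMeans(type_means[, setdiff(colnames(type_means),
                                                            lv), drop = FALSE])
    ord <- order(-lfc, rownames(type_means))
    keep <- ord[seq_len(params$markers_per_type)]
    keep <- keep[lfc[keep] > 0]
    markers[[lv]] <- tibble::tibble(level3 = lv,
                                    gene_id = rownames(type_means)[keep],
                                    mean_lfc = lfc[keep])
  }
  markers <- dplyr::bind_rows(markers)
  # level-1 marker panel: 10 per compartment (9 for the last) -> 39 genes
  panel <- character(0)
  sizes <- c(Immune = 10, Epithelial = 10, Endothelial = 10, Stroma = 9)
  for (l1 in names(sizes)) {
    sibs <- tree$level3[tree$level1 == l1]
    cand <- markers[markers$level3 %in% sibs, ]
    cand <- cand[order(-cand$mean_lfc, cand$gene_id), ]
    panel <- c(panel, utils::head(unique(cand$gene_id), sizes[[l1]]))
  }
  reference_atlas(profiles = norm, labels = labels, tree = tree,
                  markers = markers, panel = panel)
}
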