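#' Run the paired-cohort comparison pipeline from a config
#'
#' Drives the full analysis over a flat YAML (or list) configuration:
#' stages run in the fixed order
#' `qc -> normalize -> annotate -> cnv -> pseudobulk_de -> interactome ->
#' compare_metrics`, each writing its tables as TSV (floating point at 6
#' significant digits) into the output directory together with a
#' machine-readable log of parameters and versions. With a fixed seed the
#' numeric tables are byte-identical across runs.
#'
#' The config either names input files (`inputs:` with `matrix`, `genes`,
#' `barcodes`, `cell_table`, `gene_table`) or requests synthetic generation
#' (`simulate:` with [sim_params()] fields). Annotation requires an atlas,
#' which in simulation mode is built with [make_reference()].
#'
#' @param config Path to a YAML config, or an equivalent named list.
#' @param output_dir Optional override of the config's `output_dir`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  all_stages <- c("qc", "normalize", "annotate", "cnv", "pseudobulk_de",
                  "interactome", "compare_metrics")
  stages <- cfg$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stages <- all_stages[all_stages %in% stages]   # canonical order
  out <- output_dir %||% cfg$output_dir
  if (is.null(out)) stop("config must name output_dir", call. = FALSE)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  set.seed(seed)

  res <- list(output_dir = out)
  if (!is.null(cfg$simulate)) {
    sp <- do.call(sim_params, cfg$simulate)
    sp$seed <- seed
    res$params <- sp
    res$data <- generate_cohort(sp, seed = seed)
    res$atlas <- make_reference(sp)
    res$lrdb <- make_lr_database(res$atlas, seed = seed + 2000L)
    res$stress_genes <-
      res$data$truth$genes$gene_id[res$data$truth$genes$stress_set]
  } else if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    need <- c("matrix", "genes", "barcodes", "cell_table")
    miss <- need[!vapply(need, function(k) !is.null(ip[[k]]), TRUE)]
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    counts <- read_counts(ip$matrix, ip$genes, ip$barcodes)
    cells <- read_cell_table(ip$cell_table)
    genes <- if (!is.null(ip$gene_table)) read_gene_table(ip$gene_table)
    res$data <- list(counts = counts, cells = cells, genes = genes)
    if (!is.null(ip$stress_genes))
      res$stress_genes <- readLines(ip$stress_genes)
    if (!is.null(ip$lr_pairs))
      res$lrdb <- lr_database(tibble::as_tibble(utils::read.table(
        ip$lr_pairs, sep = "\t", header = TRUE, stringsAsFactors = FALSE)))
  } else {
    stop("config must provide either simulate: or inputs:", call. = FALSE)
  }
  dat <- res$data
  if (is.null(dat$genes) && any(stages %in% c("qc", "cnv")))
    stop("gene table required for requested stages", call. = FALSE)
  if (!"sample" %in% names(dat$cells))
    dat$cells$sample <- paste(dat$cells$patient, dat$cells$tissue,
                              dat$cells$method, sep = "_")

  for (stage in stages) {
    res <- switch(stage,
      qc = stage_qc(res, dat, cfg, out),
      normalize = stage_normalize(res, dat, cfg, out),
      annotate = stage_annotate(res, dat, cfg, out),
      cnv = stage_cnv(res, dat, cfg, out),
      pseudobulk_de = stage_pseudobulk(res, dat, cfg, out),
      interactome = stage_interactome(res, dat, cfg, out, seed),
      compare_metrics = stage_compare(res, dat, cfg, out))
  }

  log <- list(seed = seed, stages = stages,
              package_version = as.character(utils::packageVersion("pairseq")),
              parameters = cfg[setdiff(names(cfg), c("output_dir"))],
              input_mode = if (!is.null(cfg$simulate)) "simulate" else "files")
  yaml::write_yaml(log, file.path(out, "run_log.yaml"))
  invisible(res)
}

stage_qc <- function(res, dat, cfg, out) {
  qcfg <- cfg$qc %||% list()
  metrics <- compute_cell_metrics(dat$counts, dat$genes)
  metrics <- dplyr::left_join(metrics, dat$cells, by = "barcode")
  qf <- qc_filter(metrics, nmads = qcfg$nmads %||% 3,
                  mito_cap = qcfg$mito_cap %||% 25)
  cells <- qf$cells
  if (isTRUE(qcfg$detect_doublets %||% TRUE)) {
    dd <- list()
    for (s in unique(cells$sample)) {
      bc <- cells$barcode[cells$sample == s & cells$qc_pass]
      if (length(bc) < 50) next
      dd[[s]] <- detect_doublets(dat$counts[, bc, drop = FALSE],
                                 expected_rate = qcfg$doublet_rate %||% 0.05,
                                 seed = (cfg$seed %||% 1L) +
                                   match(s, unique(cells$sample)))
    }
    dd <- dplyr::bind_rows(dd)
    cells <- dplyr::left_join(cells, dd, by = "barcode")
    cells$doublet[is.na(cells$doublet)] <- FALSE
    cells$qc_pass <- cells$qc_pass & !cells$doublet
  } else cells$doublet <- FALSE
  res$qc <- list(cells = cells, thresholds = qf$thresholds)
  write_num_tsv(cells[, setdiff(names(cells), "zero_count")],
                file.path(out, "qc_metrics.tsv"))
  write_num_tsv(qf$thresholds, file.path(out, "qc_thresholds.tsv"))
  res
}

stage_normalize <- function(res, dat, cfg, out) {
  if (is.null(res$qc)) stop("normalize requires the qc stage", call. = FALSE)
  keep <- res$qc$cells$barcode[res$qc$cells$qc_pass]
  res$norm <- normalize_counts(dat$counts[, keep, drop = FALSE])
  smry <- tibble::tibble(n_cells = length(keep),
                         median_libsize = stats::median(
                           Matrix::colSums(dat$counts[, keep])))
  write_num_tsv(smry, file.path(out, "normalize_summary.tsv"))
  res
}

stage_annotate <- function(res, dat, cfg, out) {
  if (is.null(res$norm)) stop("annotate requires normalize", call. = FALSE)
  if (is.null(res$atlas)) stop("annotate requires a reference atlas",
                               call. = FALSE)
  acfg <- cfg$annotate %||% list()
  res$annot <- annotate_cells(res$norm, res$atlas,
                              k = acfg$k %||% 30,
                              n_pcs = acfg$n_pcs %||% 20,
                              unclassified_threshold =
                                acfg$unclassified_threshold %||% 0.5)
  write_num_tsv(res$annot, file.path(out, "annotation.tsv"))
  af <- annotated_fraction(dplyr::left_join(res$annot, dat$cells,
                                            by = "barcode"),
                           group_by = c("tissue", "method"))
  write_num_tsv(af, file.path(out, "annotated_fraction.tsv"))
  res
}

stage_cnv <- function(res, dat, cfg, out) {
  if (is.null(res$annot)) stop("cnv requires annotate", call. = FALSE)
  ccfg <- cfg$cnv %||% list()
  l1 <- res$annot[res$annot$level == 1, ]
  meta <- dplyr::left_join(dat$cells, l1[, c("barcode", "label", "score")],
                           by = "barcode")
  epi <- meta$label == "Epithelial" & meta$barcode %in% colnames(res$norm)
  calls <- list()
  for (m in unique(meta$method)) {
    qbc <- meta$barcode[epi & meta$method == m & meta$tissue == "Tumor"]
    rbc <- meta$barcode[epi & meta$method == m & meta$tissue == "Normal"]
    if (length(qbc) < 5 || length(rbc) < 20) next
    qm <- meta[match(qbc, meta$barcode),
               c("barcode", "patient", "method", "score")]
    names(qm)[4] <- "annotation_score"
    calls[[m]] <- cnv_call(res$norm[, qbc, drop = FALSE],
                           res$norm[, rbc, drop = FALSE],
                           dat$genes, qm,
                           window = ccfg$window %||% 101,
                           clip_sd = ccfg$clip_sd %||% 3)
  }
  res$cnv <- dplyr::bind_rows(calls)
  write_num_tsv(res$cnv, file.path(out, "cnv_scores.tsv"))
  res
}

stage_pseudobulk <- function(res, dat, cfg, out) {
  if (is.null(res$annot)) stop("pseudobulk_de requires annotate", call. = FALSE)
  pcfg <- cfg$pseudobulk %||% list()
  lvl <- pcfg$level %||% 1
  a <- res$annot[res$annot$level == lvl & !res$annot$unclassified,
                 c("barcode", "label")]
  names(a)[2] <- "celltype"
  cells <- dplyr::inner_join(dat$cells, a, by = "barcode")
  cells <- cells[cells$barcode %in% res$qc$cells$barcode[
    res$qc$cells$qc_pass], , drop = FALSE]
  pb <- aggregate_pseudobulk(dat$counts, cells,
                             min_cells = pcfg$min_cells %||% 10)
  res$pseudobulk <- pb
  write_num_tsv(pb$groups, file.path(out, "pseudobulk_groups.tsv"))
  ct <- pcfg$contrast %||% c("method", "cell", "nucleus")
  covs <- pcfg$covariates %||% "patient"
  epi <- pb$groups$celltype == (pcfg$de_celltype %||% "Epithelial")
  sub <- structure(list(matrix = pb$matrix[, epi, drop = FALSE],
                        groups = pb$groups[epi, , drop = FALSE]),
                   class = "pairseq_pseudobulk")
  de <- try(nb_differential_expression(sub, ct, covariates = covs),
            silent = TRUE)
  if (!inherits(de, "try-error")) {
    res$de <- de
    write_num_tsv(tidy(de), file.path(out, "de_results.tsv"))
  }
  tv <- top_variable_genes(pb, fraction = pcfg$top_fraction %||% 0.05)
  writeLines(tv, file.path(out, "top_variable_genes.txt"))
  pn <- normalize_pseudobulk(pb)
  hc <- ward_cluster(t(pn[tv, , drop = FALSE]))
  res$dendrogram <- hc
  writeLines(hclust_newick(hc), file.path(out, "dendrogram.nwk"))
  res
}

# Newick serialization of an hclust tree (labels + merge heights).
hclust_newick <- function(hc) {
  n <- length(hc$labels)
  node <- function(i, h) {
    if (i < 0) return(paste0(hc$labels[-i], ":", formatC(h, digits = 6,
                                                         format = "g")))
    hh <- hc$height[i]
    paste0("(", node(hc$merge[i, 1], hh), ",", node(hc$merge[i, 2], hh),
           "):", formatC(max(h - hh, 0), digits = 6, format = "g"))
  }
  top <- nrow(hc$merge)
  paste0("(", node(hc$merge[top, 1], hc$height[top]), ",",
         node(hc$merge[top, 2], hc$height[top]), ");")
}

stage_interactome <- function(res, dat, cfg, out, seed) {
  if (is.null(res$annot)) stop("interactome requires annotate", call. = FALSE)
  if (is.null(res$lrdb)) stop("interactome requires an LR pair table",
                              call. = FALSE)
  icfg <- cfg$interactome %||% list()
  lvl <- max(res$annot$level)
  a <- res$annot[res$annot$level == lvl, ]
  elig <- eligible_celltypes(a, level = lvl,
                             min_cells = icfg$min_cells %||% 500)
  a <- a[!a$unclassified & a$label %in% elig &
           a$barcode %in% colnames(res$norm), ]
  expr <- res$norm[, a$barcode, drop = FALSE]
  edges <- interaction_strength(expr, a$label, res$lrdb, elig)
  edges <- permutation_significance(edges, expr, a$label, res$lrdb,
                                    n_perm = icfg$n_perm %||% 200,
                                    alpha = icfg$alpha %||% 0.05,
                                    seed = seed + 5000L)
  res$interactome <- edges
  write_num_tsv(edges, file.path(out, "interactome_edges.tsv"))
  write_num_tsv(inout_counts(edges), file.path(out, "interactome_inout.tsv"))
  write_num_tsv(pathway_aggregate(edges, significant_only = TRUE),
                file.path(out, "interactome_pathways.tsv"))
  res
}

stage_compare <- function(res, dat, cfg, out) {
  if (is.null(res$annot)) stop("compare_metrics requires annotate",
                               call. = FALSE)
  qc_cells <- res$qc$cells
  keep <- qc_cells$barcode[qc_cells$qc_pass]
  comp <- composition_table(res$annot, dat$cells[dat$cells$barcode %in%
                                                   keep, ], level = 1)
  write_num_tsv(comp, file.path(out, "composition_level1.tsv"))
  lvl <- max(res$annot$level)
  a <- res$annot[res$annot$level == lvl & !res$annot$unclassified &
                   res$annot$barcode %in% colnames(res$norm), ]
  sil_rows <- list()
  meta <- dat$cells
  for (tis in unique(meta$tissue)) for (m in unique(meta$method)) {
    bc <- intersect(a$barcode,
                    meta$barcode[meta$tissue == tis & meta$method == m])
    if (length(bc) < 10) next
    emb <- compute_embedding(res$norm[, bc, drop = FALSE])
    if (length(bc) > 2000) bc <- sort(bc)[seq_len(2000)]
    labs <- a$label[match(bc, a$barcode)]
    if (length(unique(labs)) < 2) next
    sl <- silhouette_by_label(emb[match(bc, emb$barcode), ], labs)
    sil_rows[[paste(tis, m)]] <- tibble::tibble(
      tissue = tis, method = m, n = length(bc),
      median_s = stats::median(sl$cells$s))
  }
  sil <- dplyr::bind_rows(sil_rows)
  write_num_tsv(sil, file.path(out, "silhouette.tsv"))
  res$silhouette <- sil
  if (!is.null(res$stress_genes)) {
    sf <- signature_fraction(dat$counts[, keep, drop = FALSE],
                             res$stress_genes,
                             dat$cells[dat$cells$barcode %in% keep, ])
    write_num_tsv(sf$groups, file.path(out, "stress_fraction.tsv"))
    res$stress <- sf
  }
  mf <- mito_fraction_raw(dat$counts, dat$genes, dat$cells)
  write_num_tsv(mf$groups, file.path(out, "mito_raw.tsv"))
  res$mito <- mf
  res
}

#' Synthesize a ligand-receptor pair table from atlas markers
#'
#' Builds a small LR database whose ligands and receptors are type markers,
#' so some edges carry genuine sender/receiver signal; includes one
#' multi-subunit receptor entry.
#'
#' @param atlas A [reference_atlas()].
#' @param n_pairs Number of pairs (default 12).
#' @param seed Seed for the pairing draw.
#' @return An [lr_database()] tibble.
#' @export
make_lr_database <- function(atlas, n_pairs = 12, seed = 1L) {
  set.seed(seed)
  mk <- atlas$markers
  types <- unique(mk$level3)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    st <- sample(types, 2)
    lig <- sample(mk$gene_id[mk$level3 == st[1]], 1)
    rec_genes <- sample(mk$gene_id[mk$level3 == st[2]],
                        if (i == n_pairs) 2 else 1)
    rows[[i]] <- tibble::tibble(ligand = lig,
                                receptor = paste(rec_genes, collapse = ";"),
                                pathway = paste0("PW",
                                                 ((i - 1) %% 4) + 1))
  }
  lr_database(dplyr::bind_rows(rows))
}
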