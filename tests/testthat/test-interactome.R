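# A tiny deterministic expression set: two types with disjoint programs.
lr_fixture <- function(n_per_type = 60, fold = 8, seed = 50) {
  set.seed(seed)
  genes <- c("LIG1", "REC1", "LIG2", "REC2A", "REC2B", sprintf("bg%02d", 1:20))
  base <- rep(2, length(genes))
  mkmat <- function(boost, n) {
    mu <- base * boost
    matrix(rpois(length(genes) * n, mu), length(genes), n,
           dimnames = list(genes, NULL))
  }
  bA <- rep(1, length(genes)); names(bA) <- genes
  bB <- bA
  bA[c("LIG1", "REC2A", "REC2B")] <- fold
  bB[c("REC1", "LIG2")] <- fold
  m <- cbind(mkmat(bA, n_per_type), mkmat(bB, n_per_type))
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  types <- rep(c("A", "B"), each = n_per_type)
  list(expr = Matrix::Matrix(m, sparse = TRUE), types = types)
}

lrdb_fixture <- function() {
  tibble::tibble(ligand = c("LIG1", "LIG2"),
                 receptor = c("REC1", "REC2A;REC2B"),
                 pathway = c("PW1", "PW2"))
}

test_that("eligibility enforces the minimum-cell and classification rules", {
  annot <- tibble::tibble(
    barcode = sprintf("b%04d", 1:1200),
    level = 3,
    label = c(rep("A", 600), rep("B", 499), rep("C", 101)),
    score = 0.9, unclassified = FALSE)
  annot$unclassified[annot$label == "C"] <- TRUE
  annot$score[annot$label == "C"] <- 0.3
  expect_error(eligible_celltypes(annot, min_cells = 500), "fewer than 2")
  annot$label[601:1099] <- "B"          # still 499 B cells
  e1 <- eligible_celltypes(annot, min_cells = 499)
  expect_setequal(e1, c("A", "B"))
  # unclassified cells never count, regardless of volume
  expect_false("C" %in% eligible_celltypes(annot, min_cells = 1))
})

test_that("interaction strength is the (geometric-)mean product", {
  genes <- c("L", "R")
  m <- Matrix::Matrix(rbind(L = c(2, 2, 0, 0), R = c(0, 0, 3, 3)),
                      sparse = TRUE)
  colnames(m) <- sprintf("c%d", 1:4)
  types <- c("S", "S", "T", "T")
  db <- tibble::tibble(ligand = "L", receptor = "R", pathway = "p")
  e <- interaction_strength(m, types, db)
  s <- e$strength[e$sender == "S" & e$receiver == "T"]
  expect_equal(s, 2 * 3)
  # bilinearity: doubling receptor expression doubles strength
  m2 <- m; m2["R", ] <- 2 * m2["R", ]
  e2 <- interaction_strength(m2, types, db)
  expect_equal(e2$strength[e2$sender == "S" & e2$receiver == "T"], 12)
  # absent ligand -> all its edges zero (with a warning when no gene at all)
  db2 <- tibble::tibble(ligand = "MISSING", receptor = "R", pathway = "p")
  expect_warning(e3 <- interaction_strength(m, types, db2), "skipped")
  expect_equal(nrow(e3), 0)
})

test_that("permutation significance has the plus-one floor and finds signal", {
  fx <- lr_fixture()
  expr <- normalize_counts(fx$expr)
  e <- interaction_strength(expr, fx$types, lrdb_fixture())
  set.seed(60)
  e <- permutation_significance(e, expr, fx$types, lrdb_fixture(),
                                n_perm = 100, seed = 61)
  expect_true(all(e$p >= 1 / 101 - 1e-12))
  # engineered edges: A sends LIG1 to B (REC1), B sends LIG2 to A (REC2A+B)
  expect_true(e$significant[e$pair == "LIG1->REC1" & e$sender == "A" &
                              e$receiver == "B"])
  expect_true(e$significant[e$pair == "LIG2->REC2A;REC2B" &
                              e$sender == "B" & e$receiver == "A"])
  expect_error(permutation_significance(e, expr, fx$types, lrdb_fixture(),
                                        n_perm = 5), "20")
})

test_that("in/out counts conserve the number of significant edges", {
  e <- tibble::tibble(sender = c("A", "A", "B", "B"),
                      receiver = c("B", "A", "A", "B"),
                      pair = "x->y", pathway = "p",
                      strength = c(1, 2, 3, 0),
                      significant = c(TRUE, TRUE, TRUE, FALSE))
  io <- inout_counts(e)
  expect_equal(sum(io$incoming), 3)
  expect_equal(sum(io$outgoing), 3)
  # the self-loop A->A counts once in each direction for A
  a <- io[io$celltype == "A", ]
  expect_equal(a$outgoing, 2L)
  expect_equal(a$incoming, 2L)
  empty <- e[0, ]
  io0 <- inout_counts(empty)
  expect_equal(nrow(io0), 0)
})

test_that("pathway aggregation partitions the edges", {
  fx <- lr_fixture()
  expr <- normalize_counts(fx$expr)
  e <- interaction_strength(expr, fx$types, lrdb_fixture())
  pa <- pathway_aggregate(e)
  expect_equal(sum(pa$n_edges), nrow(e))
  pw1 <- pa$total_strength[pa$pathway == "PW1"]
  expect_equal(pw1, sum(e$strength[e$pathway == "PW1"]))
})

test_that("exchangeable labels keep the significant-edge rate near alpha", {
  set.seed(70)
  rates <- c()
  for (rep in 1:4) {
    genes <- sprintf("g%02d", 1:12)
    m <- Matrix::Matrix(matrix(rpois(12 * 150, 4), 12, 150,
                               dimnames = list(genes, sprintf("c%03d", 1:150))),
                        sparse = TRUE)
    types <- sample(rep(c("A", "B", "C"), each = 50))
    db <- tibble::tibble(ligand = genes[1:4], receptor = genes[5:8],
                         pathway = "p")
    expr <- normalize_counts(m)
    e <- interaction_strength(expr, types, db)
    e <- permutation_significance(e, expr, types, db, n_perm = 100,
                                  seed = 70 + rep)
    rates <- c(rates, mean(e$significant))
  }
  mc_se <- sqrt(0.05 * 0.95 / (length(rates) * 36))
  expect_lte(mean(rates), 0.05 + 3 * mc_se)
})
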