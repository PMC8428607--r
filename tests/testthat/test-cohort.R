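make_expr <- function(m, genes, fill = 2) {
  matrix(fill, m, length(genes),
         dimnames = list(sprintf("C%03d", seq_len(m)), genes))
}

test_that("feature-gene filter applies the 1%-of-lines rule at its boundary", {
  m <- 100L
  expr <- make_expr(m, c("A", "B", "C", "D"), fill = 0.5)
  expr[1, "A"] <- 1.5                      # >1 in exactly 1% of lines
  expr[, "C"] <- 3                         # high everywhere
  expr[, "D"] <- 3                         # high but outside the ontology
  keep <- filter_feature_genes(expr, ontology_genes = c("A", "B", "C"))
  expect_true("A" %in% keep)
  expect_false("B" %in% keep)              # never exceeds 1
  expect_true("C" %in% keep)
  expect_false("D" %in% keep)              # not in ontology
  expect_error(filter_feature_genes(expr, ontology_genes = "Z"),
               "no gene")
})

test_that("target-gene selection enforces both class floors and the gene lists", {
  m <- 20L
  dep <- matrix(0, m, 4, dimnames = list(sprintf("C%03d", 1:m),
                                         c("A", "B", "C", "D")))
  dep[1:5, "A"] <- 0.9                     # 5 positives: below floor
  dep[, "B"] <- 0.9                        # all dependent: no negatives
  dep[1:6, "C"] <- 0.9                     # 6 pos / 14 neg
  dep[1:6, "D"] <- 0.9
  keep <- select_target_genes(dep, ontology_genes = c("A", "B", "C", "D"),
                              druggable = c("A", "B", "C"))
  expect_identical(keep, "C")              # D fails druggability
})

test_that("binarization puts probability 0.5 in the positive class", {
  dep <- matrix(c(0.5, 0.49, 0.9, 0.1, 0.9, 0.1), 3, 2,
                dimnames = list(c("C1", "C2", "C3"), c("A", "B")))
  expr <- make_expr(3, c("A", "B"))
  rownames(expr) <- rownames(dep)
  h <- toy_hierarchy()
  h$pathways$P1$genes <- c("A", "B")       # make both genes ontologic
  h$gene_universe <- c(h$gene_universe, "A", "B")
  co <- build_cohort(expr, dep, h, min_pos = 1L, min_neg = 1L)
  expect_equal(unname(co$labels[, "A"]), c(1L, 0L, 1L))
})

test_that("feature masks accumulate smallest pathways first up to the cap", {
  # target in three pathways of sizes 5, 40 and 300 feature genes
  genes <- sprintf("G%03d", 1:320)
  raw <- list(SMALL = c("TGT", genes[1:5]),
              MID = c("TGT", genes[6:45]),
              BIG = c("TGT", genes[46:320]))
  edges <- data.frame(child = c("SMALL", "MID"), parent = c("BIG", "BIG"))
  h <- filter_pathways(raw, edges, relevant_genes = c("TGT", genes),
                       min_genes = 1L)
  u <- build_feature_mask("TGT", h, feature_genes = genes, cap = 100L)
  expect_equal(sum(u), 100L)               # cap reached exactly
  expect_true(all(u[genes[1:5]] == 1))     # smallest pathway fully in
  expect_true(all(u[genes[6:45]] == 1))    # then the 40-gene pathway
  # remainder filled from BIG in sorted-symbol order
  expect_equal(sum(u[genes[46:320]]), 55L)
  big_sorted <- sort(genes[46:320])
  expect_true(all(u[big_sorted[1:55]] == 1))

  # exhaustion: pathways jointly cover fewer genes than the cap
  u2 <- build_feature_mask("TGT", h, feature_genes = genes[1:40], cap = 100L)
  expect_equal(sum(u2), 40L)

  # a single small pathway selects exactly its feature-gene members
  u3 <- build_feature_mask("TGT", h, feature_genes = genes[1:5], cap = 100L)
  expect_equal(sum(u3), 5L)

  expect_error(build_feature_mask("ABSENT", h, genes), "no pathway")
})

test_that("mask construction is deterministic", {
  h <- toy_hierarchy()
  u1 <- build_feature_mask("G3", h, toy_genes(), cap = 3L)
  u2 <- build_feature_mask("G3", h, toy_genes(), cap = 3L)
  expect_identical(u1, u2)
})

test_that("z-scoring uses training statistics only", {
  expr <- matrix(c(1, 3, 5, 7,            # gene A
                   2, 2, 9, 9,            # gene B (constant in training)
                   1, 2, 3, 4), 4, 3,
                 dimnames = list(c("tr1", "tr2", "te1", "te2"),
                                 c("A", "B", "C")))
  zs <- zscore_by_training(expr, c("tr1", "tr2"))
  expect_equal(mean(zs$z[c("tr1", "tr2"), "A"]), 0)
  expect_equal(sd(zs$z[c("tr1", "tr2"), "A"]), 1)
  expect_equal(zs$z["te1", "A"], (5 - 2) / sd(c(1, 3)))
  expect_true(all(zs$z[, "B"][1:2] == 0))  # zero training variance -> 0
  # value equal to the training mean maps to 0
  expr2 <- expr; expr2["te1", "A"] <- 2
  expect_equal(zscore_by_training(expr2, c("tr1", "tr2"))$z["te1", "A"], 0)
  # shuffling non-training rows never changes the transform parameters
  expr3 <- expr; expr3[c("te1", "te2"), ] <- expr[c("te2", "te1"), ]
  zs3 <- zscore_by_training(expr3, c("tr1", "tr2"))
  expect_identical(zs$mean, zs3$mean)
  expect_identical(zs$sd, zs3$sd)
})

test_that("sample assembly concatenates masked expression and the deletion one-hot", {
  z <- matrix(1:6 + 0, 2, 3, dimnames = list(c("C1", "C2"),
                                             c("A", "B", "C")))
  masks <- rbind(T1 = c(1L, 0L, 1L), T2 = c(0L, 1L, 1L),
                 T3 = c(1L, 1L, 1L), T4 = c(1L, 1L, 0L), T5 = c(1L, 0L, 0L))
  colnames(masks) <- c("A", "B", "C")
  labels <- matrix(1L, 2, 5, dimnames = list(c("C1", "C2"),
                                             rownames(masks)))
  sm <- assemble_samples(z, labels, masks, c("C1", "C2"))
  expect_equal(nrow(sm$x), 2L * 5L)        # m x n samples
  expect_equal(ncol(sm$x), 3L + 5L)
  # the one-hot for target index 4 of n = 5
  row_t4 <- which(sm$target == "T4")[1]
  expect_equal(unname(sm$x[row_t4, 4:8]), c(0, 0, 0, 1, 0))
  # masked positions carry 0 regardless of expression
  row_t1 <- which(sm$target == "T1" & sm$cell == "C1")
  expect_equal(unname(sm$x[row_t1, 1:3]), c(1, 0, 5))
})

test_that("stratified folds give 64/16/20 on 100 cell lines and are reproducible", {
  set.seed(11)
  m <- 100L
  expr <- matrix(rnorm(m * 4, 3), m, 4,
                 dimnames = list(sprintf("C%03d", 1:m), c("A", "B", "C", "D")))
  dep <- matrix(runif(m * 2), m, 2,
                dimnames = list(rownames(expr), c("A", "B")))
  h <- toy_hierarchy()
  h$pathways$P1$genes <- c("A", "B", "C", "D")
  h$gene_universe <- c("A", "B", "C", "D")
  tissues <- setNames(rep(c("lung", "skin", "blood", "bone"), each = 25),
                      rownames(expr))
  co <- build_cohort(expr, dep, h, tissues = tissues,
                     min_pos = 1L, min_neg = 1L)
  f <- stratified_folds(co, seed = 9L)
  sizes <- t(vapply(f$folds, function(x)
    c(length(x$train), length(x$validation), length(x$test)), numeric(3)))
  expect_true(all(sizes[, 1] == 64L))
  expect_true(all(sizes[, 2] == 16L))
  expect_true(all(sizes[, 3] == 20L))
  # folds partition the cell lines; roles are disjoint within a fold
  expect_setequal(unlist(lapply(f$folds, `[[`, "test")), rownames(expr))
  for (k in seq_along(f$folds)) {
    fold <- f$folds[[k]]
    expect_length(intersect(fold$train, fold$validation), 0L)
    expect_length(intersect(fold$train, fold$test), 0L)
    expect_length(intersect(fold$validation, fold$test), 0L)
    expect_setequal(c(fold$train, fold$validation, fold$test),
                    rownames(expr))
  }
  # reproducibility
  f2 <- stratified_folds(co, seed = 9L)
  expect_identical(f$assignment, f2$assignment)
  # tissue balance: 25 lines per tissue -> 5 per test fold
  for (k in seq_along(f$folds)) {
    expect_equal(as.integer(table(tissues[f$folds[[k]]$test])), rep(5L, 4))
  }
  # class balance: per-fold positive fraction within 10% of global
  g <- mean(co$labels)
  for (k in seq_along(f$folds)) {
    expect_lt(abs(mean(co$labels[f$folds[[k]]$test, ]) - g), 0.1)
  }
  expect_error(stratified_folds(co, n_folds = 200L), "fewer cell lines")
})

test_that("a tissue with exactly 5 lines lands once in every test fold", {
  m <- 50L
  expr <- matrix(3, m, 2, dimnames = list(sprintf("C%02d", 1:m),
                                          c("A", "B")))
  dep <- matrix(rep(c(0.9, 0.1), m), m, 2,
                dimnames = list(rownames(expr), c("A", "B")))
  h <- toy_hierarchy(); h$gene_universe <- c("A", "B")
  tissues <- setNames(c(rep("rare", 5), rep("common", 45)), rownames(expr))
  co <- build_cohort(expr, dep, h, tissues = tissues,
                     min_pos = 1L, min_neg = 1L)
  f <- stratified_folds(co, seed = 2L)
  rare_fold <- vapply(f$folds, function(x)
    sum(tissues[x$test] == "rare"), 1)
  expect_equal(unname(rare_fold), rep(1, 5))
})

test_that("matrix readers preserve the DepMap orientation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",TP53 (7157),brca1", "ACH-1,1.5,2", "ACH-2,0,3.5"), f)
  m <- read_matrix_csv(f)
  expect_identical(colnames(m), c("TP53", "BRCA1"))
  expect_identical(rownames(m), c("ACH-1", "ACH-2"))
  expect_equal(m["ACH-2", "BRCA1"], 3.5)
})
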