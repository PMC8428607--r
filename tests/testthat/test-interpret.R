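test_that("neuron-state extraction is deterministic with full cardinality", {
  study <- small_study(seed = 12L)
  tr <- small_train(study, seed = 12L, max_epochs = 8L)
  tg <- study$cohort$target_genes[1]
  ns1 <- extract_states(tr$fit, study$cohort, tg)
  ns2 <- extract_states(tr$fit, study$cohort, tg)
  expect_identical(ns1$states, ns2$states)
  m <- nrow(study$cohort$expression)
  expect_length(ns1$states, length(tr$fit$model$blocks))
  for (s in ns1$states) expect_equal(nrow(s), m)
  # pathway states ignore genes outside their closure
  h <- study$hierarchy
  leaf <- names(h$levels)[h$levels == 1L][1]
  outside <- setdiff(study$cohort$feature_genes, h$pathways[[leaf]]$genes)[1]
  mutated <- study$cohort
  mutated$expression[, outside] <- mutated$expression[, outside] + 5
  ns3 <- extract_states(tr$fit, mutated, tg)
  expect_identical(ns1$states[[leaf]], ns3$states[[leaf]])
})

test_that("pathway PCA matches an eigendecomposition oracle on a 5x4 toy", {
  set.seed(15)
  X <- matrix(rnorm(20), 5, 4)
  pcs <- pathway_pca(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(cov(Xc))
  oracle <- Xc %*% eig$vectors[, 1:2]
  # components agree up to sign
  for (j in 1:2) {
    expect_true(max(abs(pcs[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(pcs[, j] + oracle[, j])) < 1e-8)
  }
  expect_gte(var(pcs[, 1]), var(pcs[, 2]))
  expect_error(pathway_pca(matrix(1, 5, 4)), "zero-variance")
  expect_error(pathway_pca(X[1:2, ]), "at least 3")
})

test_that("class separation detects complete separation and refuses one class", {
  set.seed(16)
  pc <- cbind(PC1 = c(rnorm(20, -5), rnorm(20, 5)), PC2 = rnorm(40))
  labels <- rep(c(0, 1), each = 20)
  res <- class_separation_test(pc, labels)
  expect_lt(res$p_combined, 1e-6)
  expect_equal(res$score, -log10(res$p_combined))
  expect_error(class_separation_test(pc, rep(1, 40)), "both classes")
})

test_that("Fisher combination follows the chi-square closed form", {
  pc <- cbind(PC1 = c(1, 2, 3, 4, 10, 11, 12, 13),
              PC2 = c(2, 1, 4, 3, 11, 10, 13, 12))
  labels <- rep(c(0, 1), each = 4)
  res <- class_separation_test(pc, labels)
  expect_equal(res$p_combined,
               pchisq(-2 * (log(res$p_pc1) + log(res$p_pc2)), df = 4,
                      lower.tail = FALSE))
})

test_that("related-vs-unrelated comparison skips ineligible genes and flat scores", {
  flat <- data.frame(pathway = paste0("P", 1:20),
                     related = rep(c(TRUE, FALSE), each = 10),
                     score = rep(1, 20))
  r <- related_vs_unrelated(flat)
  expect_false(r$skipped)
  expect_gt(r$p, 0.4)                       # all-equal scores: no signal
  few <- flat[c(1:3, 11:20), ]              # only 3 related pathways
  r2 <- related_vs_unrelated(few)
  expect_true(r2$skipped)
  expect_match(r2$reason, "related")
})

test_that("shuffling related flags calibrates the related-vs-unrelated null", {
  set.seed(17)
  nonsig <- 0L
  for (i in 1:40) {
    tab <- data.frame(pathway = paste0("P", 1:24),
                      related = sample(rep(c(TRUE, FALSE), c(8, 16))),
                      score = rexp(24))
    r <- related_vs_unrelated(tab)
    if (r$p > 0.1) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 36L)                   # >= 90% non-significant
})

test_that("prediction explanations are level-ordered cohort z-scores", {
  study <- small_study(seed = 18L)
  tr <- small_train(study, seed = 18L, max_epochs = 8L)
  tg <- study$cohort$target_genes[1]
  cell <- rownames(study$cohort$expression)[1]
  ex <- explain_prediction(tr$fit, study$cohort, cell, tg, study$hierarchy)
  expect_false(is.unsorted(ex$level))
  expect_equal(ex$pathway[nrow(ex)], study$hierarchy$root)  # root last
  expect_true(all(is.finite(ex$z)))
  expect_error(explain_prediction(tr$fit, study$cohort, "NOPE", tg,
                                  study$hierarchy), "unknown cell")
  # the z-scores have cohort mean 0 / sd 1 by construction: check one pathway
  ns <- extract_states(tr$fit, study$cohort, tg)
  pid <- ex$pathway[1]
  pc1 <- pathway_pca(ns$states[[pid]])[, 1]
  expect_equal(mean((pc1 - mean(pc1)) / sd(pc1)), 0, tolerance = 1e-12)
})

test_that("feature importance is the column norm of leaf weights", {
  m <- toy_model(seed = 4L)
  fit <- structure(list(model = m), class = "biovnn_fit")
  h <- toy_hierarchy()
  rx <- reaction_set(list(R1 = c("G3", "G1")))
  tab <- feature_importance(fit, "G3", "P1", h, rx)
  # oracle: direct norms from the block weight matrix
  bl <- m$blocks$P1
  for (i in seq_len(nrow(tab))) {
    ci <- match(tab$gene[i], bl$input_names)
    expect_equal(tab$importance[i], sqrt(sum(bl$W[, ci]^2)))
  }
  expect_true(tab$partner[tab$gene == "G1"])
  expect_false(any(tab$gene == "G3"))       # the target itself is excluded
  # zeroed weights give zero importance
  m0 <- m; m0$blocks$P1$W[] <- 0
  fit0 <- structure(list(model = m0), class = "biovnn_fit")
  expect_true(all(feature_importance(fit0, "G3", "P1", h, rx)$importance == 0))
  # interior pathway: importances summed over subtree leaf blocks
  tab6 <- feature_importance(fit, "G3", "P6", h, rx)
  g3cols <- function(id) {
    bl <- m$blocks[[id]]
    ci <- match("G6", bl$input_names)
    if (is.na(ci)) 0 else sqrt(sum(bl$W[, ci]^2))
  }
  expect_equal(tab6$importance[tab6$gene == "G6"],
               g3cols("P3") + g3cols("P5"))
  expect_error(feature_importance(fit, "G4", "P1", h, rx),
               "does not contain")
})

test_that("reaction enrichment has power at the published group sizes", {
  set.seed(19)
  hits <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    tab <- data.frame(gene = sprintf("g%02d", 1:77),
                      importance = c(rnorm(28, mean = 2), rnorm(49)),
                      partner = rep(c(TRUE, FALSE), c(28, 49)))
    res <- reaction_enrichment(list("T|P" = tab))
    if (res$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.8)
})

test_that("reaction enrichment skips undersized groups", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    importance = 1:4,
                    partner = c(TRUE, TRUE, FALSE, FALSE))
  res <- reaction_enrichment(list("T|P" = tab))
  expect_true(is.na(res$p))
  expect_match(res$reason, "insufficient")
  empty <- data.frame(gene = c("a", "b", "c"), importance = 1:3,
                      partner = rep(FALSE, 3))
  res2 <- reaction_enrichment(list("T|P" = empty))
  expect_true(is.na(res2$p))
})

test_that("BH adjustment matches hand-computed values on a fixed vector", {
  p <- c(0.01, 0.02, 0.03, 0.2, 0.5)
  # hand computation: p_(i) * n / i, cumulative minimum from the largest
  hand <- c(0.01 * 5 / 1, 0.02 * 5 / 2, 0.03 * 5 / 3, 0.2 * 5 / 4, 0.5)
  hand <- rev(cummin(rev(hand)))
  tabs <- lapply(seq_along(p), function(i) {
    data.frame(gene = sprintf("g%d", 1:10),
               importance = c(10:6, 5:1) + i,
               partner = rep(c(TRUE, FALSE), each = 5))
  })
  names(tabs) <- sprintf("T%d|P", seq_along(p))
  # direct check of the adjustment rule itself
  expect_equal(p.adjust(p, method = "BH"), hand)
})

test_that("hypergeometric overlap matches the closed-form tail sum", {
  # overlap >= 5 between a 10-gene cluster and a 10-gene pathway in 100 genes
  tail_sum <- sum(sapply(5:10, function(j) {
    choose(10, j) * choose(90, 10 - j) / choose(100, 10)
  }))
  expect_equal(phyper(4, 10, 90, 10, lower.tail = FALSE), tail_sum)
})

test_that("weight clustering recovers pathways planted in the weights", {
  study <- small_study(seed = 20L)
  co <- study$cohort
  h <- study$hierarchy
  fcn <- build_matched_fcn(h, co$feature_genes, co$target_genes, seed = 1L)
  leaf_ids <- names(h$levels)[h$levels == 1L]
  # plant: genes of the same leaf pathway share one strong weight direction
  set.seed(20)
  dirs <- matrix(rnorm(length(leaf_ids) * fcn$blocks$L1$s_o),
                 length(leaf_ids))
  W <- fcn$blocks$L1$W * 0.01
  for (li in seq_along(leaf_ids)) {
    members <- intersect(h$pathways[[leaf_ids[li]]]$genes, co$feature_genes)
    cols <- match(members, fcn$blocks$L1$input_names)
    W[, cols] <- W[, cols] + 3 * dirs[li, ]
  }
  # genes in several pathways blur; keep only single-pathway genes strong
  fcn$blocks$L1$W <- W
  fit <- structure(list(model = fcn), class = "biovnn_fit")
  res <- fcn_weight_clustering(fit, h, n_pcs = 10L, seed = 3L, n_sim = 20L)
  expect_gt(res$n_significant / res$n_clusters, 0.5)
  expect_gt(res$z, 2)

  # random weights: consistent with the size-matched null
  fcn2 <- build_matched_fcn(h, co$feature_genes, co$target_genes, seed = 9L)
  fit2 <- structure(list(model = fcn2), class = "biovnn_fit")
  res2 <- fcn_weight_clustering(fit2, h, n_pcs = 10L, seed = 3L,
                                n_sim = 20L)
  expect_lt(abs(res2$n_significant - res2$null_mean),
            2.5 * max(res2$null_sd, 1))
})
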