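test_that("the generator is reproducible and respects its constraints", {
  cfg <- synthetic_config(seed = 30L)
  g1 <- generate_hierarchy(cfg)
  g2 <- generate_hierarchy(cfg)
  expect_identical(g1$hierarchy$pathways, g2$hierarchy$pathways)
  expect_identical(unclass(g1$reactions), unclass(g2$reactions))
  validate_hierarchy(g1$hierarchy)
  h <- g1$hierarchy
  expect_equal(h$n_levels, cfg$n_levels)
  expect_length(setdiff(names(h$pathways), h$root), cfg$n_pathways)
  # leaf sizes within the configured range (+ planted target genes)
  leaf_ids <- names(h$levels)[h$levels == 1L]
  sizes <- vapply(h$pathways[leaf_ids], function(p) length(p$genes), 1L)
  expect_true(all(sizes >= cfg$leaf_size[1] & sizes <= cfg$leaf_size[2] + 3L))
  # every driver pathway contains its target gene, inside its reaction subset
  for (i in seq_len(nrow(g1$targets))) {
    d <- g1$targets$driver[i]; tg <- g1$targets$gene[i]
    expect_true(tg %in% h$pathways[[d]]$genes)
    expect_true(tg %in% unclass(g1$reactions)[[paste0("RX_", d)]])
  }
  # reaction subsets span 30-50% of their pathway (2-gene floor)
  for (id in leaf_ids) {
    n_rx <- length(unclass(g1$reactions)[[paste0("RX_", id)]])
    n_pw <- length(h$pathways[[id]]$genes)
    expect_gte(n_rx, 2L)
    expect_lte(n_rx, ceiling(0.5 * n_pw) + 1L)
  }
})

test_that("a toy-scale configuration yields a valid acyclic hierarchy", {
  cfg <- synthetic_config(n_genes = 12L, n_pathways = 7L, n_levels = 3L,
                          leaf_size = c(2L, 4L), n_cell_lines = 20L,
                          n_target_genes = 1L, seed = 31L)
  g <- generate_hierarchy(cfg)
  validate_hierarchy(g$hierarchy)
  expect_length(setdiff(names(g$hierarchy$pathways), g$hierarchy$root), 7L)
})

test_that("cohorts are reproducible and carry the planted prevalence", {
  cfg <- synthetic_config(seed = 32L)
  gen <- generate_hierarchy(cfg)
  c1 <- generate_cohort(gen, cfg)
  c2 <- generate_cohort(gen, cfg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$dependency, c2$dependency)
  expect_true(all(c1$dependency >= 0 & c1$dependency <= 1))
  expect_true(all(c1$expression >= 0))       # log2(TPM+1)-like scale
  prev <- colMeans(c1$dependency >= 0.5)
  expect_true(all(abs(prev - cfg$prevalence) < 0.12))
})

test_that("same-role co-members of a single shared pathway correlate at the loading", {
  cfg <- synthetic_config(seed = 33L, n_cell_lines = 300L)
  gen <- generate_hierarchy(cfg)
  co <- generate_cohort(gen, cfg)
  h <- gen$hierarchy
  leaf_ids <- names(h$levels)[h$levels == 1L]
  count_leaves <- function(g) {
    sum(vapply(leaf_ids, function(id) g %in% h$pathways[[id]]$genes, TRUE))
  }
  same_role <- c(); mixed <- c()
  for (id in leaf_ids) {
    singles <- Filter(function(g) count_leaves(g) == 1L,
                      h$pathways[[id]]$genes)
    singles <- singles[colMeans(co$expression[, singles, drop = FALSE]) > 1]
    if (length(singles) < 2L) next
    rx <- unclass(gen$reactions)[[paste0("RX_", id)]]
    is_rx <- singles %in% rx
    cm <- cor(co$expression[, singles])
    for (i in seq_along(singles)) for (j in seq_len(i - 1L)) {
      if (is_rx[i] == is_rx[j]) same_role <- c(same_role, cm[i, j])
      else mixed <- c(mixed, cm[i, j])
    }
  }
  expect_gt(length(same_role), 20L)
  expect_lt(abs(mean(same_role) - cfg$rho), 0.05)
  expect_lt(abs(mean(mixed) - cfg$rho / 2), 0.05)
})

test_that("a zero effect size yields labels independent of expression", {
  cfg <- synthetic_config(n_genes = 80L, n_pathways = 12L,
                          n_cell_lines = 80L, n_target_genes = 3L,
                          beta = 0, seed = 34L)
  study <- generate_synthetic_study(cfg)
  tr <- small_train(study, seed = 34L, max_epochs = 30L)
  pr <- predict(tr$fit, study$cohort, cells = tr$folds$folds[[1]]$test)
  expect_lt(abs(auroc(pr$score, pr$label) - 0.5), 0.17)
})

test_that("future cohorts come from the identical process but new cell lines", {
  cfg <- synthetic_config(n_genes = 80L, n_pathways = 12L,
                          n_cell_lines = 60L, n_target_genes = 3L,
                          seed = 35L)
  study <- generate_synthetic_study(cfg, n_future = 30L)
  expect_length(intersect(rownames(study$cohort$expression),
                          rownames(study$future$expression)), 0L)
  expect_identical(study$future$feature_genes, study$cohort$feature_genes)
  expect_identical(study$future$target_genes, study$cohort$target_genes)
  # same marginal scale
  expect_lt(abs(mean(study$future$expression) -
                  mean(study$cohort$expression)), 0.3)
})

test_that("written studies round-trip through the standard parsers", {
  cfg <- synthetic_config(n_genes = 60L, n_pathways = 10L,
                          n_cell_lines = 30L, n_target_genes = 2L,
                          seed = 36L)
  study <- generate_synthetic_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(study, dir)
  sets <- parse_gmt(paths[["gmt"]])
  h0 <- study$hierarchy
  for (id in setdiff(names(h0$pathways), h0$root)) {
    expect_setequal(sets[[id]], h0$pathways[[id]]$genes)
  }
  edges <- parse_hierarchy(paths[["hierarchy"]])
  rebuilt <- filter_pathways(sets, edges,
                             relevant_genes = h0$gene_universe,
                             min_genes = 1L)
  expect_identical(rebuilt$levels[names(h0$levels)], h0$levels)
  rx <- parse_reactions(paths[["reactions"]])
  expect_identical(lapply(unclass(rx), sort),
                   lapply(unclass(study$reactions), sort))
  expr <- read_matrix_csv(paths[["expression"]])
  expect_equal(expr, study$raw$expression, tolerance = 1e-6)
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$seed, 36L)
})

test_that("trained-model discrimination is monotone in the planted effect size", {
  # medians over 3 seeds at increasing effect sizes
  betas <- c(0, 1, 2)
  aurocs <- sapply(c(101L, 102L, 103L), function(sd) {
    sapply(betas, function(b) {
      study <- small_study(seed = sd, beta = b)
      tr <- small_train(study, seed = sd, max_epochs = 50L)
      pr <- predict(tr$fit, study$cohort, cells = tr$folds$folds[[1]]$test)
      auroc(pr$score, pr$label)
    })
  })
  med <- apply(aurocs, 1, median)
  expect_true(all(diff(med) > -0.03))       # non-decreasing up to seed noise
  expect_gt(med[3], med[1])
  expect_gt(med[3], 0.6)
  expect_lt(abs(med[1] - 0.5), 0.15)
})
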