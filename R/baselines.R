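#' Build the matched fully connected network
#'
#' A dense feedforward network with the same depth as the pathway-structured
#' model and, at every hidden layer, the same total number of neurons (the
#' sum of block output sizes over the pathways at that level). It shares the
#' Mish/BatchNorm/Dropout stack, per-layer auxiliary heads and the root
#' head, so the two models are interchangeable in training and evaluation.
#'
#' @param hierarchy A `pathway_hierarchy` providing the size template.
#' @param feature_genes,target_genes Input layout, as in [compile_biovnn()].
#' @param seed Integer seed for initialization.
#' @return A `biovnn_model` with `kind = "fcn"`.
#' @export
build_matched_fcn <- function(hierarchy, feature_genes, target_genes,
                              seed = 1L) {
  k <- length(feature_genes)
  n <- length(target_genes)
  lv <- hierarchy$levels
  widths <- vapply(seq_len(hierarchy$n_levels), function(l) {
    ids <- names(lv)[lv == l]
    sum(block_output_size(vapply(hierarchy$pathways[ids],
                                 function(p) length(p$genes), 1L)))
  }, 1)
  rng <- local_rng(seed)
  blocks <- list()
  ids <- paste0("L", seq_along(widths))
  for (l in seq_along(widths)) {
    inputs <- if (l == 1L) {
      list(list(src = "x", idx = seq_len(k + n)))
    } else {
      list(list(src = ids[l - 1L], idx = NULL))
    }
    s_q <- if (l == 1L) k + n else widths[l - 1L]
    input_names <- if (l == 1L) {
      c(feature_genes, paste0("del:", target_genes))
    }
    blocks[[ids[l]]] <- rng(function()
      new_block(ids[l], l, inputs, s_q, widths[l], input_names,
                aux = l < length(widths)))
  }
  root_s <- widths[length(widths)]
  head <- rng(function() list(w = stats::rnorm(root_s, sd = sqrt(2 / root_s)),
                              b = 0))
  structure(
    list(kind = "fcn", blocks = blocks, order = ids,
         root = ids[length(ids)],
         head_w = head$w, head_b = head$b,
         k = k, n = n,
         feature_genes = feature_genes, target_genes = target_genes,
         alpha = 0.3, lambda = 1.0, dropout = 0.5,
         bn_momentum = 0.1, bn_eps = 1e-5,
         levels = stats::setNames(seq_along(ids), ids),
         fingerprint = hierarchy_fingerprint(hierarchy)),
    class = "biovnn_model")
}

#' Randomize gene-pathway memberships
#'
#' Replaces a fraction `p` of each non-root pathway's membership slots with
#' genes drawn uniformly from the global gene pool (without replacement
#' within a pathway, with replacement across pathways). Pathway count,
#' per-pathway sizes and the parent-child topology are untouched, so a model
#' compiled on the result has exactly the same parameter count; only the
#' biological meaning of the connections is destroyed. `p = 1` gives the
#' fully matched random-gene-group control.
#'
#' @param hierarchy A `pathway_hierarchy`.
#' @param fraction Shuffle fraction `p` in \[0, 1\].
#' @param seed Integer seed.
#' @param feature_genes,target_genes Optional cohort gene panels. When given,
#'   membership slots are swapped within strata defined by (is feature,
#'   is target), so each pathway keeps its exact count of expression inputs
#'   and deletion inputs and a model compiled on the result has an identical
#'   parameter count. Without them, slots swap against the whole pool.
#' @return A `pathway_hierarchy` with attributes `shuffle_fraction` and
#'   `shuffle_seed`.
#' @export
randomize_hierarchy <- function(hierarchy, fraction, seed = 1L,
                                feature_genes = NULL, target_genes = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) {
    out <- hierarchy
    attr(out, "shuffle_fraction") <- 0
    attr(out, "shuffle_seed") <- seed
    return(out)
  }
  pool <- hierarchy$gene_universe
  stratum <- paste0(as.integer(pool %in% feature_genes),
                    as.integer(pool %in% target_genes))
  names(stratum) <- pool
  rng <- local_rng(seed)
  out <- hierarchy
  for (id in setdiff(names(hierarchy$pathways), hierarchy$root)) {
    genes <- hierarchy$pathways[[id]]$genes
    size <- length(genes)
    n_swap <- round(fraction * size)
    if (n_swap == 0L) next
    swap_idx <- rng(function() sample(size, n_swap))
    kept <- genes[-swap_idx]
    new <- character(0)
    for (s in unique(stratum[genes[swap_idx]])) {
      originals <- genes[swap_idx][stratum[genes[swap_idx]] == s]
      n_s <- length(originals)
      candidates <- setdiff(pool[stratum == s], c(kept, new))
      if (length(candidates) < n_s) {       # tiny stratum: reuse originals
        candidates <- unique(c(candidates, originals))
      }
      new <- c(new, rng(function() sample(candidates, n_s)))
    }
    out$pathways[[id]]$genes <- sort(c(kept, new))
  }
  # the root keeps its original gene set: it only sizes the root block
  attr(out, "shuffle_fraction") <- fraction
  attr(out, "shuffle_seed") <- seed
  out
}

#' Expression-only baseline
#'
#' Scores each (cell line, target gene) pair directly by the z-scored
#' expression of the target gene itself, with the sign chosen by
#' validation-set AUROC per fold. Also reports the Pearson correlation
#' between expression and dependency probability. Target genes without
#' expression data are excluded with a warning.
#'
#' @param cohort A `cohort`.
#' @param folds A `fold_split` (from [stratified_folds()]).
#' @return An `evaluation_report` (see [evaluate_predictions()]) with an
#'   extra `correlation` element.
#' @export
expression_baseline <- function(cohort, folds) {
  targets <- intersect(cohort$target_genes, cohort$feature_genes)
  missing <- setdiff(cohort$target_genes, targets)
  if (length(missing)) {
    warning("target gene(s) without expression excluded: ",
            paste(missing, collapse = ", "))
  }
  if (length(targets) == 0L) stop("no target gene has expression data")
  pooled <- list()
  for (f in seq_along(folds$folds)) {
    fold <- folds$folds[[f]]
    zs <- zscore_by_training(cohort$expression, fold$train)
    score_block <- function(ids) {
      z <- zs$z[ids, targets, drop = FALSE]
      y <- cohort$labels[ids, targets, drop = FALSE]
      list(score = as.numeric(z), y = as.numeric(y),
           cell = rep(ids, times = length(targets)),
           target = rep(targets, each = length(ids)))
    }
    val <- score_block(fold$validation)
    sign <- if (auroc(-val$score, val$y) >= auroc(val$score, val$y)) -1 else 1
    te <- score_block(fold$test)
    pooled[[f]] <- data.frame(cell = te$cell, target = te$target,
                              score = sign * te$score, label = te$y,
                              fold = f, stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, pooled)
  rep <- evaluate_predictions(pooled)
  rep$correlation <- stats::cor(as.numeric(cohort$expression[, targets]),
                                as.numeric(cohort$dependency[, targets]))
  rep$kind <- "expression"
  rep
}
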