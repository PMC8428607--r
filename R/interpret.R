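#' Extract pathway neuron states for one target gene
#'
#' Runs the fitted model in inference mode over every cell line with the
#' given gene's deletion one-hot and records each pathway block's output
#' state, the predicted probability and the label. Deterministic: dropout is
#' off and normalization uses running statistics.
#'
#' @param fit A `biovnn_fit`.
#' @param cohort A `cohort`.
#' @param target_gene Target gene symbol.
#' @param cells Cell lines (default all).
#' @return Object of class `neuron_states`: list with `states` (named list of
#'   cell-by-neuron matrices, one per pathway), `prob`, `label`, `cells`,
#'   `target_gene`.
#' @export
extract_states <- function(fit, cohort, target_gene, cells = NULL) {
  if (is.null(cells)) cells <- rownames(cohort$expression)
  z <- apply_zscore(cohort$expression, fit$zstats)
  sm <- assemble_samples(z, cohort$labels, fit$masks, cells, target_gene)
  out <- forward_pass(fit$model, sm$x, collect_states = TRUE)
  states <- lapply(out$states, function(s) {
    rownames(s) <- cells
    s
  })
  structure(list(states = states, prob = out$prob, label = sm$y,
                 cells = cells, target_gene = target_gene),
            class = "neuron_states")
}

#' Principal components of one pathway's neuron states
#'
#' Centered (unscaled) PCA fit jointly on all cell lines; returns the first
#' two component scores.
#'
#' @param state_matrix Cell-by-neuron state matrix.
#' @return Matrix with columns `PC1`, `PC2`, rows = cell lines.
#' @export
pathway_pca <- function(state_matrix) {
  if (nrow(state_matrix) < 3L) stop("need at least 3 cell lines for PCA")
  if (ncol(state_matrix) < 2L) stop("state dimension must be >= 2")
  if (all(apply(state_matrix, 2L, stats::sd) == 0)) {
    stop("degenerate input: zero-variance neuron states")
  }
  pc <- stats::prcomp(state_matrix, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("PC1", "PC2")
  scores
}

#' Class-separation test on PCA-compressed neuron states
#'
#' Two-sided Mann-Whitney-Wilcoxon tests compare PC1 and PC2 between
#' dependent and nondependent cell lines; the two p-values are combined by
#' Fisher's method and the separation score is `-log10(combined p)`.
#'
#' @param pc_scores Matrix with PC1/PC2 columns from [pathway_pca()].
#' @param labels Binary labels per cell line.
#' @return List with `p_pc1`, `p_pc2`, `p_combined`, `score`.
#' @export
class_separation_test <- function(pc_scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("class separation undefined: both classes required")
  }
  p1 <- stats::wilcox.test(pc_scores[labels == 1, 1],
                           pc_scores[labels == 0, 1],
                           alternative = "two.sided", exact = FALSE)$p.value
  p2 <- stats::wilcox.test(pc_scores[labels == 1, 2],
                           pc_scores[labels == 0, 2],
                           alternative = "two.sided", exact = FALSE)$p.value
  stat <- -2 * (log(max(p1, 1e-300)) + log(max(p2, 1e-300)))
  p <- stats::pchisq(stat, df = 4, lower.tail = FALSE)
  list(p_pc1 = p1, p_pc2 = p2, p_combined = p, score = -log10(max(p, 1e-300)))
}

#' Class-separation table over all pathways for one target gene
#'
#' Runs [pathway_pca()] + [class_separation_test()] per pathway, flags
#' pathways containing the target gene as related, and BH-adjusts the
#' combined p-values across pathways.
#'
#' @param fit A `biovnn_fit`.
#' @param cohort A `cohort`.
#' @param target_gene Target gene symbol.
#' @param hierarchy The `pathway_hierarchy` the model was compiled on.
#' @return data.frame: `pathway`, `related`, `p_combined`, `p_adjusted`,
#'   `score`, `level`.
#' @export
separation_table <- function(fit, cohort, target_gene, hierarchy) {
  ns <- extract_states(fit, cohort, target_gene)
  related <- pathways_of_gene(hierarchy, target_gene)
  ids <- setdiff(names(ns$states), hierarchy$root)
  rows <- lapply(ids, function(id) {
    pc <- tryCatch(pathway_pca(ns$states[[id]]), error = function(e) NULL)
    if (is.null(pc)) return(NULL)
    ts <- class_separation_test(pc, ns$label)
    data.frame(pathway = id, related = id %in% related,
               p_combined = ts$p_combined, score = ts$score,
               level = hierarchy$levels[[id]], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_combined, method = "BH")
  tab
}

#' Related versus unrelated pathway class separation
#'
#' One-sided Mann-Whitney-Wilcoxon test of whether separation scores of
#' pathways containing the target gene exceed those of pathways that do not.
#' Genes involved in fewer than `min_related` pathways are skipped.
#'
#' @param sep_table Output of [separation_table()].
#' @param min_related Minimum number of related pathways (default 6).
#' @return List with `p` (one-sided), `n_related`, `n_unrelated`; or a
#'   `skipped` marker with the reason.
#' @export
related_vs_unrelated <- function(sep_table, min_related = 6L) {
  n_rel <- sum(sep_table$related)
  n_unrel <- sum(!sep_table$related)
  if (n_rel < min_related) {
    return(list(skipped = TRUE,
                reason = sprintf("only %d related pathways (< %d)", n_rel,
                                 min_related)))
  }
  if (n_unrel == 0L) {
    return(list(skipped = TRUE, reason = "no unrelated pathways"))
  }
  p <- stats::wilcox.test(sep_table$score[sep_table$related],
                          sep_table$score[!sep_table$related],
                          alternative = "greater", exact = FALSE)$p.value
  list(skipped = FALSE, p = p, n_related = n_rel, n_unrelated = n_unrel)
}

#' Explain one prediction by pathway-state z-scores
#'
#' For every related pathway, the PC1 score of the queried cell line is
#' converted to a z-score across the cohort and returned ordered from
#' lower-level to higher-level pathways (root last), the layout used for
#' state heatmaps.
#'
#' @param fit A `biovnn_fit`.
#' @param cohort A `cohort`.
#' @param cell Cell-line id.
#' @param target_gene Target gene symbol.
#' @param hierarchy The compile-time `pathway_hierarchy`.
#' @return data.frame: `pathway`, `level`, `z` (the cell's z-scored PC1),
#'   plus the predicted probability in the `"prob"` attribute.
#' @export
explain_prediction <- function(fit, cohort, cell, target_gene, hierarchy) {
  if (!cell %in% rownames(cohort$expression)) stop("unknown cell line ", cell)
  ns <- extract_states(fit, cohort, target_gene)
  related <- c(pathways_of_gene(hierarchy, target_gene), hierarchy$root)
  rows <- lapply(related, function(id) {
    pc1 <- tryCatch(pathway_pca(ns$states[[id]])[, 1], error = function(e) {
      s <- ns$states[[id]]
      s[, which.max(apply(s, 2, stats::sd))]    # 1-neuron fallback
    })
    z <- (pc1 - mean(pc1)) / stats::sd(pc1)
    data.frame(pathway = id, level = hierarchy$levels[[id]],
               z = z[[cell]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$level, out$pathway), ]
  rownames(out) <- NULL
  attr(out, "prob") <- ns$prob[match(cell, ns$cells)]
  out
}

#' Feature importance of input genes for one pathway
#'
#' Importance of input gene g for pathway t is the Euclidean norm of the
#' weight column connecting g's masked-expression input to t's first-layer
#' neurons. For interior pathways the importance is computed at the leaf
#' blocks of the subtree and summed per gene. Genes are flagged as reaction
#' partners of the target gene using the reaction set.
#'
#' @param fit A `biovnn_fit`.
#' @param target_gene Target gene symbol.
#' @param pathway Pathway id (must contain the target gene).
#' @param hierarchy The compile-time `pathway_hierarchy`.
#' @param reactions A `reaction_set` (optional; partner flags NA if absent).
#' @return data.frame: `gene`, `importance`, `partner`.
#' @export
feature_importance <- function(fit, target_gene, pathway, hierarchy,
                               reactions = NULL) {
  target_gene <- toupper(target_gene)
  if (!target_gene %in% hierarchy$pathways[[pathway]]$genes) {
    stop("pathway ", pathway, " does not contain target gene ", target_gene)
  }
  ids <- subtree_ids(hierarchy, pathway)
  leaves <- ids[vapply(ids, function(i)
    length(hierarchy$pathways[[i]]$children) == 0L, TRUE)]
  acc <- new.env()
  for (id in leaves) {
    bl <- fit$model$blocks[[id]]
    if (is.null(bl$input_names)) next
    expr_cols <- which(!startsWith(bl$input_names, "del:"))
    for (ci in expr_cols) {
      g <- bl$input_names[[ci]]
      norm <- sqrt(sum(bl$W[, ci]^2))
      acc[[g]] <- (if (is.null(acc[[g]])) 0 else acc[[g]]) + norm
    }
  }
  genes <- ls(acc)
  if (length(genes) == 0L) stop("no gene-level inputs under pathway ", pathway)
  imp <- vapply(genes, function(g) acc[[g]], 1)
  partner <- if (is.null(reactions)) {
    rep(NA, length(genes))
  } else {
    genes %in% reaction_partners(reactions, target_gene)
  }
  out <- data.frame(gene = genes, importance = as.numeric(imp),
                    partner = partner, stringsAsFactors = FALSE)
  out[out$gene != target_gene, , drop = FALSE]
}

#' Reaction-partner enrichment of feature importance
#'
#' For each (target gene, pathway) pair, a one-sided Mann-Whitney-Wilcoxon
#' test asks whether reaction partners of the target gene carry higher
#' importance than the pathway's other genes; p-values are BH-adjusted across
#' pairs. Pairs with fewer than `min_group` genes in either group are skipped.
#'
#' @param importance_tables Named list of data.frames from
#'   [feature_importance()]; names `"gene|pathway"`.
#' @param min_group Minimum group size (default 3).
#' @param alpha_adj Adjusted significance threshold for the `significant`
#'   flag (default 0.1).
#' @return data.frame: `pair`, `n_partner`, `n_other`, `p`, `p_adjusted`,
#'   `significant`, `top_nonpartner` (highest-importance non-partner gene, a
#'   candidate novel reaction component). Skipped pairs carry `NA` p with a
#'   `reason`.
#' @export
reaction_enrichment <- function(importance_tables, min_group = 3L,
                                alpha_adj = 0.1) {
  rows <- lapply(names(importance_tables), function(nm) {
    tab <- importance_tables[[nm]]
    np <- sum(tab$partner %in% TRUE)
    no <- sum(tab$partner %in% FALSE)
    if (np < min_group || no < min_group) {
      return(data.frame(pair = nm, n_partner = np, n_other = no, p = NA,
                        top_nonpartner = NA,
                        reason = "insufficient group sizes",
                        stringsAsFactors = FALSE))
    }
    p <- stats::wilcox.test(tab$importance[tab$partner %in% TRUE],
                            tab$importance[tab$partner %in% FALSE],
                            alternative = "greater", exact = FALSE)$p.value
    others <- tab[tab$partner %in% FALSE, ]
    data.frame(pair = nm, n_partner = np, n_other = no, p = p,
               top_nonpartner = others$gene[which.max(others$importance)],
               reason = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha_adj
  out
}

#' Pathway recovery from dense first-layer weights
#'
#' Asks whether a trained fully connected network rediscovers pathway-like
#' gene groups: each input gene's first-layer weight vector is
#' PCA-compressed, genes are k-means clustered with k = the number of
#' leaf-level pathways, and each cluster is tested for hypergeometric overlap
#' against every leaf pathway (BH-adjusted). The count of clusters
#' overlapping at least one pathway is compared with size-matched random gene
#' groups.
#'
#' @param fit A fitted FCN (`biovnn_fit` with `kind = "fcn"`).
#' @param hierarchy The `pathway_hierarchy` providing the leaf pathways.
#' @param n_pcs Number of principal components to keep (default 50, capped at
#'   the input rank).
#' @param seed Integer seed (k-means restarts and null simulations).
#' @param n_sim Number of size-matched random-group simulations (default 100).
#' @param alpha_adj Adjusted significance threshold (default 0.1).
#' @return List with `n_significant`, `n_clusters`, `null_mean`, `null_sd`,
#'   `z` (standardized excess over the null) and the per-cluster table.
#' @export
fcn_weight_clustering <- function(fit, hierarchy, n_pcs = 50L, seed = 1L,
                                  n_sim = 100L, alpha_adj = 0.1) {
  model <- fit$model
  if (model$kind != "fcn") stop("expected a fitted fully connected network")
  first <- model$blocks[[model$order[[1L]]]]
  expr_cols <- which(!startsWith(first$input_names, "del:"))
  genes <- first$input_names[expr_cols]
  Wg <- t(first$W[, expr_cols, drop = FALSE])    # gene x neuron
  leaf_ids <- names(hierarchy$levels)[hierarchy$levels == 1L]
  k <- length(leaf_ids)
  if (k > length(genes)) stop("k (", k, ") exceeds the number of genes")
  n_pcs <- min(n_pcs, ncol(Wg), nrow(Wg) - 1L)
  pcs <- stats::prcomp(Wg, center = TRUE)$x[, seq_len(n_pcs), drop = FALSE]
  rng <- local_rng(seed)
  cl <- rng(function() stats::kmeans(pcs, centers = k, nstart = 5L,
                                     iter.max = 50L))
  clusters <- split(genes, cl$cluster)
  count_sig <- function(clusters) {
    pvals <- lapply(clusters, function(members) {
      vapply(leaf_ids, function(pid) {
        pw <- intersect(hierarchy$pathways[[pid]]$genes, genes)
        ov <- length(intersect(members, pw))
        stats::phyper(ov - 1L, length(pw), length(genes) - length(pw),
                      length(members), lower.tail = FALSE)
      }, 1)
    })
    adj <- stats::p.adjust(unlist(pvals), method = "BH")
    adj_by_cluster <- split(adj, rep(seq_along(pvals),
                                     each = length(leaf_ids)))
    sig <- vapply(adj_by_cluster, function(a) any(a < alpha_adj), TRUE)
    sig
  }
  sig <- count_sig(clusters)
  sizes <- lengths(clusters)
  null_counts <- rng(function() vapply(seq_len(n_sim), function(s) {
    perm <- sample(genes)
    rnd <- split(perm, rep(seq_along(sizes), times = sizes))
    sum(count_sig(rnd))
  }, 1))
  list(n_significant = sum(sig), n_clusters = length(clusters),
       null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
       z = (sum(sig) - mean(null_counts)) /
         max(stats::sd(null_counts), .Machine$double.eps),
       clusters = data.frame(cluster = seq_along(clusters),
                             size = as.integer(sizes),
                             significant = as.logical(sig)))
}
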