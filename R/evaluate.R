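#' Area under the ROC curve
#'
#' Rank-based AUROC (equivalent to the Mann-Whitney U statistic scaled to
#' \[0, 1\]); ties are handled by midranks.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: precision is evaluated at every recall increment,
#' walking the ranking from the highest score down; tied scores are processed
#' as one group.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("AUPRC undefined: no positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # tie groups in rank order
  tp <- tapply(y, grp, sum)
  cnt <- tapply(rep(1, length(y)), grp, sum)
  tp_cum <- cumsum(tp)
  n_cum <- cumsum(cnt)
  precision <- tp_cum / n_cum
  recall <- tp_cum / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Pool predictions and compute overall and per-fold metrics
#'
#' @param predictions data.frame with columns `cell`, `target`, `score`,
#'   `label`, `fold`.
#' @param per_target Also compute per-target-gene AUROC where both classes
#'   are present (default FALSE).
#' @return Object of class `evaluation_report` with pooled `auroc`/`auprc`,
#'   `per_fold` metrics and the pooled `predictions`.
#' @export
evaluate_predictions <- function(predictions, per_target = FALSE) {
  per_fold <- do.call(rbind, lapply(sort(unique(predictions$fold)),
                                    function(f) {
    p <- predictions[predictions$fold == f, ]
    data.frame(fold = f, auroc = auroc(p$score, p$label),
               auprc = auprc(p$score, p$label), n = nrow(p))
  }))
  rep <- list(auroc = auroc(predictions$score, predictions$label),
              auprc = auprc(predictions$score, predictions$label),
              per_fold = per_fold,
              predictions = predictions)
  if (per_target) {
    tg <- unique(predictions$target)
    rep$per_target <- do.call(rbind, lapply(tg, function(t) {
      p <- predictions[predictions$target == t, ]
      if (length(unique(p$label)) < 2L) return(NULL)
      data.frame(target = t, auroc = auroc(p$score, p$label),
                 auprc = auprc(p$score, p$label))
    }))
  }
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation: pooled AUROC = %.3f, AUPRC = %.3f over %d samples\n",
              x$auroc, x$auprc, nrow(x$predictions)))
  if (!is.null(x$per_fold)) {
    cat(sprintf("  per-fold AUROC: %s\n",
                paste(sprintf("%.3f", x$per_fold$auroc), collapse = " ")))
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("  expression-dependency Pearson r = %.3f\n", x$correlation))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Metrics as JSON, pooled predictions as TSV.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(auroc = report$auroc, auprc = report$auprc,
                  per_fold = report$per_fold)
  if (!is.null(report$correlation)) metrics$correlation <- report$correlation
  json_path <- file.path(dir, "metrics.json")
  tsv_path <- file.path(dir, "predictions.tsv")
  jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.table(report$predictions, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Two-sided Mann-Whitney-Wilcoxon comparison of per-fold metrics
#'
#' Used to compare convergence epochs or per-fold AUROC/AUPRC between two
#' model kinds; exact p-values at these small sample sizes.
#'
#' @param a,b Numeric vectors (e.g. five per-fold values per model).
#' @param alternative Test sidedness (default two-sided).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_folds <- function(a, b, alternative = "two.sided") {
  stats::wilcox.test(a, b, alternative = alternative, exact = TRUE)
}

#' Time-stamped evaluation: train on an old cohort, test on new cell lines
#'
#' Each per-fold fitted model scores every (cell line, target) pair of the
#' new cohort, with the new expression z-scored by that fold's training
#' statistics from the old cohort. New cell lines must be disjoint from the
#' old cohort's; target genes absent from the new dependency data are skipped
#' with a warning.
#'
#' @param fits List of `biovnn_fit` objects (one per fold).
#' @param old_cohort The training-era `cohort`.
#' @param new_cohort The later-release `cohort` (same feature-gene columns).
#' @return An `evaluation_report`; `per_fold` carries one row per fold model
#'   scored on the full new cohort.
#' @export
timestamp_evaluate <- function(fits, old_cohort, new_cohort) {
  shared <- intersect(rownames(old_cohort$expression),
                      rownames(new_cohort$expression))
  if (length(shared)) {
    stop("new cohort shares cell lines with the old cohort: ",
         paste(utils::head(shared, 5L), collapse = ", "))
  }
  targets <- intersect(old_cohort$target_genes,
                       colnames(new_cohort$dependency))
  missing <- setdiff(old_cohort$target_genes, targets)
  if (length(missing)) {
    warning("target gene(s) absent from the new dependency data skipped: ",
            paste(missing, collapse = ", "))
  }
  preds <- list()
  for (f in seq_along(fits)) {
    fit <- fits[[f]]
    z <- apply_zscore(new_cohort$expression[, old_cohort$feature_genes,
                                            drop = FALSE], fit$zstats)
    sm <- assemble_samples(z, new_cohort$labels, fit$masks,
                           rownames(new_cohort$expression), targets)
    p <- forward_pass(fit$model, sm$x)$prob
    preds[[f]] <- data.frame(cell = sm$cell, target = sm$target,
                             score = p, label = sm$y, fold = f,
                             stringsAsFactors = FALSE)
  }
  evaluate_predictions(do.call(rbind, preds))
}
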