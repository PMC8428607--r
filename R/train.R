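#' Training configuration
#'
#' @param batch_size Mini-batch size (default 2000).
#' @param lr Learning rate (default 1e-3).
#' @param patience Early-stop patience in epochs of non-improving validation
#'   loss (default 2).
#' @param min_epochs Epochs to run before early stopping may trigger
#'   (default 10): inference-mode validation loss uses batch-norm running
#'   statistics, which need several epochs to adapt from their
#'   initialization, so stopping decisions before that are noise. Best-model
#'   tracking still covers all epochs.
#' @param max_epochs Safety bound on epochs (default 200).
#' @param seed Integer seed governing shuffling, dropout and initialization.
#' @param alpha Auxiliary-loss weight (default 0.3).
#' @param lambda L2 regularization factor (default 1), applied as decoupled
#'   weight decay on block weight matrices during optimization.
#' @param mask_cap Feature-mask cardinality cap (default 100).
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 2000L, lr = 1e-3, patience = 2L,
                            min_epochs = 10L, max_epochs = 200L, seed = 1L,
                            alpha = 0.3, lambda = 1.0, mask_cap = 100L) {
  stopifnot(patience >= 1L, batch_size >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), alpha = alpha, lambda = lambda,
                 mask_cap = as.integer(mask_cap)),
            class = "training_config")
}

#' Read a training configuration from a YAML file
#'
#' Keys mirror [training_config()] arguments; unknown keys error.
#'
#' @param path YAML file path.
#' @return A `training_config`.
#' @export
training_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(training_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(training_config, vals)
}

#' Write a per-epoch training trace as JSON lines
#'
#' One JSON object per epoch with the training and validation objective.
#'
#' @param fit A `biovnn_fit`.
#' @param path Output path.
#' @export
write_trace_jsonl <- function(fit, path) {
  lines <- vapply(seq_len(nrow(fit$trace)), function(i) {
    jsonlite::toJSON(as.list(fit$trace[i, ]), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

adam_init <- function(model) {
  st <- list(t = 0, blocks = list(), head_w_m = 0 * model$head_w,
             head_w_v = 0 * model$head_w, head_b_m = 0, head_b_v = 0)
  for (id in names(model$blocks)) {
    bl <- model$blocks[[id]]
    pn <- c("W", "b", "gamma", "beta",
            if (!is.null(bl$aux_w)) c("aux_w", "aux_b"))
    st$blocks[[id]] <- lapply(stats::setNames(pn, pn), function(p) {
      list(m = 0 * bl[[p]], v = 0 * bl[[p]])
    })
  }
  st
}

adam_update <- function(model, grads, st, lr, lambda,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  step <- function(theta, g, slot) {
    slot$m <- beta1 * slot$m + (1 - beta1) * g
    slot$v <- beta2 * slot$v + (1 - beta2) * g^2
    theta_new <- theta - lr * (slot$m / corr1) / (sqrt(slot$v / corr2) + eps)
    list(theta = theta_new, slot = slot)
  }
  for (id in names(model$blocks)) {
    for (p in names(st$blocks[[id]])) {
      g <- grads$blocks[[id]][[p]]
      if (is.null(g)) next
      up <- step(model$blocks[[id]][[p]], g, st$blocks[[id]][[p]])
      model$blocks[[id]][[p]] <- up$theta
      st$blocks[[id]][[p]] <- up$slot
    }
    # decoupled weight decay realizes the lambda * ||W||^2 penalty
    model$blocks[[id]]$W <- model$blocks[[id]]$W * (1 - lr * lambda)
  }
  up <- step(model$head_w, grads$head_w,
             list(m = st$head_w_m, v = st$head_w_v))
  model$head_w <- up$theta
  st$head_w_m <- up$slot$m; st$head_w_v <- up$slot$v
  up <- step(model$head_b, grads$head_b,
             list(m = st$head_b_m, v = st$head_b_v))
  model$head_b <- up$theta
  st$head_b_m <- up$slot$m; st$head_b_v <- up$slot$v
  list(model = model, st = st)
}

#' Train a model on one cross-validation fold
#'
#' Mini-batch optimization with Adam, early stopping on the validation
#' objective (without the regularization term), negative-class weighting by
#' the training positives/negatives ratio, and restoration of the
#' best-validation checkpoint. All randomness (shuffling, dropout) is driven
#' by `config$seed`.
#'
#' @param model A compiled `biovnn_model`.
#' @param cohort A `cohort`.
#' @param fold One element of `stratified_folds()$folds`.
#' @param config A `training_config`.
#' @param masks Feature-mask matrix from [build_feature_masks()].
#' @return Object of class `biovnn_fit`: the trained model plus the training
#'   trace, fold, masks and z-score statistics.
#' @export
train_model <- function(model, cohort, fold, config = training_config(),
                        masks) {
  stopifnot(length(intersect(fold$train, fold$validation)) == 0L)
  model$alpha <- config$alpha
  model$lambda <- config$lambda
  zs <- zscore_by_training(cohort$expression, fold$train)
  tr <- assemble_samples(zs$z, cohort$labels, masks, fold$train)
  va <- assemble_samples(zs$z, cohort$labels, masks, fold$validation)
  n_pos <- sum(tr$y == 1)
  n_neg <- sum(tr$y == 0)
  if (n_pos == 0L || n_neg == 0L) stop("training set must contain both classes")
  neg_weight <- n_pos / n_neg
  N <- nrow(tr$x)
  rng <- local_rng(config$seed)
  st <- adam_init(model)
  best <- list(loss = Inf, model = model, epoch = 0L)
  bad_epochs <- 0L
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(config$max_epochs)) {
    perm <- rng(function() sample.int(N))
    batch_losses <- numeric(0)
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, N)]
      xb <- tr$x[idx, , drop = FALSE]
      yb <- tr$y[idx]
      out <- rng(function()
        forward_pass(model, xb, training = TRUE, keep_cache = TRUE))
      model <- out$model                    # running BN statistics advance
      l <- model_loss(model, out, yb, neg_weight, include_reg = FALSE)
      if (!is.finite(l)) {
        stop(sprintf("non-finite loss at epoch %d, batch starting %d", epoch,
                     start))
      }
      batch_losses <- c(batch_losses, l)
      grads <- backward_pass(model, out, yb, neg_weight)
      up <- adam_update(model, grads, st, config$lr, config$lambda)
      model <- up$model
      st <- up$st
    }
    val_out <- forward_pass(model, va$x)
    val_loss <- model_loss(model, val_out, va$y, neg_weight,
                           include_reg = FALSE)
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_loss = val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, model = model, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (epoch >= config$min_epochs && bad_epochs >= config$patience) break
    }
  }
  structure(
    list(model = best$model, trace = trace,
         best_epoch = best$epoch, best_val_loss = best$loss,
         stopping_epoch = nrow(trace),
         wall_time = proc.time()[["elapsed"]] - t0,
         neg_weight = neg_weight, fold = fold, masks = masks,
         zstats = list(mean = zs$mean, sd = zs$sd),
         config = config),
    class = "biovnn_fit")
}

#' @export
print.biovnn_fit <- function(x, ...) {
  cat(sprintf("Fitted %s model: converged at epoch %d (stopped after %d), val loss %.4f\n",
              toupper(x$model$kind), x$best_epoch, x$stopping_epoch,
              x$best_val_loss))
  invisible(x)
}

#' @export
summary.biovnn_fit <- function(object, ...) {
  cat(sprintf("%s fit\n", toupper(object$model$kind)))
  cat(sprintf("  parameters: %d\n", count_parameters(object$model)))
  cat(sprintf("  epochs run: %d, best epoch: %d, best validation loss: %.4f\n",
              object$stopping_epoch, object$best_epoch, object$best_val_loss))
  cat(sprintf("  train / validation cell lines: %d / %d\n",
              length(object$fold$train), length(object$fold$validation)))
  cat(sprintf("  negative-class weight: %.3f\n", object$neg_weight))
  invisible(object)
}

#' @export
coef.biovnn_fit <- function(object, ...) {
  lapply(object$model$blocks, `[[`, "W")
}

#' @export
plot.biovnn_fit <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$train_loss, tr$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "objective", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict dependency probabilities for (cell line, target gene) pairs
#'
#' @param object A `biovnn_fit`.
#' @param cohort A `cohort` containing the cell lines to score (expression is
#'   z-scored with the fit's stored training statistics).
#' @param cells Cell-line ids (default: all in `cohort`).
#' @param targets Target genes (default: all the fit knows).
#' @param ... Unused.
#' @return data.frame with `cell`, `target`, `score` and, when labels exist,
#'   `label`.
#' @export
predict.biovnn_fit <- function(object, cohort, cells = NULL, targets = NULL,
                               ...) {
  if (is.null(cells)) cells <- rownames(cohort$expression)
  if (is.null(targets)) targets <- rownames(object$masks)
  z <- apply_zscore(cohort$expression, object$zstats)
  sm <- assemble_samples(z, cohort$labels, object$masks, cells, targets)
  p <- forward_pass(object$model, sm$x)$prob
  out <- data.frame(cell = sm$cell, target = sm$target, score = p,
                    stringsAsFactors = FALSE)
  if (!is.null(sm$y)) out$label <- sm$y
  out
}

#' Run five-fold cross-validation for one model kind
#'
#' Trains one model per fold and pools the test-set predictions into a single
#' report, the protocol behind all model comparisons.
#'
#' @param kind One of `"biovnn"`, `"fcn"`, `"random"`, `"expression"`.
#' @param cohort A `cohort`.
#' @param hierarchy A `pathway_hierarchy`.
#' @param config A `training_config`.
#' @param folds Optional precomputed `fold_split` (defaults to
#'   [stratified_folds()] with `config$seed`).
#' @param fraction Membership shuffle fraction for `kind = "random"`
#'   (default 1, the fully randomized control).
#' @return List of class `cv_run` with `kind`, `fits`, `report`
#'   (an `evaluation_report` with pooled predictions), `epochs` (best epoch
#'   per fold) and `folds`.
#' @export
run_cross_validation <- function(kind = c("biovnn", "fcn", "random",
                                          "expression"),
                                 cohort, hierarchy,
                                 config = training_config(),
                                 folds = NULL, fraction = 1) {
  kind <- match.arg(kind)
  if (is.null(folds)) {
    folds <- stratified_folds(cohort, seed = config$seed)
  }
  if (kind == "expression") {
    rep <- expression_baseline(cohort, folds)
    return(structure(list(kind = kind, fits = NULL, report = rep,
                          epochs = NULL, folds = folds), class = "cv_run"))
  }
  arch <- if (kind == "random") {
    randomize_hierarchy(hierarchy, fraction, seed = config$seed,
                        feature_genes = cohort$feature_genes,
                        target_genes = cohort$target_genes)
  } else {
    hierarchy
  }
  masks <- build_feature_masks(cohort, arch, cap = config$mask_cap)
  fits <- vector("list", length(folds$folds))
  preds <- vector("list", length(folds$folds))
  for (f in seq_along(folds$folds)) {
    fold_seed <- (config$seed * 131L + f * 7919L) %% 2147483647L
    model <- if (kind == "fcn") {
      build_matched_fcn(arch, cohort$feature_genes, cohort$target_genes,
                        seed = fold_seed)
    } else {
      compile_biovnn(arch, cohort$feature_genes, cohort$target_genes,
                     seed = fold_seed)
    }
    cfg <- config
    cfg$seed <- fold_seed
    fit <- tryCatch(
      train_model(model, cohort, folds$folds[[f]], cfg, masks),
      error = function(e) stop("fold ", f, " failed: ", conditionMessage(e)))
    fits[[f]] <- fit
    pr <- predict(fit, cohort, cells = folds$folds[[f]]$test)
    pr$fold <- f
    preds[[f]] <- pr
  }
  pooled <- do.call(rbind, preds)
  names(pooled)[names(pooled) == "label"] <- "label"
  rep <- evaluate_predictions(pooled)
  structure(list(kind = kind, fits = fits, report = rep,
                 epochs = vapply(fits, `[[`, 1L, "best_epoch"),
                 folds = folds),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  cat(sprintf("Cross-validation (%s): ", x$kind))
  print(x$report)
  if (!is.null(x$epochs)) {
    cat("  epochs to converge per fold:", paste(x$epochs, collapse = " "),
        "\n")
  }
  invisible(x)
}
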