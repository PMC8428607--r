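#' Mish activation
#'
#' The smooth, nonmonotonic activation `x * tanh(softplus(x))`, applied
#' elementwise.
#'
#' @param x Numeric vector/matrix.
#' @return Same shape as `x`.
#' @export
mish <- function(x) {
  x * tanh(softplus(x))
}

softplus <- function(x) {
  # log(1 + exp(x)) in the overflow-safe branch-free form
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) {
  1 / (1 + exp(-pmin(pmax(x, -30), 30)))
}

mish_grad <- function(x) {
  sp <- softplus(x)
  t <- tanh(sp)
  t + x * (1 - t^2) * sigmoid(x)
}

kaiming <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

new_block <- function(id, level, inputs, s_q, s_o, input_names = NULL,
                      aux = TRUE) {
  list(id = id, level = level, inputs = inputs, s_q = s_q, s_o = s_o,
       input_names = input_names,
       W = kaiming(s_o, s_q), b = numeric(s_o),
       gamma = rep(1, s_o), beta = numeric(s_o),
       run_mean = numeric(s_o), run_var = rep(1, s_o),
       aux_w = if (aux) stats::rnorm(s_o, sd = sqrt(2 / s_o)),
       aux_b = if (aux) 0)
}

#' Pathway-block output size
#'
#' `max(10, ceiling(0.3 * n_genes))`: blocks of larger pathways get more
#' neurons because their representation is harder to learn; 10 is the floor,
#' reached by every pathway with fewer than 34 genes.
#'
#' @param n_genes Number of member genes of the pathway.
#' @return Integer output size.
#' @export
block_output_size <- function(n_genes) {
  pmax(10L, as.integer(ceiling(0.3 * n_genes)))
}

#' Compile a pathway hierarchy into a sparse visible neural network
#'
#' One neuron block per pathway. Leaf-level blocks read the masked-expression
#' entries of their member genes plus the deletion-status bits of their
#' member target genes; interior blocks read the concatenated output states
#' of their child pathways (children at non-adjacent levels pass their state
#' through unchanged). No connection links a gene to a pathway not containing
#' it, nor a pathway to a non-parent. Weights are Kaiming-initialized.
#'
#' @param hierarchy A validated `pathway_hierarchy`.
#' @param feature_genes Ordered feature-gene list (defines input layout).
#' @param target_genes Ordered target-gene list (deletion one-hot layout).
#' @param seed Integer seed for initialization.
#' @return Object of class `biovnn_model`.
#' @export
compile_biovnn <- function(hierarchy, feature_genes, target_genes, seed = 1L) {
  validate_hierarchy(hierarchy)
  k <- length(feature_genes)
  n <- length(target_genes)
  ids <- names(hierarchy$pathways)
  ord <- ids[order(hierarchy$levels[ids], ids)]
  rng <- local_rng(seed)
  blocks <- list()
  for (id in ord) {
    p <- hierarchy$pathways[[id]]
    lvl <- hierarchy$levels[[id]]
    is_root <- id == hierarchy$root
    if (length(p$children) == 0L) {
      expr_genes <- intersect(p$genes, feature_genes)
      del_genes <- intersect(p$genes, target_genes)
      if (length(expr_genes) + length(del_genes) == 0L) {
        stop("leaf pathway ", id, " has no feature or target member genes")
      }
      idx <- c(match(expr_genes, feature_genes),
               k + match(del_genes, target_genes))
      inputs <- list(list(src = "x", idx = idx))
      s_q <- length(idx)
      input_names <- c(expr_genes, paste0("del:", del_genes))
    } else {
      inputs <- lapply(p$children, function(ch) list(src = ch, idx = NULL))
      s_q <- sum(vapply(p$children, function(ch) blocks[[ch]]$s_o, 1L))
      input_names <- NULL
    }
    s_o <- block_output_size(length(p$genes))
    blocks[[id]] <- rng(function()
      new_block(id, lvl, inputs, s_q, s_o, input_names, aux = !is_root))
  }
  root_s <- blocks[[hierarchy$root]]$s_o
  head <- rng(function() list(w = stats::rnorm(root_s, sd = sqrt(2 / root_s)),
                              b = 0))
  structure(
    list(kind = "biovnn", blocks = blocks, order = ord,
         root = hierarchy$root,
         head_w = head$w, head_b = head$b,
         k = k, n = n,
         feature_genes = feature_genes, target_genes = target_genes,
         alpha = 0.3, lambda = 1.0, dropout = 0.5,
         bn_momentum = 0.1, bn_eps = 1e-5,
         levels = hierarchy$levels,
         fingerprint = hierarchy_fingerprint(hierarchy)),
    class = "biovnn_model")
}

#' @export
print.biovnn_model <- function(x, ...) {
  cat(sprintf("%s model: %d blocks over %d levels, input width %d (k=%d, n=%d)\n",
              toupper(x$kind), length(x$blocks),
              max(vapply(x$blocks, `[[`, 1L, "level")), x$k + x$n, x$k, x$n))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums all trainable weights and biases: block linear layers, batch-norm
#' scale/shift, auxiliary heads and the root head. Running batch-norm
#' statistics are buffers, not parameters.
#'
#' @param model A `biovnn_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (length(model$blocks) == 0L) stop("model has no blocks")
  total <- sum(vapply(model$blocks, function(bl) {
    length(bl$W) + length(bl$b) + length(bl$gamma) + length(bl$beta) +
      length(bl$aux_w) + length(bl$aux_b)
  }, 1))
  as.integer(total + length(model$head_w) + 1L)
}

gather_input <- function(model, states, x, block) {
  parts <- lapply(block$inputs, function(inp) {
    if (inp$src == "x") x[, inp$idx, drop = FALSE] else states[[inp$src]]
  })
  do.call(cbind, parts)
}

#' Forward pass
#'
#' Evaluates blocks in level order. In training mode batch normalization uses
#' batch statistics (updating running buffers) and dropout is active; in
#' inference mode running statistics are used and the pass is deterministic.
#'
#' @param model A `biovnn_model`.
#' @param x Sample matrix, one row per sample, width `k + n`.
#' @param training Logical; training mode.
#' @param collect_states Return every block's output state.
#' @param keep_cache Keep intermediate quantities for backprop.
#' @return List with `prob` (root probability per sample), `aux` (named list
#'   of auxiliary probabilities), optionally `states` and `cache`, and
#'   `model` (with updated running statistics when training).
#' @export
forward_pass <- function(model, x, training = FALSE, collect_states = FALSE,
                         keep_cache = FALSE) {
  if (ncol(x) != model$k + model$n) {
    stop(sprintf("input width %d does not match model width %d",
                 ncol(x), model$k + model$n))
  }
  N <- nrow(x)
  states <- list()
  cache <- if (keep_cache) list()
  aux <- list()
  for (id in model$order) {
    bl <- model$blocks[[id]]
    Q <- gather_input(model, states, x, bl)
    Z <- Q %*% t(bl$W)
    Z <- Z + rep(bl$b, each = N)
    A <- mish(Z)
    if (training) {
      mu <- colMeans(A)
      Ac <- A - rep(mu, each = N)
      v <- colMeans(Ac^2)                          # biased batch variance
      Ahat <- Ac * rep(1 / sqrt(v + model$bn_eps), each = N)
      model$blocks[[id]]$run_mean <-
        (1 - model$bn_momentum) * bl$run_mean + model$bn_momentum * mu
      model$blocks[[id]]$run_var <-
        (1 - model$bn_momentum) * bl$run_var +
        model$bn_momentum * v * N / max(N - 1L, 1L)
    } else {
      mu <- bl$run_mean
      v <- bl$run_var
      Ahat <- (A - rep(mu, each = N)) *
        rep(1 / sqrt(v + model$bn_eps), each = N)
    }
    H <- Ahat * rep(bl$gamma, each = N) + rep(bl$beta, each = N)
    if (training && model$dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= model$dropout,
                     nrow(H), ncol(H))
      O <- H * mask / (1 - model$dropout)
    } else {
      mask <- NULL
      O <- H
    }
    states[[id]] <- O
    if (!is.null(bl$aux_w)) {
      ua <- as.numeric(O %*% bl$aux_w + bl$aux_b)
      aux[[id]] <- sigmoid(ua)
      attr(aux[[id]], "logit") <- ua
    }
    if (keep_cache) {
      cache[[id]] <- list(Q = Q, Z = Z, Ahat = Ahat, mask = mask,
                          var = v, training = training)
    }
  }
  u <- as.numeric(states[[model$root]] %*% model$head_w + model$head_b)
  out <- list(prob = sigmoid(u), root_logit = u, aux = aux, model = model)
  if (collect_states) out$states <- states
  if (keep_cache) {
    out$cache <- cache
    out$states <- states
  }
  out
}

# logit-space binary cross-entropy, negative class weighted
wbce <- function(u, y, neg_weight) {
  w <- ifelse(y == 1, 1, neg_weight)
  mean(w * (softplus(u) - y * u))
}

#' Objective value
#'
#' Weighted binary cross-entropy at the root head, plus the `alpha`-scaled
#' sum of every pathway's auxiliary cross-entropy, plus `lambda` times the
#' summed squared Frobenius norm of the block weight matrices. The negative
#' class is weighted by the training-set positives/negatives ratio.
#'
#' @param model A `biovnn_model`.
#' @param out Output of [forward_pass()] on the same model.
#' @param y Binary label vector.
#' @param neg_weight Weight applied to negative-class samples.
#' @param include_reg Include the `lambda`-scaled regularization term
#'   (default TRUE); early stopping monitors the objective without it.
#' @return Scalar loss.
#' @export
model_loss <- function(model, out, y, neg_weight = 1, include_reg = TRUE) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  aux_logits <- lapply(names(out$aux), function(id) {
    lg <- attr(out$aux[[id]], "logit")
    if (is.null(lg)) stats::qlogis(pmin(pmax(out$aux[[id]], 1e-12), 1 - 1e-12))
    else lg
  })
  loss <- wbce(out$root_logit, y, neg_weight) +
    model$alpha * sum(vapply(aux_logits, wbce, 1, y = y,
                             neg_weight = neg_weight))
  if (include_reg) loss <- loss + model$lambda * weight_sq_norm(model)
  loss
}

#' Summed squared norm of block weight matrices
#'
#' @param model A `biovnn_model`.
#' @return Scalar `sum_t ||W^t||^2` (heads and biases excluded).
#' @export
weight_sq_norm <- function(model) {
  sum(vapply(model$blocks, function(bl) sum(bl$W^2), 1))
}

# Backward pass. Returns per-block parameter gradients, head gradients and,
# when want_dx, the gradient w.r.t. the input matrix. `seed_dO` optionally
# injects the output-side gradient at one block (for input-sparsity probes)
# instead of the loss gradients.
backward_pass <- function(model, out, y = NULL, neg_weight = 1,
                          want_dx = FALSE, seed_dO = NULL) {
  cache <- out$cache
  states <- out$states
  N <- nrow(states[[model$root]])
  dO <- lapply(states, function(s) matrix(0, nrow(s), ncol(s)))
  grads <- list(blocks = list(), head_w = NULL, head_b = NULL)

  if (is.null(seed_dO)) {
    w <- ifelse(y == 1, 1, neg_weight)
    dU <- w * (out$prob - y) / N
    grads$head_w <- as.numeric(t(states[[model$root]]) %*% dU)
    grads$head_b <- sum(dU)
    dO[[model$root]] <- dO[[model$root]] + outer(dU, model$head_w)
    for (id in names(out$aux)) {
      bl <- model$blocks[[id]]
      dUa <- model$alpha * w * (out$aux[[id]] - y) / N
      grads$blocks[[id]] <- list(aux_w = as.numeric(t(states[[id]]) %*% dUa),
                                 aux_b = sum(dUa))
      dO[[id]] <- dO[[id]] + outer(dUa, bl$aux_w)
    }
  } else {
    for (id in names(seed_dO)) dO[[id]] <- dO[[id]] + seed_dO[[id]]
  }

  dx <- if (want_dx) matrix(0, N, model$k + model$n)
  for (id in rev(model$order)) {
    bl <- model$blocks[[id]]
    cc <- cache[[id]]
    d <- dO[[id]]
    if (!is.null(cc$mask)) d <- d * cc$mask / (1 - model$dropout)
    # batch norm backward
    Nb <- nrow(d)
    dgamma <- colSums(d * cc$Ahat)
    dbeta <- colSums(d)
    dAhat <- d * rep(bl$gamma, each = Nb)
    istd <- 1 / sqrt(cc$var + model$bn_eps)
    if (isTRUE(cc$training)) {
      m1 <- colMeans(dAhat)
      m2 <- colMeans(dAhat * cc$Ahat)
      dA <- (dAhat - rep(m1, each = Nb) - cc$Ahat * rep(m2, each = Nb)) *
        rep(istd, each = Nb)
    } else {
      dA <- dAhat * rep(istd, each = Nb)
    }
    dZ <- dA * mish_grad(cc$Z)
    g <- grads$blocks[[id]]
    g$W <- t(dZ) %*% cc$Q
    g$b <- colSums(dZ)
    g$gamma <- dgamma
    g$beta <- dbeta
    grads$blocks[[id]] <- g
    dQ <- dZ %*% bl$W
    off <- 0L
    for (inp in bl$inputs) {
      wdt <- if (inp$src == "x") length(inp$idx) else ncol(states[[inp$src]])
      slice <- dQ[, off + seq_len(wdt), drop = FALSE]
      if (inp$src == "x") {
        if (want_dx) dx[, inp$idx] <- dx[, inp$idx] + slice
      } else {
        dO[[inp$src]] <- dO[[inp$src]] + slice
      }
      off <- off + wdt
    }
  }
  grads$dx <- dx
  grads
}

#' Gradient of one pathway block's state with respect to the input
#'
#' Probes the network's structural sparsity: the gradient of the summed
#' output state of `block_id` is exactly zero for every input coordinate
#' outside that pathway's gene closure. Runs in inference mode.
#'
#' @param model A `biovnn_model`.
#' @param x Input matrix (rows = samples).
#' @param block_id Block (pathway) id; defaults to the root head output.
#' @return Gradient matrix of the same shape as `x`.
#' @export
state_input_gradient <- function(model, x, block_id = NULL) {
  out <- forward_pass(model, x, training = FALSE, keep_cache = TRUE)
  if (is.null(block_id)) {
    N <- nrow(x)
    seed <- stats::setNames(
      list(matrix(rep(model$head_w, each = N),
                  N, length(model$head_w))), model$root)
  } else {
    s <- out$states[[block_id]]
    seed <- stats::setNames(list(matrix(1, nrow(s), ncol(s))), block_id)
  }
  backward_pass(model, out, seed_dO = seed, want_dx = TRUE)$dx
}

#' Save a model checkpoint
#'
#' Serializes weights together with the hierarchy fingerprint so checkpoints
#' refuse to load onto a mismatched ontology.
#'
#' @param model A `biovnn_model` (or `biovnn_fit`).
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint, verifying the ontology fingerprint
#'
#' @param path Checkpoint path.
#' @param hierarchy The `pathway_hierarchy` the model is to be used with.
#' @return The stored model.
#' @export
load_checkpoint <- function(path, hierarchy) {
  obj <- readRDS(path)
  model <- if (inherits(obj, "biovnn_fit")) obj$model else obj
  fp <- hierarchy_fingerprint(hierarchy)
  if (!identical(model$fingerprint, fp) && model$kind != "fcn") {
    stop("checkpoint fingerprint ", model$fingerprint,
         " does not match hierarchy fingerprint ", fp)
  }
  obj
}
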