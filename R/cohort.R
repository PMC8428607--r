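#' Read a cell-line-by-gene matrix from CSV/TSV
#'
#' Expects the DepMap orientation: first column the cell-line id, header row
#' the gene symbols. Gene symbols are uppercased; annotation suffixes like
#' `"TP53 (7157)"` are stripped to the symbol.
#'
#' @param path CSV or TSV file path (delimiter sniffed from the extension).
#' @return Numeric matrix, rows = cell lines, columns = genes.
#' @export
read_matrix_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  colnames(m) <- toupper(sub(" *\\(.*\\)$", "", colnames(m)))
  storage.mode(m) <- "double"
  m
}

#' Read a two-column cell line to tissue map
#'
#' @param path TSV with columns cell line id, tissue label (no header).
#' @return Named character vector (names = cell-line ids).
#' @export
read_tissue_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Select feature genes by expression level and ontology membership
#'
#' Keeps genes whose log2(TPM+1) expression exceeds `min_value` in at least
#' `ceil(min_fraction * m)` cell lines and which belong to the pathway gene
#' universe.
#'
#' @param expression Cell-line-by-gene matrix of log2(TPM+1) values.
#' @param ontology_genes Gene universe of the pathway hierarchy.
#' @param min_value Expression threshold (default 1.0).
#' @param min_fraction Minimum fraction of cell lines above threshold
#'   (default 0.01).
#' @return Ordered character vector of retained gene symbols (matrix column
#'   order preserved).
#' @export
filter_feature_genes <- function(expression, ontology_genes,
                                 min_value = 1.0, min_fraction = 0.01) {
  m <- nrow(expression)
  need <- ceiling(min_fraction * m)
  n_hi <- colSums(expression > min_value)
  keep <- colnames(expression)[n_hi >= need]
  keep <- keep[keep %in% toupper(ontology_genes)]
  if (length(keep) == 0L) {
    stop("no gene passes the expression filter within the ontology universe")
  }
  keep
}

#' Select target genes by label balance, ontology and druggability
#'
#' Binarizes dependency probabilities at 0.5 (>= 0.5 positive) and keeps
#' genes with at least `min_pos` positive and `min_neg` negative cell lines
#' that are in the ontology universe and, if supplied, the druggable list.
#' The balance floors exclude genes that are nearly always (non)dependent,
#' whose evaluation would be unstable.
#'
#' @param dependency Cell-line-by-gene matrix of dependency probabilities in
#'   \[0, 1\].
#' @param ontology_genes Gene universe of the pathway hierarchy.
#' @param druggable Optional character vector of druggable gene symbols.
#' @param min_pos,min_neg Minimum positive/negative sample counts (default 6).
#' @return Ordered character vector of target genes.
#' @export
select_target_genes <- function(dependency, ontology_genes, druggable = NULL,
                                min_pos = 6L, min_neg = 6L) {
  labels <- dependency >= 0.5
  n_pos <- colSums(labels)
  n_neg <- colSums(!labels)
  keep <- colnames(dependency)[n_pos >= min_pos & n_neg >= min_neg]
  keep <- keep[keep %in% toupper(ontology_genes)]
  if (!is.null(druggable)) keep <- keep[keep %in% toupper(druggable)]
  if (length(keep) == 0L) {
    stop("no target gene satisfies the label-balance / ontology / druggability filters")
  }
  keep
}

#' Assemble a model-ready cohort
#'
#' Applies the feature-gene and target-gene filters and packages the matrices
#' with binarized labels and tissue annotations.
#'
#' @param expression Cell-line-by-gene log2(TPM+1) matrix.
#' @param dependency Cell-line-by-gene dependency probability matrix (same
#'   cell lines).
#' @param hierarchy A `pathway_hierarchy`.
#' @param tissues Optional named character vector cell line -> tissue; a
#'   single dummy tissue is used if absent.
#' @param druggable Optional druggable gene list.
#' @param min_pos,min_neg,min_value,min_fraction Filter settings, see
#'   [select_target_genes()] and [filter_feature_genes()].
#' @return Object of class `cohort` with elements `expression` (m x k,
#'   feature genes), `dependency` and `labels` (m x n, target genes),
#'   `tissues`, `feature_genes`, `target_genes`.
#' @export
build_cohort <- function(expression, dependency, hierarchy, tissues = NULL,
                         druggable = NULL, min_pos = 6L, min_neg = 6L,
                         min_value = 1.0, min_fraction = 0.01) {
  stopifnot(identical(rownames(expression), rownames(dependency)))
  if (anyNA(expression) || anyNA(dependency)) {
    stop("expression/dependency matrices must not contain NA")
  }
  universe <- hierarchy$gene_universe
  feature_genes <- filter_feature_genes(expression, universe,
                                        min_value, min_fraction)
  target_genes <- select_target_genes(dependency, universe, druggable,
                                      min_pos, min_neg)
  if (is.null(tissues)) {
    tissues <- stats::setNames(rep("all", nrow(expression)),
                               rownames(expression))
  }
  tissues <- tissues[rownames(expression)]
  structure(
    list(expression = expression[, feature_genes, drop = FALSE],
         dependency = dependency[, target_genes, drop = FALSE],
         labels = (dependency[, target_genes, drop = FALSE] >= 0.5) * 1L,
         tissues = tissues,
         feature_genes = feature_genes,
         target_genes = target_genes),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d cell lines, %d feature genes, %d target genes, %d tissue(s)\n",
              nrow(x$expression), length(x$feature_genes),
              length(x$target_genes), length(unique(x$tissues))))
  cat(sprintf("  positive-label fraction: %.3f\n", mean(x$labels)))
  invisible(x)
}

#' Build the pathway-guided feature mask for one target gene
#'
#' Keeps only feature genes sharing a pathway with the target gene, taken
#' from the smallest pathway to the largest (smaller pathways encode stronger
#' relationships) until `cap` genes are selected. Ties in pathway size break
#' by pathway id; if the cap is crossed mid-pathway, that pathway's remaining
#' genes are added in sorted-symbol order until the cap is reached.
#'
#' @param target_gene Gene symbol.
#' @param hierarchy A `pathway_hierarchy`.
#' @param feature_genes Ordered feature-gene list (mask index space).
#' @param cap Maximum mask cardinality (default 100).
#' @return Integer 0/1 vector of length `length(feature_genes)`, named by
#'   gene.
#' @export
build_feature_mask <- function(target_gene, hierarchy, feature_genes,
                               cap = 100L) {
  target_gene <- toupper(target_gene)
  pws <- pathways_of_gene(hierarchy, target_gene, include_root = FALSE)
  if (length(pws) == 0L) {
    pws <- if (target_gene %in% hierarchy$pathways[[hierarchy$root]]$genes) {
      hierarchy$root
    } else {
      stop("target gene ", target_gene,
           " belongs to no pathway; cannot build a feature mask")
    }
  }
  sizes <- vapply(pws, function(p) length(hierarchy$pathways[[p]]$genes), 1L)
  pws <- pws[order(sizes, pws)]
  selected <- character(0)
  for (p in pws) {
    members <- sort(intersect(hierarchy$pathways[[p]]$genes, feature_genes))
    new <- setdiff(members, selected)
    room <- cap - length(selected)
    if (room <= 0L) break
    selected <- c(selected, new[seq_len(min(room, length(new)))])
  }
  mask <- as.integer(feature_genes %in% selected)
  names(mask) <- feature_genes
  mask
}

#' Feature masks for every target gene
#'
#' @param cohort A `cohort`.
#' @param hierarchy A `pathway_hierarchy`.
#' @param cap Mask cardinality cap (default 100).
#' @return Matrix n targets x k feature genes of 0/1 masks.
#' @export
build_feature_masks <- function(cohort, hierarchy, cap = 100L) {
  masks <- t(vapply(cohort$target_genes, build_feature_mask,
                    integer(length(cohort$feature_genes)),
                    hierarchy = hierarchy,
                    feature_genes = cohort$feature_genes, cap = cap))
  rownames(masks) <- cohort$target_genes
  masks
}

#' Z-score expression by training statistics
#'
#' Per gene, subtracts the training-set mean and divides by the training-set
#' standard deviation; genes constant in the training set map to 0
#' everywhere. Validation/test rows never influence the transform.
#'
#' @param expression Cell-line-by-gene matrix (all splits).
#' @param training_ids Cell-line ids of the training set.
#' @return List with `z` (transformed matrix), `mean`, `sd` (the training
#'   statistics, reusable on future cohorts).
#' @export
zscore_by_training <- function(expression, training_ids) {
  stopifnot(length(training_ids) > 0L)
  tr <- expression[training_ids, , drop = FALSE]
  mu <- colMeans(tr)
  sd <- apply(tr, 2L, stats::sd)
  z <- sweep(expression, 2L, mu, "-")
  nz <- sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sd[nz], "/")
  z[, !nz] <- 0
  list(z = z, mean = mu, sd = sd)
}

#' Apply stored z-score statistics to a new expression matrix
#'
#' @param expression New cell-line-by-gene matrix (same gene columns).
#' @param stats List with `mean` and `sd` from [zscore_by_training()].
#' @return Transformed matrix.
#' @export
apply_zscore <- function(expression, stats) {
  z <- sweep(expression[, names(stats$mean), drop = FALSE], 2L, stats$mean, "-")
  nz <- stats$sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, stats$sd[nz], "/")
  z[, !nz] <- 0
  z
}

#' Class- and tissue-balanced five-fold split by cell line
#'
#' Cell lines are grouped by tissue, shuffled with `seed`, ordered within
#' tissue by their positive-label fraction and dealt round-robin into
#' `n_folds` folds, which balances tissue composition and class prevalence
#' simultaneously. Per fold f: test = fold f; the remaining lines split into
#' training and validation at 4:1, giving the 3.2:0.8:1 overall ratio.
#'
#' @param cohort A `cohort`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `fold_split`: list with `assignment` (named
#'   integer fold id per cell line) and `folds`, a list of
#'   `list(train, validation, test)` id vectors.
#' @export
stratified_folds <- function(cohort, n_folds = 5L, seed = 1L) {
  cells <- rownames(cohort$expression)
  if (length(cells) < n_folds) {
    stop("fewer cell lines (", length(cells), ") than folds (", n_folds, ")")
  }
  pos_frac <- rowMeans(cohort$labels)
  assignment <- stats::setNames(integer(length(cells)), cells)
  rng <- local_rng(seed)
  counter <- 0L
  for (tissue in sort(unique(cohort$tissues))) {
    ids <- cells[cohort$tissues == tissue]
    ids <- rng(function() sample(ids))       # seeded shuffle breaks ties
    ids <- ids[order(pos_frac[ids])]          # class balance via sorted deal
    for (id in ids) {
      assignment[[id]] <- (counter %% n_folds) + 1L
      counter <- counter + 1L
    }
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- cells[assignment == f]
    rest_folds <- c(seq_len(n_folds)[-f])
    # rotate so the fold after f contributes validation lines first
    rest_folds <- rest_folds[order((rest_folds - f) %% n_folds)]
    rest <- unlist(lapply(rest_folds, function(g) cells[assignment == g]),
                   use.names = FALSE)
    n_val <- round(length(rest) / 5)
    # deal every 4th line to validation to retain tissue/class balance
    val_idx <- unique(round(seq(1L, length(rest), length.out = n_val)))
    list(train = rest[-val_idx], validation = rest[val_idx], test = test)
  })
  structure(list(assignment = assignment, folds = folds, n_folds = n_folds,
                 seed = seed),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  sizes <- vapply(x$folds, function(f)
    c(length(f$train), length(f$validation), length(f$test)), numeric(3))
  cat(sprintf("%d-fold split (seed %d); train/validation/test sizes:\n",
              x$n_folds, x$seed))
  for (i in seq_len(ncol(sizes))) {
    cat(sprintf("  fold %d: %d / %d / %d\n", i, sizes[1, i], sizes[2, i],
                sizes[3, i]))
  }
  invisible(x)
}

#' Assemble input samples for a set of cell lines and target genes
#'
#' One sample per (cell line, target gene) pair: the z-scored expression
#' vector masked by the target's pathway filter, concatenated with the
#' one-hot deletion-status vector marking the knocked-out gene.
#'
#' @param zexpr Z-scored expression matrix (m x k).
#' @param labels Binary label matrix (m x n), or NULL for unlabeled scoring.
#' @param masks Mask matrix from [build_feature_masks()] (n x k).
#' @param cell_ids Cell lines to include.
#' @param target_genes Target genes to include (default: all rows of
#'   `masks`).
#' @return List with `x` ((m*n) x (k+n) input matrix), `y` (label vector or
#'   NULL), `cell` and `target` id vectors aligned with rows.
#' @export
assemble_samples <- function(zexpr, labels, masks, cell_ids,
                             target_genes = rownames(masks)) {
  k <- ncol(zexpr)
  n <- nrow(masks)
  all_targets <- rownames(masks)
  blocks <- vector("list", length(target_genes))
  for (j in seq_along(target_genes)) {
    tg <- target_genes[[j]]
    xm <- sweep(zexpr[cell_ids, , drop = FALSE], 2L, masks[tg, ], "*")
    onehot <- matrix(0, nrow(xm), n)
    onehot[, match(tg, all_targets)] <- 1
    blocks[[j]] <- cbind(xm, onehot)
  }
  x <- do.call(rbind, blocks)
  colnames(x) <- c(colnames(zexpr), paste0("del:", all_targets))
  cell <- rep(cell_ids, times = length(target_genes))
  target <- rep(target_genes, each = length(cell_ids))
  y <- if (!is.null(labels)) {
    as.numeric(labels[cbind(match(cell, rownames(labels)),
                            match(target, colnames(labels)))])
  }
  list(x = x, y = y, cell = cell, target = target)
}

# run `f` under a private RNG stream without disturbing the global stream
local_rng <- function(seed) {
  state <- NULL
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(state)) set.seed(seed) else {
      assign(".Random.seed", state, envir = globalenv())
    }
    f()
  }
}
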