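# Toy signaling hierarchy: P1 {G1,G2,G3,G7}, P2 {G4,G5}, P3 {G3,G6},
# P4 {G3,G7}, P5 {G5,G6}; P7 parent of P1/P2, P6 parent of P3/P4/P5;
# P6/P7 carry their descendants' genes. With every gene relevant and
# min_genes = 1 this yields 7 pathways plus a synthetic root.
toy_sets <- function() {
  list(P1 = c("G1", "G2", "G3", "G7"), P2 = c("G4", "G5"),
       P3 = c("G3", "G6"), P4 = c("G3", "G7"), P5 = c("G5", "G6"),
       P6 = c("G3", "G5", "G6", "G7"),
       P7 = c("G1", "G2", "G3", "G4", "G5", "G7"))
}

toy_edges <- function() {
  data.frame(child = c("P1", "P2", "P3", "P4", "P5"),
             parent = c("P7", "P7", "P6", "P6", "P6"),
             stringsAsFactors = FALSE)
}

toy_hierarchy <- function() {
  filter_pathways(toy_sets(), toy_edges(),
                  relevant_genes = paste0("G", 1:7), min_genes = 1L)
}

toy_genes <- function() paste0("G", 1:7)

# A compiled toy model: 7 feature genes, 2 target genes (G3, G7)
toy_model <- function(seed = 3L) {
  compile_biovnn(toy_hierarchy(), toy_genes(), c("G3", "G7"), seed = seed)
}

# Small planted study for fast training tests
small_study <- function(seed = 1L, ...) {
  cfg <- synthetic_config(n_genes = 80L, n_pathways = 12L,
                          n_cell_lines = 80L, n_target_genes = 3L,
                          seed = seed, ...)
  generate_synthetic_study(cfg)
}

small_train <- function(study, seed = 1L, fold = 1L, max_epochs = 60L) {
  folds <- stratified_folds(study$cohort, seed = seed)
  arch <- study$hierarchy
  masks <- build_feature_masks(study$cohort, arch)
  model <- compile_biovnn(arch, study$cohort$feature_genes,
                          study$cohort$target_genes, seed = seed)
  fit <- train_model(model, study$cohort, folds$folds[[fold]],
                     training_config(seed = seed, batch_size = 32L,
                                     min_epochs = min(30L, max_epochs),
                                     max_epochs = max_epochs), masks)
  list(fit = fit, folds = folds, masks = masks)
}

# brute-force AUROC: fraction of (pos, neg) pairs correctly ordered,
# ties counted half
bruteforce_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force AUPRC: walk the full ranking one sample at a time and
# accumulate precision at each recall increment
bruteforce_auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  # average tied blocks by treating ties as a single threshold step
  s <- scores[ord]
  steps <- which(!duplicated(s))
  ends <- c(steps[-1] - 1L, length(s))
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  tp <- 0; seen <- 0
  for (b in seq_along(steps)) {
    idx <- steps[b]:ends[b]
    tp <- tp + sum(y[idx])
    seen <- seen + length(idx)
    recall <- tp / n_pos
    precision <- tp / seen
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
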