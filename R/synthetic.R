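#' Configuration for the synthetic study generator
#'
#' Defines a toy pathway hierarchy and a cohort with a planted
#' pathway-dependent dependency mechanism: expression carries per-pathway
#' latent factors so co-members correlate, and each target gene's dependency
#' is driven by the reaction-subset genes of its driver pathway.
#'
#' @param n_genes Gene pool size (default 200).
#' @param n_pathways Number of non-root pathways (default 30).
#' @param n_levels Hierarchy depth including the root (default 4).
#' @param leaf_size Range of leaf pathway sizes (default c(8, 15)).
#' @param n_cell_lines Cohort size m (default 300).
#' @param n_target_genes Number of dependency targets (default 6).
#' @param beta Effect size of the planted signal (default 2).
#' @param label_noise Standard deviation of noise added to the dependency
#'   linear predictor (default 0.5).
#' @param rho Latent factor loading; the expression correlation between
#'   genes whose only pathway is a shared one (default 0.4, the order of
#'   within-pathway co-expression seen in real cell-line panels; it also
#'   keeps the planted signal specific to the reaction subset rather than
#'   readable from any pathway member).
#' @param prevalence Target positive-label fraction (default 0.3).
#' @param low_expr_frac Fraction of genes generated at low expression so the
#'   feature filter has nontrivial behavior (default 0.08).
#' @param n_tissues Number of tissue groups (default 3).
#' @param extra_parent_prob Probability a pathway gains a second parent,
#'   making the hierarchy a DAG rather than a tree (default 0.2).
#' @param reaction_frac Range of the fraction of a pathway's members marked
#'   as its reaction subset (default c(0.3, 0.5)).
#' @param seed Integer master seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L, n_pathways = 30L, n_levels = 4L,
                             leaf_size = c(8L, 15L), n_cell_lines = 300L,
                             n_target_genes = 6L, beta = 2, label_noise = 0.5,
                             rho = 0.4, prevalence = 0.3,
                             low_expr_frac = 0.08, n_tissues = 3L,
                             extra_parent_prob = 0.2,
                             reaction_frac = c(0.3, 0.5), seed = 1L) {
  stopifnot(n_levels >= 2L, n_genes > max(leaf_size),
            n_target_genes >= 1L, rho >= 0, rho <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a random layered pathway hierarchy with reactions
#'
#' Leaves sample genes without replacement; parents group children (their
#' gene sets are the unions of their children's); a single root tops the
#' hierarchy. Each leaf pathway gets one marked "reaction" subset of 30-50%
#' of its members. Each target gene is planted into three distinct leaf
#' pathways — its driver (whose reaction subset it joins) plus two others —
#' so that every target has enough related pathways for the
#' related-vs-unrelated analysis.
#'
#' @param config A `synthetic_config`.
#' @return List with `hierarchy` (a `pathway_hierarchy`), `reactions`
#'   (a `reaction_set`) and `targets` (data.frame `gene`, `driver`).
#' @export
generate_hierarchy <- function(config) {
  rng <- local_rng(config$seed)
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  n_pw_levels <- config$n_levels - 1L
  raw_w <- 2^-(seq_len(n_pw_levels) - 1L)
  counts <- pmax(1L, round(config$n_pathways * raw_w / sum(raw_w)))
  counts[1L] <- counts[1L] + (config$n_pathways - sum(counts))
  if (counts[1L] < config$n_target_genes) {
    stop("infeasible: fewer leaf pathways than target genes")
  }
  ids_by_level <- lapply(seq_len(n_pw_levels), function(l) {
    sprintf("P%d_%02d", l, seq_len(counts[l]))
  })

  sets <- list()
  for (id in ids_by_level[[1L]]) {
    size <- rng(function() sample(config$leaf_size[1]:config$leaf_size[2], 1L))
    sets[[id]] <- rng(function() sample(genes, size))
  }

  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  for (l in seq_len(n_pw_levels)) {
    upper <- if (l < n_pw_levels) ids_by_level[[l + 1L]] else "ROOT"
    kids <- ids_by_level[[l]]
    # every upper pathway gets at least one child; remaining kids random
    first <- rng(function() sample(kids, min(length(upper), length(kids))))
    par_of <- stats::setNames(rep(NA_character_, length(kids)), kids)
    par_of[first] <- upper[seq_along(first)]
    rest <- kids[is.na(par_of)]
    par_of[rest] <- rng(function()
      sample(upper, length(rest), replace = TRUE))
    edges <- rbind(edges, data.frame(child = kids, parent = par_of[kids],
                                     stringsAsFactors = FALSE))
    if (l < n_pw_levels) {
      extra <- rng(function()
        kids[stats::runif(length(kids)) < config$extra_parent_prob])
      for (ch in extra) {
        cand <- setdiff(upper, par_of[[ch]])
        if (length(cand)) {
          edges <- rbind(edges, data.frame(
            child = ch, parent = rng(function() sample(cand, 1L)),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  edges <- unique(edges[edges$parent != "ROOT", , drop = FALSE])

  # plant target genes: driver leaf + two other leaves each
  drivers <- rng(function()
    sample(ids_by_level[[1L]], config$n_target_genes))
  target_genes <- character(config$n_target_genes)
  for (i in seq_len(config$n_target_genes)) {
    d <- drivers[[i]]
    cand <- setdiff(sets[[d]], target_genes)
    target_genes[[i]] <- rng(function() sample(cand, 1L))
    others <- rng(function() sample(setdiff(ids_by_level[[1L]], d), 2L))
    for (o in others) {
      sets[[o]] <- unique(c(sets[[o]], target_genes[[i]]))
    }
  }

  # interior gene sets: union over children (computed bottom-up)
  children_of <- split(edges$child, edges$parent)
  for (l in seq_len(n_pw_levels)[-1L]) {
    for (id in ids_by_level[[l]]) {
      ch <- children_of[[id]]
      sets[[id]] <- sort(unique(unlist(sets[ch], use.names = FALSE)))
    }
  }

  hierarchy <- filter_pathways(sets, edges,
                               relevant_genes = genes, min_genes = 1L)

  reactions <- list()
  for (i in seq_along(ids_by_level[[1L]])) {
    id <- ids_by_level[[1L]][[i]]
    members <- hierarchy$pathways[[id]]$genes
    frac <- rng(function()
      stats::runif(1L, config$reaction_frac[1], config$reaction_frac[2]))
    size <- max(2L, ceiling(frac * length(members)))
    sub <- rng(function() sample(members, size))
    if (id %in% drivers) {                 # driver reactions carry the target
      tg <- target_genes[match(id, drivers)]
      if (!tg %in% sub) sub <- c(sub[-1L], tg)
    }
    reactions[[paste0("RX_", id)]] <- sort(sub)
  }

  list(hierarchy = hierarchy, reactions = reaction_set(reactions),
       targets = data.frame(gene = target_genes, driver = drivers,
                            stringsAsFactors = FALSE))
}

#' Generate a cohort with a planted pathway-dependent mechanism
#'
#' Expression: per-leaf-pathway latent factors plus gene noise, mapped
#' through a softplus onto a nonnegative, right-skewed log2(TPM+1)-like
#' scale. Each leaf pathway carries a shared factor plus two role factors
#' (reaction subset vs complement): same-role co-members correlate at `rho`,
#' mixed pairs at `rho/2`. Dependency of target gene j:
#' `sigmoid(beta * s + noise - theta)`, where s is the standardized mean
#' latent expression of the driver pathway's reaction subset and theta fixes
#' the positive prevalence. Because the reaction factor is carried by the
#' subset only, the planted signal is specific to the reaction partners —
#' the premise the importance analyses must rediscover. Labels are the
#' 0.5-binarization.
#'
#' Gene-level parameters (baseline expression, low-expression genes) derive
#' from `config$seed` only, so cohorts drawn with different `cohort_seed`
#' values (e.g. a later "future" release) come from the identical process.
#'
#' @param generated Output of [generate_hierarchy()].
#' @param config The `synthetic_config` used to generate the hierarchy.
#' @param cohort_seed Seed for the cell-line-level draws (default
#'   `config$seed`).
#' @param n_cell_lines Number of cell lines (default `config$n_cell_lines`).
#' @param cell_prefix Prefix for cell-line ids.
#' @return List with `expression` (m x n_genes), `dependency` (m x targets),
#'   `tissues` (named vector) and `latent` (the gene-level latent matrix,
#'   for diagnostics).
#' @export
generate_cohort <- function(generated, config,
                            cohort_seed = config$seed,
                            n_cell_lines = config$n_cell_lines,
                            cell_prefix = "C") {
  hierarchy <- generated$hierarchy
  reactions <- generated$reactions
  targets <- generated$targets
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  leaf_ids <- names(hierarchy$levels)[hierarchy$levels == 1L]

  # gene-level parameters: fixed across cohorts drawn from this config
  grng <- local_rng((config$seed * 7L + 13L) %% 2147483647L)
  mu <- grng(function() stats::rnorm(config$n_genes, mean = 3, sd = 0.25))
  names(mu) <- genes
  signal_genes <- unique(c(targets$gene,
                           unlist(unclass(reactions), use.names = FALSE)))
  low_cand <- setdiff(genes, signal_genes)
  n_low <- round(config$low_expr_frac * config$n_genes)
  low <- grng(function() sample(low_cand, min(n_low, length(low_cand))))
  mu[low] <- -2

  crng <- local_rng((cohort_seed * 17L + 101L) %% 2147483647L)
  cells <- sprintf("%s%04d", cell_prefix, seq_len(n_cell_lines))
  # three independent factors per leaf pathway: a shared pathway factor, a
  # reaction-subset factor and a complement factor. Partners load on the
  # first two, other members on the first and third, so co-members of the
  # same reaction role correlate at rho, mixed pairs at rho/2, and the
  # dependency-driving component (pathway + reaction factor) is carried by
  # the reaction subset specifically.
  nf <- length(leaf_ids)
  Fp <- crng(function() matrix(stats::rnorm(n_cell_lines * nf),
                               n_cell_lines, nf,
                               dimnames = list(cells, leaf_ids)))
  Frx <- crng(function() matrix(stats::rnorm(n_cell_lines * nf),
                                n_cell_lines, nf,
                                dimnames = list(cells, leaf_ids)))
  Fnon <- crng(function() matrix(stats::rnorm(n_cell_lines * nf),
                                 n_cell_lines, nf,
                                 dimnames = list(cells, leaf_ids)))
  membership <- lapply(leaf_ids, function(id) hierarchy$pathways[[id]]$genes)
  names(membership) <- leaf_ids
  rx_members <- lapply(leaf_ids, function(id) {
    rid <- paste0("RX_", id)
    if (rid %in% names(unclass(reactions))) unclass(reactions)[[rid]]
    else character(0)
  })
  names(rx_members) <- leaf_ids
  Z <- crng(function()
    matrix(stats::rnorm(n_cell_lines * length(genes)), n_cell_lines,
           length(genes), dimnames = list(cells, genes)))
  for (g in genes) {
    in_leaves <- leaf_ids[vapply(membership, function(m) g %in% m, TRUE)]
    if (length(in_leaves)) {
      terms <- vapply(in_leaves, function(id) {
        role <- if (g %in% rx_members[[id]]) Frx[, id] else Fnon[, id]
        (Fp[, id] + role) / sqrt(2)
      }, numeric(n_cell_lines))
      fac <- rowSums(terms) / sqrt(length(in_leaves))
      Z[, g] <- sqrt(config$rho) * fac + sqrt(1 - config$rho) * Z[, g]
    }
  }
  expression <- softplus(sweep(Z, 2L, mu[genes], "+"))
  dimnames(expression) <- list(cells, genes)

  theta <- stats::qnorm(1 - config$prevalence, mean = 0,
                        sd = sqrt(config$beta^2 + config$label_noise^2))
  dependency <- matrix(0, n_cell_lines, nrow(targets),
                       dimnames = list(cells, targets$gene))
  for (i in seq_len(nrow(targets))) {
    subset <- unclass(reactions)[[paste0("RX_", targets$driver[i])]]
    s <- rowMeans(Z[, subset, drop = FALSE])
    s <- s / stats::sd(s)
    noise <- crng(function() stats::rnorm(n_cell_lines,
                                          sd = config$label_noise))
    dependency[, i] <- sigmoid(config$beta * s + noise - theta)
  }

  tissues <- if (config$n_tissues > 1L) {
    km <- crng(function() stats::kmeans(Fp, centers = config$n_tissues,
                                        nstart = 3L))
    stats::setNames(paste0("T", km$cluster), cells)
  } else {
    stats::setNames(rep("T1", n_cell_lines), cells)
  }

  list(expression = expression, dependency = dependency, tissues = tissues,
       latent = Z)
}

#' Generate a complete synthetic study
#'
#' Hierarchy + reactions + cohort, assembled into a model-ready `cohort` via
#' the standard feature/target filters. Optionally adds a disjoint "future"
#' cohort drawn from the identical generative process, for time-stamped
#' evaluation.
#'
#' @param config A `synthetic_config`.
#' @param n_future Number of future-cohort cell lines (0 = none).
#' @return List with `hierarchy`, `reactions`, `targets`, `cohort`, `raw`
#'   (the unfiltered matrices) and optionally `future` (+ `future_raw`).
#' @export
generate_synthetic_study <- function(config = synthetic_config(),
                                     n_future = 0L) {
  gen <- generate_hierarchy(config)
  raw <- generate_cohort(gen, config)
  cohort <- build_cohort(raw$expression, raw$dependency, gen$hierarchy,
                         tissues = raw$tissues)
  out <- list(hierarchy = gen$hierarchy, reactions = gen$reactions,
              targets = gen$targets, cohort = cohort, raw = raw,
              config = config)
  if (n_future > 0L) {
    fraw <- generate_cohort(gen, config,
                            cohort_seed = (config$seed * 31L + 7L) %%
                              2147483647L,
                            n_cell_lines = n_future, cell_prefix = "F")
    out$future_raw <- fraw
    out$future <- build_cohort(fraw$expression, fraw$dependency,
                               gen$hierarchy, tissues = fraw$tissues,
                               min_pos = 0L, min_neg = 0L)
    # align the future cohort to the training-era gene/target panels
    out$future$expression <- fraw$expression[, cohort$feature_genes,
                                             drop = FALSE]
    out$future$dependency <- fraw$dependency[, cohort$target_genes,
                                             drop = FALSE]
    out$future$labels <- (out$future$dependency >= 0.5) * 1L
    out$future$feature_genes <- cohort$feature_genes
    out$future$target_genes <- cohort$target_genes
  }
  out
}

#' Write a synthetic study to plain-text files
#'
#' Emits the GMT gene sets, hierarchy TSV, reaction TSV, expression and
#' dependency CSVs, tissue TSV and a JSON manifest recording the
#' configuration.
#'
#' @param study Output of [generate_synthetic_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- study$hierarchy
  paths <- c(gmt = file.path(dir, "pathways.gmt"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             reactions = file.path(dir, "reactions.tsv"),
             expression = file.path(dir, "expression.csv"),
             dependency = file.path(dir, "dependency.csv"),
             tissues = file.path(dir, "tissues.tsv"),
             manifest = file.path(dir, "manifest.json"))
  sets <- lapply(h$pathways, `[[`, "genes")
  write_gmt(sets[setdiff(names(sets), h$root)], paths[["gmt"]])
  edges <- do.call(rbind, lapply(h$pathways, function(p) {
    if (length(p$parents) == 0L) return(NULL)
    data.frame(child = p$id, parent = p$parents, stringsAsFactors = FALSE)
  }))
  edges <- edges[edges$parent != h$root, , drop = FALSE]
  utils::write.table(edges, paths[["hierarchy"]], sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(vapply(names(unclass(study$reactions)), function(id) {
    paste(c(id, unclass(study$reactions)[[id]]), collapse = "\t")
  }, ""), paths[["reactions"]])
  utils::write.csv(study$raw$expression, paths[["expression"]])
  utils::write.csv(study$raw$dependency, paths[["dependency"]])
  utils::write.table(data.frame(names(study$raw$tissues),
                                study$raw$tissues),
                     paths[["tissues"]], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(study$config), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
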