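#' Parse a GMT pathway gene-set file
#'
#' Reads the standard GMT format: one pathway per line, tab-separated fields
#' `id`, `description`, then one or more gene symbols. Gene symbols are
#' uppercased and whitespace-stripped; duplicates within a line collapse to a
#' set.
#'
#' @param path Path to a GMT file.
#' @return Named list mapping pathway id to a character vector of unique gene
#'   symbols. Pathway descriptions are kept in the `"descriptions"` attribute.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- structure(list(), descriptions = character(0))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1L]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    g <- toupper(trimws(f[-c(1L, 2L)]))
    unique(g[nzchar(g)])
  })
  names(sets) <- ids
  names(desc) <- ids
  structure(sets, descriptions = desc)
}

#' Write pathway gene sets to a GMT file
#'
#' @param sets Named list of gene vectors (as from [parse_gmt()]).
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the pathway id.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id])) {
      descriptions[[id]]
    } else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a pathway hierarchy relation file
#'
#' Two tab-separated columns per line: child pathway id, parent pathway id.
#' Duplicate edges collapse; self-edges are rejected.
#'
#' @param path Path to the relation TSV.
#' @return A data.frame with columns `child` and `parent` (unique edges).
#' @export
parse_hierarchy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed hierarchy line %d: expected 2 tab-separated columns",
                 bad[1L]))
  }
  child <- trimws(vapply(fields, `[[`, "", 1L))
  parent <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(child == parent)) {
    stop(sprintf("self-edge in hierarchy at line %d: '%s'",
                 which(child == parent)[1L], child[child == parent][1L]))
  }
  unique(data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}

#' Parse a reaction membership file
#'
#' Each line maps one reaction id to its member genes (tab-separated).
#' Reactions describe finer gene-gene relationships (binding, activation,
#' translocation, ...) than pathways; they are used only to validate feature
#' importance, never to build the network. Reactions with fewer than two
#' genes are dropped with a warning.
#'
#' @param path Path to the reaction TSV (reaction id, then genes).
#' @return An object of class `reaction_set`: a named list of gene vectors.
#' @export
parse_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) {
    g <- toupper(trimws(f[-1L]))
    unique(g[nzchar(g)])
  })
  names(sets) <- ids
  small <- vapply(sets, length, 1L) < 2L
  if (any(small)) {
    warning(sprintf("dropped %d reaction(s) with fewer than 2 genes",
                    sum(small)))
    sets <- sets[!small]
  }
  reaction_set(sets)
}

#' Construct a reaction set
#'
#' @param sets Named list mapping reaction id to a gene vector (each >= 2
#'   genes).
#' @return Object of class `reaction_set`.
#' @export
reaction_set <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) && any(vapply(sets, length, 1L) < 2L)) {
    stop("every reaction must have at least 2 genes")
  }
  structure(sets, class = "reaction_set")
}

#' Reaction partners of a gene
#'
#' The union of co-members over every reaction that contains `gene`.
#'
#' @param reactions A `reaction_set`.
#' @param gene Gene symbol.
#' @return Character vector of partner genes (excluding `gene` itself).
#' @export
reaction_partners <- function(reactions, gene) {
  gene <- toupper(gene)
  hits <- vapply(unclass(reactions), function(g) gene %in% g, TRUE)
  setdiff(unique(unlist(unclass(reactions)[hits], use.names = FALSE)), gene)
}

# topological order, leaves first; errors on a cycle
topo_order <- function(ids, parents_of) {
  indeg <- vapply(ids, function(id) length(parents_of[[id]]), 1L)
  # we orient edges child -> parent, so process nodes whose children are done
  children_of <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents_of[[id]]) {
      children_of[[p]] <- c(children_of[[p]], id)
    }
  }
  n_children <- vapply(ids, function(id) length(children_of[[id]]), 1L)
  remaining <- n_children
  queue <- ids[remaining == 0L]
  out <- character(0)
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, id)
    for (p in parents_of[[id]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids)) {
    stop("cycle detected in pathway hierarchy")
  }
  out
}

#' Filter pathways and build the layered hierarchy
#'
#' Restricts pathway gene sets to the relevant genes (feature genes plus
#' target genes), keeps pathways with at least `min_genes` relevant members,
#' restricts hierarchy edges to survivors, attaches orphaned pathways to a
#' single root, validates acyclicity and assigns levels by longest path from
#' the leaf side (leaves at level 1, root at `n_levels`). The level layering
#' templates the network: a pathway's block is evaluated after all of its
#' children.
#'
#' @param raw Named list of pathway gene sets (from [parse_gmt()]).
#' @param edges data.frame with `child`, `parent` columns (from
#'   [parse_hierarchy()]).
#' @param relevant_genes Character vector: the union of feature and target
#'   genes.
#' @param min_genes Minimum number of relevant member genes to retain a
#'   pathway (default 5).
#' @param root_id Id used for the root. If a pathway with this id exists it
#'   is used as the root; otherwise a synthetic root whose gene set is the
#'   union of all retained pathways is created.
#' @return Object of class `pathway_hierarchy` with elements `pathways`
#'   (named list of `list(id, name, genes, parents, children)`), `root`,
#'   `levels` (named integer, root = max), `n_levels` and `gene_universe`.
#' @export
filter_pathways <- function(raw, edges, relevant_genes, min_genes = 5L,
                            root_id = "ROOT") {
  relevant_genes <- unique(toupper(relevant_genes))
  restricted <- lapply(raw, function(g) intersect(toupper(g), relevant_genes))
  keep <- names(restricted)[vapply(restricted, length, 1L) >= min_genes]
  keep <- setdiff(keep, root_id)        # root handled explicitly below
  if (length(keep) == 0L) {
    stop("no pathway retains at least ", min_genes, " relevant genes")
  }
  edges <- edges[edges$child %in% keep & edges$parent %in% keep, , drop = FALSE]

  ids <- c(keep, root_id)
  parents_of <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    parents_of[[edges$child[i]]] <-
      unique(c(parents_of[[edges$child[i]]], edges$parent[i]))
  }
  # orphans (no surviving parent) re-attach to the root
  for (id in keep) {
    if (length(parents_of[[id]]) == 0L) parents_of[[id]] <- root_id
  }
  parents_of[[root_id]] <- character(0)

  ord <- topo_order(ids, parents_of)

  children_of <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents_of[[id]]) {
      children_of[[p]] <- c(children_of[[p]], id)
    }
  }

  root_genes <- if (root_id %in% names(restricted)) {
    intersect(toupper(raw[[root_id]]), relevant_genes)
  } else {
    sort(unique(unlist(restricted[keep], use.names = FALSE)))
  }
  if (length(root_genes) == 0L) root_genes <- relevant_genes

  gene_sets <- c(restricted[keep], stats::setNames(list(root_genes), root_id))
  desc <- attr(raw, "descriptions")

  levels <- stats::setNames(integer(length(ids)), ids)
  for (id in ord) {                      # leaves first
    ch <- children_of[[id]]
    levels[[id]] <- if (length(ch) == 0L) 1L else 1L + max(levels[ch])
  }
  # root must sit strictly on top
  levels[[root_id]] <- max(levels) + if (length(children_of[[root_id]])) 0L else 1L
  if (levels[[root_id]] <= max(levels[setdiff(ids, root_id)])) {
    levels[[root_id]] <- max(levels[setdiff(ids, root_id)]) + 1L
  }

  pathways <- lapply(ids, function(id) {
    list(id = id,
         name = if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else id,
         genes = sort(gene_sets[[id]]),
         parents = sort(unique(parents_of[[id]])),
         children = sort(unique(children_of[[id]])))
  })
  names(pathways) <- ids

  structure(
    list(pathways = pathways, root = root_id, levels = levels,
         n_levels = as.integer(levels[[root_id]]),
         gene_universe = sort(unique(unlist(gene_sets, use.names = FALSE)))),
    class = "pathway_hierarchy")
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat(sprintf("Pathway hierarchy: %d pathways (root '%s'), %d levels, %d genes\n",
              length(x$pathways), x$root, x$n_levels,
              length(x$gene_universe)))
  tab <- table(x$levels)
  cat("  pathways per level:",
      paste(sprintf("L%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Pathways containing a gene
#'
#' @param hierarchy A `pathway_hierarchy`.
#' @param gene Gene symbol.
#' @param include_root Include the root pathway (default FALSE: the root
#'   contains every gene by construction and is uninformative).
#' @return Character vector of pathway ids.
#' @export
pathways_of_gene <- function(hierarchy, gene, include_root = FALSE) {
  gene <- toupper(gene)
  ids <- names(hierarchy$pathways)
  hit <- vapply(hierarchy$pathways, function(p) gene %in% p$genes, TRUE)
  out <- ids[hit]
  if (!include_root) out <- setdiff(out, hierarchy$root)
  out
}

# all pathway ids in the subtree rooted at `id` (id itself included)
subtree_ids <- function(hierarchy, id) {
  out <- character(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    stack <- c(stack, hierarchy$pathways[[cur]]$children)
  }
  out
}

# gene closure of a pathway: genes reachable through its subtree's leaf blocks
gene_closure <- function(hierarchy, id) {
  ids <- subtree_ids(hierarchy, id)
  leaves <- ids[vapply(ids,
    function(i) length(hierarchy$pathways[[i]]$children) == 0L, TRUE)]
  sort(unique(unlist(lapply(leaves, function(i) hierarchy$pathways[[i]]$genes),
                     use.names = FALSE)))
}

# FNV-1a 32-bit hash over pathway ids and sorted gene lists; ties a trained
# checkpoint to the ontology it was compiled from
hierarchy_fingerprint <- function(hierarchy) {
  ids <- sort(names(hierarchy$pathways))
  txt <- paste(vapply(ids, function(id) {
    paste(id, paste(sort(hierarchy$pathways[[id]]$genes), collapse = ","),
          sep = ":")
  }, ""), collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 2166136261        # double arithmetic mod 2^32 (avoids 32-bit int limits)
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * m + ((h_hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0)  # printable, stable
}

#' Validate a pathway hierarchy
#'
#' Checks the structural invariants: exactly one root, every non-root pathway
#' reaches the root, acyclicity, child level strictly below parent level and
#' nonempty gene sets.
#'
#' @param hierarchy A `pathway_hierarchy`.
#' @return Invisibly TRUE; errors describing the first violated invariant.
#' @export
validate_hierarchy <- function(hierarchy) {
  ids <- names(hierarchy$pathways)
  roots <- ids[vapply(hierarchy$pathways,
                      function(p) length(p$parents) == 0L, TRUE)]
  if (length(roots) != 1L || roots != hierarchy$root) {
    stop("hierarchy must have exactly one parentless root")
  }
  parents_of <- lapply(hierarchy$pathways, `[[`, "parents")
  topo_order(ids, parents_of)            # errors on cycles
  for (id in setdiff(ids, hierarchy$root)) {
    p <- hierarchy$pathways[[id]]
    if (length(p$genes) == 0L) stop("pathway ", id, " has an empty gene set")
    for (par in p$parents) {
      if (hierarchy$levels[[id]] >= hierarchy$levels[[par]]) {
        stop("level(", id, ") must be below level(", par, ")")
      }
    }
    # reachability to root
    seen <- character(0); stack <- id
    ok <- FALSE
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      if (cur == hierarchy$root) { ok <- TRUE; break }
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, hierarchy$pathways[[cur]]$parents)
    }
    if (!ok) stop("pathway ", id, " cannot reach the root")
  }
  invisible(TRUE)
}
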