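# Internal nested-list tree representation used by the simulator.
#
# ape's phylo is ideal for traversal and I/O but awkward for surgery
# (grafting duplicated subtrees, per-copy loss pruning). The simulator
# therefore works on a recursive structure and serializes back to Newick:
#   leaf:     list(label =, len =)
#   internal: list(children = list(...), len =, label = optional support)
# Every node may carry `id`, the node number of the phylo it was built from.

nested_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  elen <- phy$edge.length %||% rep(NA_real_, nrow(phy$edge))
  len_of <- rep(NA_real_, ntip + phy$Nnode)
  len_of[phy$edge[, 2L]] <- elen
  build <- function(node) {
    if (node <= ntip) {
      return(list(label = phy$tip.label[node], len = len_of[node], id = node))
    }
    kids <- lapply(children[[as.character(node)]], build)
    lab <- if (!is.null(phy$node.label)) phy$node.label[node - ntip] else NULL
    list(children = kids, len = len_of[node], label = lab, id = node)
  }
  root <- ntip + 1L
  build(root)
}

nested_is_leaf <- function(node) is.null(node$children)

nested_leaves <- function(node) {
  if (nested_is_leaf(node)) return(node$label)
  unlist(lapply(node$children, nested_leaves))
}

# keep only leaves with labels in `keep`; suppress unary nodes, summing
# branch lengths; returns NULL when no leaf survives
nested_prune <- function(node, keep) {
  if (nested_is_leaf(node)) {
    if (node$label %in% keep) return(node) else return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(node$children, nested_prune, keep = keep))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) {
    child <- kids[[1L]]
    child$len <- sum(c(child$len, node$len), na.rm = FALSE)
    return(child)
  }
  node$children <- kids
  node
}

nested_relabel <- function(node, fn) {
  if (nested_is_leaf(node)) {
    node$label <- fn(node$label)
    return(node)
  }
  node$children <- lapply(node$children, nested_relabel, fn = fn)
  node
}

# multiply every branch length by an independent lognormal factor (mean 1)
nested_noise <- function(node, sd) {
  if (sd > 0 && !is.na(node$len %||% NA_real_)) {
    node$len <- node$len * stats::rlnorm(1L, meanlog = -sd^2 / 2, sdlog = sd)
  }
  if (!nested_is_leaf(node)) {
    node$children <- lapply(node$children, nested_noise, sd = sd)
  }
  node
}

# replace the subtree whose `id` equals `target_id` using `fn(subtree)`;
# fn may return NULL to delete it
nested_replace <- function(node, target_id, fn) {
  if (!is.null(node$id) && identical(node$id, target_id)) return(fn(node))
  if (nested_is_leaf(node)) return(node)
  node$children <- Filter(
    Negate(is.null),
    lapply(node$children, nested_replace, target_id = target_id, fn = fn)
  )
  if (length(node$children) == 1L) {
    child <- node$children[[1L]]
    child$len <- sum(c(child$len, node$len), na.rm = FALSE)
    return(child)
  }
  node
}

nested_to_newick <- function(node) {
  fmt <- function(n) {
    lab <- if (nested_is_leaf(n)) n$label else {
      inner <- paste(vapply(n$children, fmt, ""), collapse = ",")
      paste0("(", inner, ")", if (!is.null(n$label) && !is.na(n$label)) n$label else "")
    }
    if (!is.null(n$len) && !is.na(n$len)) paste0(lab, ":", format(n$len, digits = 10)) else lab
  }
  paste0(fmt(node), ";")
}

nested_to_phylo <- function(node) {
  ape::read.tree(text = nested_to_newick(node))
}
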