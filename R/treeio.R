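#' Gene trees with species annotations
#'
#' A `gene_tree` wraps an ape `phylo` whose leaves are gene identifiers
#' carrying a species code (see [species_rule()]). Internal-node labels are
#' interpreted as branch supports when numeric; supports are normalized to
#' `[0, 1]` (percentages divided by 100 so one threshold semantics serves
#' aLRT, bootstrap, and posterior probabilities alike).
#'
#' @param phy A `phylo` object.
#' @param rule A [species_rule()] used to extract species codes, or `NULL`
#'   when `species` is given directly.
#' @param species Optional named character vector mapping leaf label to
#'   species code; overrides `rule`.
#' @param tree_id Optional identifier for the tree.
#' @return An object of class `gene_tree` with elements `tree`, `species`
#'   (named by leaf), `tree_id`, `rooted`.
#' @examples
#' gt <- parse_newick("((A_g1:1,B_g1:1)0.99:1,C_g1:2);")
#' gt$species
#' @export
gene_tree <- function(phy, rule = species_rule(), species = NULL, tree_id = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) {
    stop("gene tree leaf labels must be unique", call. = FALSE)
  }
  if (is.null(species)) {
    species <- extract_species(phy$tip.label, rule)
    names(species) <- phy$tip.label
  } else {
    miss <- setdiff(phy$tip.label, names(species))
    if (length(miss)) {
      stop("no species mapping for leaf: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    species <- species[phy$tip.label]
  }
  structure(
    list(tree = phy, species = species, tree_id = tree_id,
         rooted = ape::is.rooted(phy)),
    class = "gene_tree"
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree", if (!is.null(x$tree_id)) paste0(" ", x$tree_id), "> ",
      length(x$tree$tip.label), " leaves, ",
      length(unique(x$species)), " species, ",
      if (x$rooted) "rooted" else "unrooted", "\n", sep = "")
  invisible(x)
}

#' Parse a Newick string or file into an annotated tree
#'
#' Supports are read from internal-node labels when numeric; branch lengths
#' from the usual `:length` suffixes.
#'
#' @param text Newick string, or a path to a file containing one tree when
#'   `file = TRUE`.
#' @param rule A [species_rule()].
#' @param tree_id Optional tree identifier.
#' @param file Logical; treat `text` as a file path.
#' @return A [gene_tree()].
#' @examples
#' parse_newick("((A_g1,B_g1),(A_g2,B_g2));")
#' @export
parse_newick <- function(text, rule = species_rule(), tree_id = NULL,
                         file = FALSE) {
  phy <- tryCatch(
    suppressWarnings(
      if (file) ape::read.tree(text) else ape::read.tree(text = text)
    ),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(phy)) stop("malformed Newick: could not parse input", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  gene_tree(phy, rule = rule, tree_id = tree_id)
}

#' Write a gene tree back to Newick
#'
#' Round-trips topology, leaf labels, supports (as internal node labels)
#' and branch lengths.
#'
#' @param gt A [gene_tree()] or `phylo`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(gt, file = NULL) {
  phy <- if (inherits(gt, "gene_tree")) gt$tree else gt
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# numeric supports per node (indexed ntip+1 .. ntip+Nnode), NA when absent
gene_tree_supports <- function(gt) {
  phy <- gt$tree
  n <- phy$Nnode
  if (is.null(phy$node.label)) return(rep(NA_real_, n))
  normalize_support(phy$node.label)
}

#' Root a gene tree with an outgroup species set
#'
#' Roots on the branch separating the largest monophyletic outgroup-only
#' clade from the rest; when no outgroup-only split exists, falls back to
#' the single outgroup leaf with the greatest mean path length to the
#' in-group leaves. Supports are treated as branch (edge) properties so the
#' re-rooted tree keeps them attached to the correct bipartitions.
#'
#' @param gt A [gene_tree()].
#' @param outgroup_species Character vector of species codes.
#' @return A rooted [gene_tree()].
#' @examples
#' gt <- parse_newick("((A_g1,B_g1),C_out);", species_rule())
#' rooted <- root_with_outgroup(gt, "C")
#' @export
root_with_outgroup <- function(gt, outgroup_species) {
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$tree
  out_tips <- names(gt$species)[gt$species %in% outgroup_species]
  if (length(out_tips) == 0L) {
    stop("no leaf belongs to the outgroup species; cannot root", call. = FALSE)
  }
  if (length(out_tips) == length(phy$tip.label)) {
    stop("outgroup covers every leaf; cannot root", call. = FALSE)
  }
  target <- largest_monophyletic_subset(phy, out_tips)
  if (is.null(target)) {
    # fallback: outgroup leaf farthest (on average) from the in-group
    d <- ape::cophenetic.phylo(phy)
    ingroup <- setdiff(phy$tip.label, out_tips)
    means <- rowMeans(d[out_tips, ingroup, drop = FALSE])
    target <- names(which.max(means))
  }
  # if the root already separates the target set, keep the tree as is
  # (re-rooting an already-rooted phylo scrambles its support labels)
  if (ape::is.rooted(phy)) {
    ntip <- length(phy$tip.label)
    kids <- phy$edge[phy$edge[, 1L] == ntip + 1L, 2L]
    for (k in kids) {
      tips <- if (k <= ntip) phy$tip.label[k]
        else ape::extract.clade(phy, k)$tip.label
      if (setequal(tips, target) ||
          setequal(tips, setdiff(phy$tip.label, target))) {
        return(gene_tree(phy, species = gt$species, tree_id = gt$tree_id))
      }
    }
    phy <- ape::unroot(phy)
  }
  rooted <- ape::root(phy, outgroup = target, resolve.root = TRUE,
                      edgelabel = TRUE)
  gene_tree(rooted, species = gt$species, tree_id = gt$tree_id)
}

# largest subset of `tips` forming a clade in the unrooted sense, or NULL
largest_monophyletic_subset <- function(phy, tips) {
  if (length(tips) == 1L) return(tips)
  if (ape::is.monophyletic(phy, tips)) return(tips)
  ntip <- length(phy$tip.label)
  unrooted <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  parts <- ape::prop.part(unrooted)
  labs <- attr(parts, "labels")
  best <- NULL
  for (p in parts) {
    side <- labs[p]
    for (s in list(side, setdiff(labs, side))) {
      if (length(s) > 1L && all(s %in% tips) &&
          (is.null(best) || length(s) > length(best))) {
        best <- s
      }
    }
  }
  if (is.null(best)) {
    # any single outgroup tip is trivially monophyletic only if preferred
    # over no split at all; signal no clade so the caller uses the fallback
    return(NULL)
  }
  best
}

#' Prune a gene tree to a set of species
#'
#' Removes leaves of all other species, suppresses unary nodes, and keeps
#' path lengths between surviving leaves additive.
#'
#' @param gt A [gene_tree()].
#' @param keep Character vector of species codes to retain.
#' @return A [gene_tree()].
#' @examples
#' gt <- parse_newick("((A_g1:1,C_g1:1):2,B_g1:1);")
#' prune_to_species(gt, c("A", "B"))
#' @export
prune_to_species <- function(gt, keep) {
  stopifnot(inherits(gt, "gene_tree"))
  tips <- names(gt$species)[gt$species %in% keep]
  if (length(tips) == 0L) {
    stop("no leaf belongs to the species to keep", call. = FALSE)
  }
  if (length(tips) < 2L) {
    stop("pruning would leave fewer than 2 leaves (degenerate tree)",
         call. = FALSE)
  }
  pruned <- ape::keep.tip(gt$tree, tips)
  gene_tree(pruned, species = gt$species[tips], tree_id = gt$tree_id)
}

#' Read a two-column species map (leaf, species) TSV
#'
#' Alternative to a naming-convention [species_rule()] when leaf labels do
#' not encode the species.
#'
#' @param path TSV with columns `leaf` and `species` (header required).
#' @return Named character vector usable as the `species` argument of
#'   [gene_tree()].
#' @export
read_species_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("leaf", "species") %in% names(df))) {
    stop("species map needs columns 'leaf' and 'species'", call. = FALSE)
  }
  stats::setNames(df$species, df$leaf)
}

#' A phylome: a collection of gene trees for one seed genome
#'
#' @param trees List of [gene_tree()]s, each containing at least one leaf of
#'   the seed species.
#' @param seed_species Species code of the seed genome.
#' @return Object of class `phylome`.
#' @export
phylome <- function(trees, seed_species) {
  stopifnot(is.list(trees), length(trees) > 0L)
  ok <- vapply(trees, function(t) seed_species %in% t$species, TRUE)
  if (!all(ok)) {
    stop(sum(!ok), " tree(s) contain no leaf of the seed species '",
         seed_species, "'", call. = FALSE)
  }
  ids <- vapply(seq_along(trees), function(i) {
    trees[[i]]$tree_id %||% paste0("tree", i)
  }, "")
  names(trees) <- ids
  structure(list(trees = trees, seed_species = seed_species),
            class = "phylome")
}

#' @export
print.phylome <- function(x, ...) {
  cat("<phylome> seed = ", x$seed_species, ", ",
      length(x$trees), " gene trees\n", sep = "")
  invisible(x)
}
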