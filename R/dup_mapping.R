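#' Detect duplication nodes by species overlap
#'
#' A gene-tree node is called a duplication when at least one pair of its
#' child subtrees contains the same species: the presence of one species on
#' both sides of a split can only be explained by a duplication at or above
#' that split. The relative age of the event is taken as the species-tree
#' MRCA of all species descending from the node (the lineages that diverged
#' after the duplication), and the event is mapped to the branch above that
#' MRCA. Multifurcating nodes are duplications when *any* pair of children
#' shares a species.
#'
#' @param gt A rooted [gene_tree()].
#' @param st A [species_tree()] containing every species of `gt`.
#' @param min_support Events on nodes with support below this are dropped
#'   when `min_support > 0`; nodes with *missing* support fail the filter
#'   (conservative). Default 0 keeps every node.
#' @return A tibble with one row per duplication event: `tree_id`, `node`
#'   (gene-tree node number), `mapped_branch` (species-tree branch id),
#'   `support`, `n_species`, and a list column `species` of the species
#'   below the node.
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", "A")
#' gt <- parse_newick("((A_g1,B_g1),(A_g2,B_g2));")
#' detect_duplications(gt, st)
#' @export
detect_duplications <- function(gt, st, min_support = 0) {
  stopifnot(inherits(gt, "gene_tree"), inherits(st, "species_tree"))
  if (!gt$rooted) {
    stop("gene tree is unrooted; root it first (see root_with_outgroup())",
         call. = FALSE)
  }
  check_species_known(gt, st)
  phy <- gt$tree
  ntip <- length(phy$tip.label)
  sets <- gene_node_species(phy, gt$species)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  supports <- gene_tree_supports(gt)
  rows <- list()
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    ch <- kids[[as.character(v)]]
    child_sets <- lapply(ch, function(c) sets[[c]])
    if (!any(duplicated(unlist(child_sets)))) next
    sup <- supports[v - ntip]
    if (min_support > 0 && (is.na(sup) || sup < min_support)) next
    sp <- unique(unlist(child_sets))
    m <- st_mrca(st, sp)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tree_id = gt$tree_id %||% NA_character_,
      node = v,
      mapped_branch = st$branch_id[m],
      support = sup,
      n_species = length(sp),
      species = list(sp)
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(tree_id = character(), node = integer(),
                          mapped_branch = character(), support = double(),
                          n_species = integer(), species = list()))
  }
  dplyr::bind_rows(rows)
}

check_species_known <- function(gt, st) {
  miss <- setdiff(unique(gt$species), st$tree$tip.label)
  if (length(miss)) {
    stop("gene tree contains species absent from the species tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

# per-node unique species sets of a gene tree
gene_node_species <- function(phy, species) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  sets[seq_len(ntip)] <- as.list(unname(species[phy$tip.label]))
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, unique)
}

#' LCA reconciliation of a binary gene tree against the species tree
#'
#' The classical mapping M(node) = species-tree MRCA of the species below
#' the node; a node is a duplication when it maps to the same species-tree
#' node as one of its children. Serves as the independent oracle for
#' [detect_duplications()]; defined for binary trees only.
#'
#' @inheritParams detect_duplications
#' @return A tibble shaped like [detect_duplications()] output.
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", "A")
#' gt <- parse_newick("((A_g1,B_g1),(A_g2,B_g2));")
#' lca_reconcile(gt, st)
#' @export
lca_reconcile <- function(gt, st) {
  stopifnot(inherits(gt, "gene_tree"), inherits(st, "species_tree"))
  if (!gt$rooted) stop("gene tree is unrooted; root it first", call. = FALSE)
  check_species_known(gt, st)
  phy <- gt$tree
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  if (any(lengths(kids) > 2L)) {
    stop("LCA reconciliation requires a binary gene tree (polytomy found)",
         call. = FALSE)
  }
  sets <- gene_node_species(phy, gt$species)
  supports <- gene_tree_supports(gt)
  M <- integer(ntip + phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  for (tip in seq_len(ntip)) {
    M[tip] <- match(gt$species[[phy$tip.label[tip]]], st$tree$tip.label)
  }
  ord <- unique(po$edge[, 1L])  # postorder parents: children visited first
  rows <- list()
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    M[v] <- st_mrca(st, unique(unlist(sets[ch])))
    if (any(M[ch] == M[v])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tree_id = gt$tree_id %||% NA_character_,
        node = v,
        mapped_branch = st$branch_id[M[v]],
        support = supports[v - ntip],
        n_species = length(sets[[v]]),
        species = list(sets[[v]])
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(tree_id = character(), node = integer(),
                          mapped_branch = character(), support = double(),
                          n_species = integer(), species = list()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$node)
}

#' Per-branch duplication densities along the seed lineage
#'
#' For every branch of the seed lineage (root to seed tip), counts the
#' duplications mapped to it and divides by the number of *informative*
#' trees: those containing at least one species that diverged before the
#' branch (for the root, every tree). When an ohnolog-pair table is given,
#' the phylome is restricted to trees containing a listed pair and only the
#' duplication node that is the MRCA of the two pair members is counted.
#'
#' @param p A [phylome()].
#' @param st A [species_tree()].
#' @param ohnologs Optional tibble/data.frame with columns `gene1`, `gene2`
#'   (leaf labels of seed-species ohnolog pairs). Pairs whose members are
#'   not found together in any tree are skipped with a warning.
#' @param min_support Support filter forwarded to the duplication detector.
#' @param method `"species_overlap"` (default) or `"lca"`.
#' @return A `density_profile`: a tibble with `branch_id` (ancestral to
#'   recent), `dup_count`, `informative_trees`, `density` (`NA` when no
#'   tree is informative, never reported as 0 in that case).
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", "A")
#' gts <- list(parse_newick("((A_g1,B_g1),(A_g2,B_g2));", tree_id = "t1"),
#'             parse_newick("((A_g3,B_g3),C_g1);", tree_id = "t2"))
#' density_profile(phylome(gts, "A"), st)
#' @export
density_profile <- function(p, st, ohnologs = NULL, min_support = 0,
                            method = c("species_overlap", "lca")) {
  stopifnot(inherits(p, "phylome"), inherits(st, "species_tree"))
  method <- match.arg(method)
  mapper <- if (method == "species_overlap") {
    function(gt) detect_duplications(gt, st, min_support = min_support)
  } else {
    function(gt) {
      ev <- lca_reconcile(gt, st)
      if (min_support > 0) ev <- dplyr::filter(ev, !is.na(.data$support),
                                               .data$support >= min_support)
      ev
    }
  }
  lineage <- st$lineage
  lineage_nodes <- vapply(lineage, branch_node, 0L, st = st)
  counts <- stats::setNames(rep(0L, length(lineage)), lineage)
  informative <- stats::setNames(rep(0L, length(lineage)), lineage)
  trees <- p$trees
  n_used <- 0L
  for (gt in trees) {
    events <- mapper(gt)
    if (!is.null(ohnologs)) {
      pair <- find_ohnolog_pair(gt, ohnologs)
      if (is.null(pair)) next
      mnode <- ape::getMRCA(gt$tree, pair)
      events <- dplyr::filter(events, .data$node == mnode)
    }
    n_used <- n_used + 1L
    sp <- unique(gt$species)
    inf <- vapply(seq_along(lineage), function(i) {
      lineage[i] == "root" ||
        length(intersect(sp, species_outside(st, lineage_nodes[[i]]))) > 0L
    }, TRUE)
    informative[inf] <- informative[inf] + 1L
    if (nrow(events)) {
      # an event only counts where the tree belongs to the denominator set
      tab <- table(events$mapped_branch)
      hit <- intersect(names(tab), lineage[inf])
      counts[hit] <- counts[hit] + as.integer(tab[hit])
    }
  }
  out <- tibble::tibble(
    branch_id = lineage,
    dup_count = as.integer(counts),
    informative_trees = as.integer(informative),
    density = ifelse(informative > 0, counts / informative, NA_real_)
  )
  structure(out,
            class = c("density_profile", class(out)),
            n_trees = n_used, min_support = min_support, method = method,
            subset = !is.null(ohnologs))
}

# first listed ohnolog pair fully present in the tree, else NULL (warns)
find_ohnolog_pair <- function(gt, ohnologs) {
  tips <- gt$tree$tip.label
  present <- ohnologs$gene1 %in% tips & ohnologs$gene2 %in% tips
  if (!any(present)) {
    partial <- xor(ohnologs$gene1 %in% tips, ohnologs$gene2 %in% tips)
    if (any(partial)) {
      warning("tree ", gt$tree_id %||% "?",
              ": ohnolog pair only partially present; pair skipped",
              call. = FALSE)
    }
    return(NULL)
  }
  idx <- which(present)
  if (length(idx) > 1L) {
    warning("tree ", gt$tree_id %||% "?",
            ": multiple ohnolog pairs present; using the first",
            call. = FALSE)
  }
  c(ohnologs$gene1[idx[1L]], ohnologs$gene2[idx[1L]])
}

#' Agreement between two duplication mappings
#'
#' Compares mapped branches for the trees present in both event lists
#' (e.g. species-overlap vs reconciliation, or two inference methods),
#' matching the convention of scoring agreement only over trees that pass
#' both methods' filters.
#'
#' @param a,b Tibbles of duplication events with one row per `tree_id`
#'   (filter to the event of interest first, e.g. the ohnolog-pair node).
#' @return One-row tibble: `n_shared`, `n_agree`, `pct_agreement` (`NA`
#'   when no tree is shared).
#' @export
compare_mappings <- function(a, b) {
  for (x in list(a, b)) {
    if (anyDuplicated(x$tree_id)) {
      stop("event lists must have one row per tree_id; ",
           "filter to one event per tree first", call. = FALSE)
    }
  }
  shared <- dplyr::inner_join(
    dplyr::select(a, "tree_id", a_branch = "mapped_branch"),
    dplyr::select(b, "tree_id", b_branch = "mapped_branch"),
    by = "tree_id"
  )
  n <- nrow(shared)
  agree <- sum(shared$a_branch == shared$b_branch)
  tibble::tibble(
    n_shared = n,
    n_agree = agree,
    pct_agreement = if (n > 0) 100 * agree / n else NA_real_
  )
}

#' Ohnolog monophyly consistency with and without outgroups
#'
#' Long-branch attraction is diagnosed by rebuilding a tree without the
#' outgroup sequences: in the absence of the artifact the in-group topology
#' is stable. This test asks, in both versions of a tree, whether the two
#' seed ohnologs have a common ancestor containing no sequence from either
#' parental clade, and reports whether the two answers agree.
#'
#' @param t_without_outgroup [gene_tree()] rebuilt without outgroups (may be
#'   unrooted; it is rooted on a parental-clade leaf internally, which
#'   leaves the monophyly question unchanged).
#' @param t_rooted Outgroup-rooted [gene_tree()] of the same family.
#' @param pair Character vector of the two seed-ohnolog leaf labels.
#' @param parental_species Character vector: the union of the two parental
#'   clades' species codes.
#' @param min_support Minimum support of the pair's MRCA clade in each tree;
#'   below it the tree pair is `"unfilterable"`. Default 0.5.
#' @return One-row tibble: `call` (`consistent`, `inconsistent`,
#'   `unfilterable`), per-tree monophyly flags and supports.
#' @export
ohnolog_monophyly_test <- function(t_without_outgroup, t_rooted, pair,
                                   parental_species, min_support = 0.5) {
  check_pair <- function(gt) {
    miss <- setdiff(pair, gt$tree$tip.label)
    if (length(miss)) {
      stop("pair member(s) missing from tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  check_pair(t_without_outgroup); check_pair(t_rooted)
  eval_tree <- function(gt) {
    phy <- gt$tree
    if (!ape::is.rooted(phy)) {
      par_tip <- names(gt$species)[gt$species %in% parental_species][1L]
      if (is.na(par_tip)) {
        stop("cannot root the outgroup-free tree: no parental-clade leaf",
             call. = FALSE)
      }
      phy <- ape::root(phy, outgroup = par_tip, resolve.root = TRUE,
                       edgelabel = TRUE)
      gt <- gene_tree(phy, species = gt$species, tree_id = gt$tree_id)
    }
    m <- ape::getMRCA(gt$tree, pair)
    clade_tips <- ape::extract.clade(gt$tree, m)$tip.label
    clade_sp <- unique(gt$species[clade_tips])
    sup <- gene_tree_supports(gt)[m - length(gt$tree$tip.label)]
    list(mono = !any(clade_sp %in% parental_species), support = sup)
  }
  a <- eval_tree(t_rooted)
  b <- eval_tree(t_without_outgroup)
  filt_fail <- function(s) min_support > 0 && (is.na(s) || s < min_support)
  call <- if (filt_fail(a$support) || filt_fail(b$support)) {
    "unfilterable"
  } else if (identical(a$mono, b$mono)) "consistent" else "inconsistent"
  tibble::tibble(
    call = call,
    mono_rooted = a$mono, support_rooted = a$support,
    mono_no_outgroup = b$mono, support_no_outgroup = b$support
  )
}
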