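#' Classify a seed sequence's sister clade against two parental lineages
#'
#' After rooting with the outgroups, the clade immediately neighbouring the
#' seed sequence is inspected: if its species all belong to parental clade A
#' the call is `A`, all in clade B gives `B`, and a mix of both gives `C`.
#' Trees lacking homologs in clade A, clade B, or the outgroups are
#' `excluded` (no placement is testable), as are sisters consisting only of
#' outgroup species. The call is `unsupported` when the support of the
#' clade enclosing the seed and its sister is below `min_support`. When the
#' immediate sister contains only further seed-species paralogs (complete
#' phylomes), the scan ascends until a clade containing non-seed species is
#' found.
#'
#' @param gt A [gene_tree()].
#' @param seed Leaf label of the seed sequence.
#' @param parentA,parentB Character vectors of species codes for the two
#'   putative parental clades.
#' @param outgroups Character vector of outgroup species codes.
#' @param min_support Support threshold; default 0.95. Missing support
#'   fails the filter when `min_support > 0`.
#' @return One-row tibble: `tree_id`, `seed`, `call` (`A`, `B`, `C`,
#'   `excluded`, `unsupported`), `support`, `sister_species`
#'   (comma-collapsed).
#' @examples
#' gt <- parse_newick("(((S_g1,Z_g1)0.98:1,K_g1):1,O_g1);")
#' classify_seed_topology(gt, "S_g1", parentA = "Z", parentB = "K",
#'                        outgroups = "O")
#' @export
classify_seed_topology <- function(gt, seed, parentA, parentB, outgroups,
                                   min_support = 0.95) {
  stopifnot(inherits(gt, "gene_tree"))
  if (!seed %in% gt$tree$tip.label) {
    stop("seed leaf '", seed, "' not found in tree", call. = FALSE)
  }
  seed_species <- gt$species[[seed]]
  sp <- unique(gt$species)
  res <- function(call, support = NA_real_, sister = character()) {
    tibble::tibble(tree_id = gt$tree_id %||% NA_character_, seed = seed,
                   call = call, support = support,
                   sister_species = paste(sister, collapse = ","))
  }
  if (!any(sp %in% parentA) || !any(sp %in% parentB) ||
      !any(sp %in% outgroups)) {
    return(res("excluded"))
  }
  gt <- root_with_outgroup(gt, outgroups)
  phy <- gt$tree
  ntip <- length(phy$tip.label)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  sets <- gene_node_species(phy, gt$species)
  tipsets <- gene_node_tips(phy)
  supports <- gene_tree_supports(gt)
  root <- ntip + 1L
  node <- match(seed, phy$tip.label)
  repeat {
    if (node == root) return(res("excluded"))
    up <- parent[node]
    sibs <- setdiff(kids[[as.character(up)]], node)
    sister_sp <- unique(unlist(sets[sibs]))
    non_seed <- setdiff(sister_sp, seed_species)
    if (length(non_seed) > 0L) {
      sup <- if (up == root) NA_real_ else supports[up - ntip]
      in_a <- any(non_seed %in% parentA)
      in_b <- any(non_seed %in% parentB)
      outside <- setdiff(non_seed, c(parentA, parentB))
      call <- if (length(outside) > 0L || (!in_a && !in_b)) {
        "excluded"
      } else if (min_support > 0 && (is.na(sup) || sup < min_support)) {
        "unsupported"
      } else if (in_a && in_b) "C" else if (in_a) "A" else "B"
      return(res(call, sup, non_seed))
    }
    node <- up
  }
}

# per-node tip label sets (memoized shape of gene_node_species)
gene_node_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  sets[seq_len(ntip)] <- as.list(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Nine-way topology classification of a conserved ohnolog pair
#'
#' Each ohnolog is classified `A`/`B`/`C` by [classify_seed_topology()]
#' after pruning the other ohnolog from the tree, so each copy's parental
#' affiliation is read independently. The suffix encodes whether the pair
#' is monophyletic: `1` when the pair's common-ancestor clade contains no
#' parental sequence (compatible with post-event divergence or gene
#' conversion), `2` otherwise. Mixed labels are unordered (`A-B` == `B-A`).
#'
#' @inheritParams classify_seed_topology
#' @param pair Character vector of the two seed-ohnolog leaf labels.
#' @return One-row tibble: `tree_id`, `call` (one of `A-A1`, `A-A2`,
#'   `B-B1`, `B-B2`, `C-C1`, `C-C2`, `A-B`, `A-C`, `B-C`, or
#'   `excluded`/`unsupported`), per-copy calls, `pair_monophyletic`.
#' @export
classify_ohnolog_pair <- function(gt, pair, parentA, parentB, outgroups,
                                  min_support = 0.95) {
  stopifnot(inherits(gt, "gene_tree"), length(pair) == 2L)
  miss <- setdiff(pair, gt$tree$tip.label)
  if (length(miss)) {
    stop("pair member(s) missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  one <- function(keep, drop) {
    pruned <- ape::drop.tip(gt$tree, drop, collapse.singles = TRUE)
    sub <- gene_tree(pruned, species = gt$species[pruned$tip.label],
                     tree_id = gt$tree_id)
    classify_seed_topology(sub, keep, parentA, parentB, outgroups,
                           min_support = min_support)
  }
  c1 <- one(pair[1L], pair[2L])
  c2 <- one(pair[2L], pair[1L])
  rooted <- root_with_outgroup(gt, outgroups)
  m <- ape::getMRCA(rooted$tree, pair)
  clade_sp <- unique(rooted$species[ape::extract.clade(rooted$tree, m)$tip.label])
  mono <- !any(clade_sp %in% c(parentA, parentB))
  calls <- c(c1$call, c2$call)
  call <- if (any(calls == "excluded")) {
    "excluded"
  } else if (any(calls == "unsupported")) {
    "unsupported"
  } else if (calls[1L] == calls[2L]) {
    paste0(calls[1L], "-", calls[1L], if (mono) "1" else "2")
  } else {
    paste(sort(calls), collapse = "-")
  }
  tibble::tibble(
    tree_id = gt$tree_id %||% NA_character_,
    call = call,
    call_1 = c1$call, call_2 = c2$call,
    pair_monophyletic = mono
  )
}

#' Frequency table of topology calls
#'
#' Percentages are computed over the trees that pass the filters (calls
#' other than `excluded`/`unsupported`); the number and fraction passing is
#' reported alongside, mirroring the "n passing filters" annotation of the
#' pie-chart summaries.
#'
#' @param calls A tibble of calls from [classify_seed_topology()] or
#'   [classify_ohnolog_pair()] (rows bound together).
#' @return A `topology_distribution` tibble: `call`, `n`, `pct`, with
#'   attributes `n_total`, `n_passing`.
#' @export
topology_distribution <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- tibble::tibble(call = character(), n = integer(), pct = double())
    return(structure(out, class = c("topology_distribution", class(out)),
                     n_total = 0L, n_passing = 0L))
  }
  passing <- dplyr::filter(calls, !.data$call %in% c("excluded", "unsupported"))
  out <- passing |>
    dplyr::count(.data$call, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(out, class = c("topology_distribution", class(out)),
            n_total = nrow(calls), n_passing = nrow(passing))
}

#' Scan a phylome's seed sequences for their parental affiliation
#'
#' Applies [classify_seed_topology()] to the designated seed leaf of every
#' tree in a phylome.
#'
#' @param p A [phylome()].
#' @param seeds Optional named character vector (tree id -> seed leaf);
#'   defaults to the first seed-species leaf of each tree.
#' @inheritParams classify_seed_topology
#' @return Tibble of calls, one row per tree.
#' @export
scan_phylome_topologies <- function(p, parentA, parentB, outgroups,
                                    min_support = 0.95, seeds = NULL) {
  stopifnot(inherits(p, "phylome"))
  purrr::map_dfr(names(p$trees), function(id) {
    gt <- p$trees[[id]]
    seed <- if (!is.null(seeds) && id %in% names(seeds)) {
      seeds[[id]]
    } else {
      names(gt$species)[gt$species == p$seed_species][1L]
    }
    classify_seed_topology(gt, seed, parentA, parentB, outgroups,
                           min_support = min_support)
  })
}
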