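#' Reference species tree with named branches
#'
#' Wraps a rooted `phylo` whose tips are species codes and assigns a stable
#' branch identifier to every node (the branch *above* that node). Branches
#' on the lineage from the root to the seed species are numbered `n1`
#' (most ancestral, just below the root) to `nK` (the seed terminal branch),
#' mirroring the convention of numbering the seed lineage ancestral to
#' recent; the root itself is the mapping point for duplications older than
#' every split and carries the id `"root"`. All other internal nodes get ids
#' `b<node>` and tips their species code.
#'
#' @param x A rooted `phylo` object or a Newick string.
#' @param seed_species Species code of the seed (focal) genome; must be a
#'   tip label.
#' @return An object of class `species_tree` with elements `tree` (`phylo`),
#'   `seed_species`, `branch_id` (per-node ids), `lineage` (branch ids
#'   root -> seed tip, ancestral to recent), `clades` (species below each
#'   node).
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", seed_species = "A")
#' st$lineage
#' @export
species_tree <- function(x, seed_species) {
  phy <- if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  if (is.null(phy)) stop("could not parse species tree", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("species tree must be rooted", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("species tree tip labels must be unique", call. = FALSE)
  }
  if (!seed_species %in% phy$tip.label) {
    stop("seed species '", seed_species, "' is not a tip of the species tree",
         call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  parent <- integer(nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- ntip + 1L
  # path root -> seed tip
  path <- integer(0)
  node <- match(seed_species, phy$tip.label)
  while (node != root) {
    path <- c(node, path)
    node <- parent[node]
  }
  branch_id <- character(nnode)
  branch_id[root] <- "root"
  branch_id[path] <- paste0("n", seq_along(path))
  others <- setdiff(seq_len(nnode), c(root, path))
  branch_id[others] <- ifelse(others <= ntip,
                              phy$tip.label[others],
                              paste0("b", others))
  clades <- node_clades(phy)
  structure(
    list(tree = phy, seed_species = seed_species, branch_id = branch_id,
         lineage = c("root", branch_id[path]), parent = parent,
         clades = clades),
    class = "species_tree"
  )
}

# species set below every node (tips included)
node_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sets <- vector("list", nnode)
  sets[seq_len(ntip)] <- as.list(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, unique)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("<species_tree> ", length(x$tree$tip.label), " species, seed = ",
      x$seed_species, "\n  seed lineage: ",
      paste(x$lineage, collapse = " > "), "\n", sep = "")
  invisible(x)
}

# node whose above-branch carries `branch_id`
branch_node <- function(st, branch_id) {
  i <- match(branch_id, st$branch_id)
  if (is.na(i)) stop("unknown branch id: ", branch_id, call. = FALSE)
  i
}

# ancestors of each node, root first, self last
node_ancestry <- function(st, node) {
  ntip <- length(st$tree$tip.label)
  root <- ntip + 1L
  path <- node
  while (node != root) {
    node <- st$parent[node]
    path <- c(node, path)
  }
  path
}

# MRCA node id of a set of species codes
st_mrca <- function(st, species) {
  species <- unique(species)
  miss <- setdiff(species, st$tree$tip.label)
  if (length(miss)) {
    stop("species not in species tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tips <- match(species, st$tree$tip.label)
  if (length(tips) == 1L) return(tips)
  paths <- lapply(tips, node_ancestry, st = st)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# is node `a` a strict descendant of node `b`?
st_is_descendant <- function(st, a, b) {
  if (a == b) return(FALSE)
  anc <- node_ancestry(st, a)
  b %in% anc[-length(anc)]
}

# species that diverged before the branch above `node` (outside its clade)
species_outside <- function(st, node) {
  setdiff(st$tree$tip.label, st$clades[[node]])
}

#' Built-in yeast species trees
#'
#' Stylized reference trees for the Saccharomycetaceae study system. The
#' `"full"` tree has 14 taxa: a post-WGD clade (Scer, Cgla, Vpol), the ZT
#' clade (Zrou, Tdel), the KLE clade (Klac, Agos, Lklu, Lthe, Lwal), and
#' four outgroups (Wano, Calb, Ylip, Spom). The `"reduced"` tree collapses
#' the post-WGD clade to S. cerevisiae alone (12 taxa), the configuration
#' used for sequence-level simulations. Branch lengths are stylized
#' substitutions/site values resembling protein-level divergences, with the
#' pre-KLE branch among the longest internal branches.
#'
#' @param taxa `"full"` (14 taxa, three post-WGD species) or `"reduced"`
#'   (12 taxa, S. cerevisiae the only post-WGD species).
#' @return A [species_tree()] seeded on `"Scer"`.
#' @examples
#' st <- yeast_species_tree("reduced")
#' st$lineage
#' @export
yeast_species_tree <- function(taxa = c("full", "reduced")) {
  taxa <- match.arg(taxa)
  ingroup <- if (taxa == "full") {
    paste0("(((Scer:0.08,Cgla:0.09):0.05,Vpol:0.10):0.08,",
           "(Zrou:0.12,Tdel:0.12):0.10):0.05")
  } else {
    "(Scer:0.25,(Zrou:0.12,Tdel:0.12):0.10):0.05"
  }
  nwk <- paste0(
    "((((", ingroup, ",",
    "((Klac:0.15,Agos:0.18):0.05,(Lklu:0.12,(Lthe:0.08,Lwal:0.08):0.05):0.05):0.08",
    "):0.25,Wano:0.45):0.05,(Calb:0.40,Ylip:0.55):0.05):0.10,Spom:0.65);"
  )
  species_tree(nwk, seed_species = "Scer")
}

#' Clade membership helpers for the built-in yeast trees
#'
#' @return Named list of species-code vectors: `zt`, `kle`, `postwgd`,
#'   `outgroups`.
#' @examples
#' yeast_clades()$zt
#' @export
yeast_clades <- function() {
  list(
    zt = c("Zrou", "Tdel"),
    kle = c("Klac", "Agos", "Lklu", "Lthe", "Lwal"),
    postwgd = c("Scer", "Cgla", "Vpol"),
    outgroups = c("Wano", "Calb", "Ylip", "Spom")
  )
}
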