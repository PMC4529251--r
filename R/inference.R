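#' Pairwise Kimura distance matrix of an alignment
#'
#' All pairwise [kimura_distance()] values; saturated pairs are set to a
#' finite ceiling with a warning so tree building stays possible. The
#' default ceiling sits just above the largest distance the correction can
#' produce before saturating (about 1.9 substitutions/site): assigning
#' saturated pairs a value far beyond the tree diameter would distort the
#' neighbor-joining geometry around fast-evolving sequences.
#'
#' @param aln Character matrix (taxa x columns) or `sim_alignment`.
#' @param ceiling Distance assigned to saturated pairs (substitutions/site).
#' @return Symmetric numeric matrix with zero diagonal, class
#'   `dist_matrix`.
#' @export
distance_matrix <- function(aln, ceiling = 2.0) {
  stopifnot(is.matrix(aln))
  n <- nrow(aln)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- tryCatch(kimura_distance(aln[i, ], aln[j, ]),
                    error = function(e) NA_real_)
      if (is.na(v)) { v <- ceiling; saturated <- saturated + 1L }
      d[i, j] <- d[j, i] <- v
    }
  }
  if (saturated > 0L) {
    warning(saturated, " saturated pair(s) set to the ceiling ", ceiling,
            call. = FALSE)
  }
  structure(d, class = c("dist_matrix", class(d)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (additive matrices are recovered exactly); the resulting
#' tree is unrooted with gene-labelled leaves.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @param rule A [species_rule()] for species annotation.
#' @param tree_id Optional identifier.
#' @return An unrooted [gene_tree()].
#' @export
neighbor_joining <- function(dm, rule = species_rule(), tree_id = NULL) {
  stopifnot(is.matrix(dm))
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  phy <- ape::nj(stats::as.dist(dm))
  gene_tree(phy, rule = rule, tree_id = tree_id)
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal bipartition of the point-estimate
#' tree with its replicate frequency in `[0, 1]`.
#'
#' @param aln Character matrix (taxa x columns).
#' @param n_reps Number of replicates (default 100).
#' @param seed Optional RNG seed.
#' @inheritParams neighbor_joining
#' @return A [gene_tree()] whose internal-node labels carry supports.
#' @export
bootstrap_support <- function(aln, n_reps = 100, rule = species_rule(),
                              tree_id = NULL, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  point <- suppressWarnings(
    ape::nj(stats::as.dist(unclass(distance_matrix(aln))))
  )
  reps <- lapply(seq_len(n_reps), function(i) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    suppressWarnings(
      ape::nj(stats::as.dist(unclass(distance_matrix(aln[, cols, drop = FALSE]))))
    )
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- formatC(counts / n_reps, format = "f", digits = 3)
  gene_tree(point, rule = rule, tree_id = tree_id)
}

#' Infer a gene tree from a simulated alignment
#'
#' Distance (Kimura) + NJ, optionally with bootstrap supports; the
#' desk-scale inference stage of the simulate-infer-map loop. External ML
#' trees can be imported through [parse_newick()] instead.
#'
#' @param aln Character matrix (taxa x columns).
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @inheritParams neighbor_joining
#' @return An unrooted [gene_tree()].
#' @export
infer_gene_tree <- function(aln, bootstrap = 0, rule = species_rule(),
                            tree_id = NULL) {
  if (bootstrap > 0) {
    return(bootstrap_support(aln, n_reps = bootstrap, rule = rule,
                             tree_id = tree_id))
  }
  dm <- suppressWarnings(distance_matrix(aln))
  neighbor_joining(unclass(dm), rule = rule, tree_id = tree_id)
}
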