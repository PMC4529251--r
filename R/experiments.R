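#' Gene-conversion sweep: when do duplications start looking younger?
#'
#' Simulates gene families carrying a seed-paralog pair whose true
#' (apparent) duplication maps to an ancestral branch -- the two homeologs
#' of a hybridization whose parents diverged at that branch -- evolves
#' sequences, and for each conversion fraction `f` overwrites a contiguous
#' fraction `f` of one paralog with the other's homologous fragment,
#' re-infers the tree by distance/NJ, roots it with the outgroups, and maps
#' the paralog duplication (the MRCA of the two seed copies) with the
#' species-overlap rule. Reports, per `f`, the fraction of families whose
#' mapping lands on a branch strictly younger than the truth, and the
#' smallest `f` at which that outcome is the majority.
#'
#' @param st A [species_tree()]; defaults to the reduced 12-taxon yeast
#'   tree.
#' @param n_families Families per sweep point.
#' @param f_grid Conversion fractions to test.
#' @param seq_length Alignment length (amino acids).
#' @param rate_scale Global rate multiplier; the default 0.3 matches the
#'   conserved single-copy-ortholog gene set these control simulations
#'   model (same regime as [lba_experiment()]).
#' @param outgroups Outgroup species used for rooting.
#' @param seed RNG seed.
#' @param cfg Optional [scenario_config()] overriding the default
#'   hybridization setup (advanced).
#' @return A `conversion_sweep` tibble: `f`, `n_trees`, `n_younger`,
#'   `p_younger`, with attribute `threshold_f` (smallest `f` with
#'   `p_younger > 0.5`, `NA` when never reached) and `true_branch`.
#' @export
conversion_sweep <- function(st = yeast_species_tree("reduced"),
                             n_families = 200,
                             f_grid = seq(0, 0.5, by = 0.05),
                             seq_length = 300, rate_scale = 0.3,
                             outgroups = yeast_clades()$outgroups,
                             seed = NULL, cfg = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cfg)) {
    cfg <- scenario_config(
      scenario = "hybridization",
      event_branch = seed_terminal_branch(st),
      parent_b = intersect(yeast_clades()$kle, st$tree$tip.label),
      n_families = n_families, loss_prob = 0,
      seq_length = seq_length, indel_freq = 0,
      rate_scale = rate_scale
    )
  }
  sim <- simulate_phylome(st, cfg)
  truth_branch <- unique(stats::na.omit(sim$truth$true_branch))[1L]
  true_node <- branch_node(st, truth_branch)
  results <- lapply(names(sim$phylome$trees), function(id) {
    gt <- sim$phylome$trees[[id]]
    aln <- evolve_sequences(gt, cfg)
    pair <- rownames(aln)[startsWith(rownames(aln),
                                     paste0(st$seed_species, "_"))]
    if (length(pair) != 2L) return(NULL)
    vapply(f_grid, function(f) {
      a2 <- apply_gene_conversion(aln, pair[1L], pair[2L], f)
      inf <- infer_gene_tree(a2, tree_id = id)
      mapped <- tryCatch(
        map_pair_duplication(inf, st, pair, outgroups),
        error = function(e) NA_character_
      )
      if (is.na(mapped)) return(NA)
      st_is_descendant(st, branch_node(st, mapped), true_node)
    }, NA)
  })
  results <- Filter(Negate(is.null), results)
  younger <- do.call(rbind, results)   # families x f_grid
  out <- tibble::tibble(
    f = f_grid,
    n_trees = colSums(!is.na(younger)),
    n_younger = colSums(younger, na.rm = TRUE),
    p_younger = colSums(younger, na.rm = TRUE) / colSums(!is.na(younger))
  )
  thr <- out$f[which(out$p_younger > 0.5)[1L]]
  structure(out, class = c("conversion_sweep", class(out)),
            threshold_f = if (length(thr)) thr else NA_real_,
            true_branch = truth_branch, n_families = length(results))
}

# species-tree branch id of the MRCA of a paralog pair in a gene tree,
# after outgroup rooting (the species-overlap age of the pair duplication)
map_pair_duplication <- function(gt, st, pair, outgroups) {
  rooted <- root_with_outgroup(gt, outgroups)
  m <- ape::getMRCA(rooted$tree, pair)
  sp <- unique(rooted$species[ape::extract.clade(rooted$tree, m)$tip.label])
  st$branch_id[st_mrca(st, sp)]
}

seed_terminal_branch <- function(st) {
  st$lineage[length(st$lineage)]
}

#' Long-branch-acceleration experiment
#'
#' Simulates single-copy families, bifurcates the seed terminal branch at
#' its midpoint into a slow copy (the original length cut in half) and a
#' paralog evolving `lba_multiplier` times the original branch length --
#' with the default 10 the fast copy evolves 20-fold faster than its
#' halved sister, the strongest acceleration the study design describes --
#' evolves sequences, re-infers each tree by distance/NJ, and maps the
#' seed-pair duplication. Under long-branch attraction the fast copy can
#' be pulled rootward, inflating ancestral branches; the experiment
#' measures whether the density peak stays at the true (terminal)
#' duplication branch.
#'
#' The default `rate_scale` of 0.3 emulates the conservation-biased gene
#' set such control simulations are run on (universal single-copy
#' orthologs, distinctly slower than the genome average); it also keeps the
#' accelerated paralog's corrected distances statistically reliable, which
#' any distance-based placement requires (see the methods vignette).
#'
#' @param st A [species_tree()].
#' @param n_families Number of families.
#' @param lba_multiplier Multiplier on the original terminal branch length
#'   for the fast copy (10 here = 20-fold rate ratio between paralogs).
#' @param seq_length Alignment length (default 450, a typical full-length
#'   yeast protein).
#' @param rate_scale Global rate multiplier of the sequence simulator.
#' @param outgroups Outgroup species for rooting.
#' @param seed RNG seed.
#' @return An `lba_experiment` list: `profile` (a [density_profile()]-like
#'   tibble of mapped duplication counts over the seed lineage),
#'   `true_branch`, `n_mapped`.
#' @export
lba_experiment <- function(st = yeast_species_tree("reduced"),
                           n_families = 200, lba_multiplier = 10,
                           seq_length = 450, rate_scale = 0.3,
                           outgroups = yeast_clades()$outgroups,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- scenario_config(
    scenario = "none", n_families = n_families,
    seq_length = seq_length, indel_freq = 0,
    lba_multiplier = lba_multiplier, rate_scale = rate_scale
  )
  sim <- simulate_phylome(st, cfg)
  true_branch <- seed_terminal_branch(st)
  mapped <- character(0)
  for (id in names(sim$phylome$trees)) {
    gt <- sim$phylome$trees[[id]]
    seed_leaf <- names(gt$species)[gt$species == st$seed_species][1L]
    gt2 <- apply_lba(gt, seed_leaf, cfg)
    aln <- evolve_sequences(gt2, cfg)
    pair <- rownames(aln)[startsWith(rownames(aln),
                                     paste0(st$seed_species, "_"))]
    b <- tryCatch(map_pair_duplication(infer_gene_tree(aln, tree_id = id),
                                       st, pair, outgroups),
                  error = function(e) NA_character_)
    if (!is.na(b)) mapped <- c(mapped, b)
  }
  tab <- table(factor(mapped, levels = st$lineage))
  profile <- tibble::tibble(
    branch_id = st$lineage,
    dup_count = as.integer(tab),
    density = as.integer(tab) / length(mapped)
  )
  structure(list(profile = profile, true_branch = true_branch,
                 n_mapped = length(mapped),
                 lba_multiplier = lba_multiplier),
            class = "lba_experiment")
}

#' @export
print.lba_experiment <- function(x, ...) {
  cat("<lba_experiment> ", x$n_mapped, " mapped families, acceleration x",
      x$lba_multiplier, ", true branch ", x$true_branch, "\n", sep = "")
  print(x$profile)
  invisible(x)
}
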