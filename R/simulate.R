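#' Simulation scenario configuration
#'
#' Bundles every knob of the phylome generator. All randomness downstream
#' flows from `seed`.
#'
#' @param scenario `"none"` (single-copy families), `"autoWGD"` (both
#'   copies descend from the event branch), or `"hybridization"` (two
#'   homeologs whose coalescence is at the parental-divergence branch).
#' @param event_branch Species-tree branch id of the event: the WGD branch
#'   for `"autoWGD"`; for `"hybridization"`, the branch above the
#'   post-hybrid clade (the hybridization point).
#' @param parent_b Species codes of the second parental clade
#'   (hybridization only); the second homeolog attaches as sister to their
#'   MRCA clade.
#' @param n_families Number of gene families.
#' @param loss_prob Per-copy, per-species loss probability applied to the
#'   duplicated copies after the event (the seed species always keeps at
#'   least one copy, since a phylome is seeded on its genes).
#' @param seq_length Alignment length in amino acids at the root.
#' @param rate_alpha Gamma shape for among-site rate heterogeneity.
#' @param n_rate_categories Discrete gamma categories (default 16).
#' @param rate_scale Global rate multiplier; 1 keeps expected divergence
#'   calibrated to branch lengths in substitutions/site.
#' @param indel_freq Per-site, per-unit-branch-length indel rate.
#' @param lba_multiplier Rate-acceleration factor for [apply_lba()].
#' @param conversion_fraction Default conversion fraction for
#'   [apply_gene_conversion()].
#' @param branch_noise_sd Lognormal sd of per-branch length noise (mean 1).
#' @param seed RNG seed (integer) or `NULL` to use the current stream.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("none", "autoWGD", "hybridization"),
                            event_branch = NULL, parent_b = NULL,
                            n_families = 100, loss_prob = 0.3,
                            seq_length = 300, rate_alpha = 1.0,
                            n_rate_categories = 16, rate_scale = 1,
                            indel_freq = 0.0003, lba_multiplier = 10,
                            conversion_fraction = 0, branch_noise_sd = 0.2,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n_families >= 1, loss_prob >= 0, loss_prob <= 1,
            conversion_fraction >= 0, conversion_fraction <= 1,
            seq_length >= 1, rate_alpha > 0, n_rate_categories >= 1)
  if (scenario != "none" && is.null(event_branch)) {
    stop("scenario '", scenario, "' needs an event_branch", call. = FALSE)
  }
  if (scenario == "hybridization" && is.null(parent_b)) {
    stop("hybridization needs parent_b (second parental clade species)",
         call. = FALSE)
  }
  structure(
    list(scenario = scenario, event_branch = event_branch,
         parent_b = parent_b, n_families = as.integer(n_families),
         loss_prob = loss_prob, seq_length = as.integer(seq_length),
         rate_alpha = rate_alpha,
         n_rate_categories = as.integer(n_rate_categories),
         rate_scale = rate_scale, indel_freq = indel_freq,
         lba_multiplier = lba_multiplier,
         conversion_fraction = conversion_fraction,
         branch_noise_sd = branch_noise_sd, seed = seed),
    class = "scenario_config"
  )
}

#' Simulate a phylome with known ground truth
#'
#' Generates `n_families` gene trees along the species tree under the
#' configured scenario. `"none"` yields one copy per species. `"autoWGD"`
#' duplicates the whole clade below the event branch at that branch's
#' midpoint; each copy is then lost per species with `loss_prob`.
#' `"hybridization"` keeps one homeolog set at the clade's true position
#' (parent-A descent, the lineage it is sister to) and grafts a second,
#' clock-depth-matched homeolog set as sister to the `parent_b` clade, so
#' the two homeologs coalesce at the parental-divergence branch -- the
#' branch where apparent duplications are expected to map, which predates
#' the hybridization point itself. Branch lengths receive multiplicative
#' lognormal noise. Leaves are named `<species>_f<family>` with `_c1`/`_c2`
#' suffixes for duplicated copies.
#'
#' @param st A [species_tree()] with branch lengths.
#' @param cfg A [scenario_config()].
#' @return A list of class `sim_phylome`: `phylome` (a [phylome()]) and
#'   `truth`, a tibble with per-family ground truth: `tree_id`, `scenario`,
#'   `true_branch` (where the apparent duplication should map; `NA` when no
#'   duplication survives), `event_branch`, `dup_observable`, `n_copy1`,
#'   `n_copy2`, `seed_gene`, `seed_copies`.
#' @export
simulate_phylome <- function(st, cfg) {
  stopifnot(inherits(st, "species_tree"), inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nested0 <- nested_from_phylo(st$tree)
  scen <- cfg$scenario
  event_node <- if (!is.null(cfg$event_branch)) {
    branch_node(st, cfg$event_branch)
  } else NA_integer_
  post_species <- if (!is.na(event_node)) st$clades[[event_node]] else character()
  if (scen == "hybridization") {
    b_node <- st_mrca(st, cfg$parent_b)
    true_node <- st_mrca(st, c(post_species, cfg$parent_b))
    true_branch <- st$branch_id[true_node]
    depths <- ape::node.depth.edgelength(st$tree)
  } else if (scen == "autoWGD") {
    true_branch <- cfg$event_branch
  } else {
    true_branch <- NA_character_
  }
  trees <- vector("list", cfg$n_families)
  truth <- vector("list", cfg$n_families)
  for (i in seq_len(cfg$n_families)) {
    fam <- sprintf("f%04d", i)
    base <- nested_relabel(nested0, function(l) paste0(l, "_", fam))
    keep1 <- keep2 <- character()
    if (scen == "none") {
      nt <- base
      n1 <- 0L; n2 <- 0L
    } else {
      surv <- draw_copy_survival(post_species, cfg$loss_prob, st$seed_species)
      keep1 <- surv$copy1; keep2 <- surv$copy2
      post_labels <- paste0(post_species, "_", fam)
      if (scen == "autoWGD") {
        nt <- nested_replace(base, event_node, function(sub) {
          duplicate_subtree(sub, fam, keep1, keep2, stem_split = 0.5)
        })
      } else {
        nt <- graft_homeolog(base, st, fam, event_node, b_node,
                             keep1, keep2, depths)
      }
      n1 <- length(keep1); n2 <- length(keep2)
    }
    if (is.null(nt)) next  # cannot happen: seed always retained
    nt <- nested_noise(nt, cfg$branch_noise_sd)
    phy <- nested_to_phylo(nt)
    gt <- gene_tree(phy, rule = species_rule(), tree_id = fam)
    trees[[i]] <- gt
    observable <- scen != "none" && n1 > 0L && n2 > 0L &&
      length(intersect(keep1, keep2)) > 0L
    seed_copies <- c(if (st$seed_species %in% keep1) "c1",
                     if (st$seed_species %in% keep2) "c2")
    seed_leaves <- names(gt$species)[gt$species == st$seed_species]
    seed_gene <- if (length(seed_leaves)) sample(seed_leaves, 1L) else NA_character_
    truth[[i]] <- tibble::tibble(
      tree_id = fam, scenario = scen,
      true_branch = if (isTRUE(observable)) true_branch else NA_character_,
      event_branch = cfg$event_branch %||% NA_character_,
      dup_observable = isTRUE(observable),
      n_copy1 = n1, n_copy2 = n2,
      seed_gene = seed_gene,
      seed_copies = paste(seed_copies, collapse = "+")
    )
  }
  trees <- Filter(Negate(is.null), trees)
  structure(
    list(phylome = phylome(trees, st$seed_species),
         truth = dplyr::bind_rows(truth), config = cfg),
    class = "sim_phylome"
  )
}

# per-copy survival of the doubled species set; the seed always keeps >= 1
draw_copy_survival <- function(post_species, loss_prob, seed_species) {
  copy1 <- post_species[stats::runif(length(post_species)) >= loss_prob]
  copy2 <- post_species[stats::runif(length(post_species)) >= loss_prob]
  if (seed_species %in% post_species &&
      !seed_species %in% c(copy1, copy2)) {
    if (stats::runif(1) < 0.5) copy1 <- c(copy1, seed_species)
    else copy2 <- c(copy2, seed_species)
  }
  list(copy1 = copy1, copy2 = copy2)
}

# replace the event clade by a cherry of two loss-pruned copies
duplicate_subtree <- function(sub, fam, keep1, keep2, stem_split = 0.5) {
  stem <- sub$len %||% NA_real_
  half <- if (is.na(stem)) NA_real_ else stem * stem_split
  strip <- function(node) { node$len <- if (is.na(stem)) NA_real_ else stem - half; node }
  mk <- function(suffix, keep) {
    cp <- nested_relabel(sub, function(l) paste0(l, "_", suffix))
    cp <- strip(cp)
    nested_prune(cp, paste0(keep, "_", fam, "_", suffix))
  }
  c1 <- mk("c1", keep1)
  c2 <- mk("c2", keep2)
  kids <- Filter(Negate(is.null), list(c1, c2))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) {
    k <- kids[[1L]]
    k$len <- sum(c(k$len, half), na.rm = FALSE)
    return(k)
  }
  list(children = kids, len = half, label = NULL, id = NULL)
}

# hybridization: copy1 stays in place; copy2 grafted sister to parent-B
# clade at the midpoint of its stem, depth-matched to the true clade root
graft_homeolog <- function(base, st, fam, event_node, b_node,
                           keep1, keep2, depths) {
  copy1 <- nested_replace(base, event_node, function(sub) {
    cp <- nested_relabel(sub, function(l) paste0(l, "_c1"))
    nested_prune(cp, paste0(keep1, "_", fam, "_c1"))
  })
  if (length(keep2) == 0L) return(copy1)
  sub0 <- nested_subtree(nested_from_phylo(st$tree), event_node)
  cp2 <- nested_relabel(sub0, function(l) paste0(l, "_", fam, "_c2"))
  cp2 <- nested_prune(cp2, paste0(keep2, "_", fam, "_c2"))
  if (is.null(cp2)) return(copy1)
  b_len <- nested_subtree_len(nested_from_phylo(st$tree), b_node)
  attach_depth <- depths[b_node] - b_len / 2
  stem2 <- max(depths[event_node] - attach_depth, 0.01)
  cp2$len <- stem2
  nested_replace(copy1, b_node, function(bsub) {
    half <- (bsub$len %||% 0.02) / 2
    bsub$len <- half
    list(children = list(bsub, cp2), len = half, label = NULL, id = NULL)
  })
}

nested_subtree <- function(node, target_id) {
  if (!is.null(node$id) && identical(node$id, target_id)) return(node)
  if (nested_is_leaf(node)) return(NULL)
  for (ch in node$children) {
    r <- nested_subtree(ch, target_id)
    if (!is.null(r)) return(r)
  }
  NULL
}

nested_subtree_len <- function(node, target_id) {
  sub <- nested_subtree(node, target_id)
  if (is.null(sub)) stop("node not found", call. = FALSE)
  sub$len %||% NA_real_
}

# JTT-style amino-acid stationary frequencies
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
aa_frequencies <- c(0.077, 0.051, 0.043, 0.051, 0.020, 0.041, 0.062,
                    0.074, 0.023, 0.053, 0.091, 0.059, 0.024, 0.040,
                    0.051, 0.069, 0.059, 0.014, 0.032, 0.066)

#' Evolve amino-acid sequences along a gene tree
#'
#' A stationary-frequency replacement model: the root sequence is drawn
#' from amino-acid stationary frequencies; along each branch of length `t`
#' each site is redrawn from the stationary distribution with probability
#' `1 - exp(-r * rate_scale * t)`, where `r` is the site's rate from a
#' discretized gamma (shape `rate_alpha`, `n_rate_categories` classes,
#' mean 1). Indels (single-residue) occur at `indel_freq` per site per
#' unit branch length; the alignment is tracked exactly through insertions
#' and deletions.
#'
#' @param gt A [gene_tree()] with branch lengths.
#' @param cfg A [scenario_config()] (fields `seq_length`, `rate_alpha`,
#'   `n_rate_categories`, `rate_scale`, `indel_freq` are used).
#' @return A character matrix (taxa x alignment columns, gaps `-`) of
#'   class `sim_alignment`.
#' @export
evolve_sequences <- function(gt, cfg) {
  stopifnot(inherits(gt, "gene_tree"), inherits(cfg, "scenario_config"))
  phy <- gt$tree
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("gene tree must have branch lengths", call. = FALSE)
  }
  L <- cfg$seq_length
  if (L < 1L) stop("zero-length sequences requested", call. = FALSE)
  rates <- phangorn::discrete.gamma(cfg$rate_alpha, cfg$n_rate_categories)
  ntip <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  root <- ntip + 1L
  draw <- function(n) sample(aa_alphabet, n, replace = TRUE,
                             prob = aa_frequencies)
  state0 <- list(
    keys = seq_len(L),
    chars = draw(L),
    rates = sample(rates, L, replace = TRUE)
  )
  tips <- vector("list", ntip)
  walk <- function(node, state) {
    if (node <= ntip) {
      tips[[node]] <<- state
      return(invisible())
    }
    for (e in kids[[as.character(node)]]) {
      child <- phy$edge[e, 2L]
      t <- phy$edge.length[e]
      st2 <- evolve_branch(state, t, cfg, draw, rates)
      walk(child, st2)
    }
  }
  walk(root, state0)
  all_keys <- sort(unique(unlist(lapply(tips, `[[`, "keys"))))
  aln <- matrix("-", nrow = ntip, ncol = length(all_keys),
                dimnames = list(phy$tip.label, NULL))
  for (i in seq_len(ntip)) {
    aln[i, match(tips[[i]]$keys, all_keys)] <- tips[[i]]$chars
  }
  structure(aln, class = c("sim_alignment", class(aln)))
}

evolve_branch <- function(state, t, cfg, draw, rates) {
  n <- length(state$chars)
  p_sub <- 1 - exp(-state$rates * cfg$rate_scale * t)
  hit <- stats::runif(n) < p_sub
  if (any(hit)) state$chars[hit] <- draw(sum(hit))
  if (cfg$indel_freq > 0 && n > 0L) {
    p_indel <- 1 - exp(-cfg$indel_freq * t)
    del <- stats::runif(n) < p_indel
    if (any(del) && sum(del) < n) {
      state$keys <- state$keys[!del]
      state$chars <- state$chars[!del]
      state$rates <- state$rates[!del]
    }
    n <- length(state$chars)
    ins <- which(stats::runif(n) < p_indel)
    for (pos in rev(ins)) {
      lo <- state$keys[pos]
      hi <- if (pos < n) state$keys[pos + 1L] else lo + 1
      key <- lo + (hi - lo) * stats::runif(1, 0.25, 0.75)
      state$keys <- append(state$keys, key, after = pos)
      state$chars <- append(state$chars, draw(1L), after = pos)
      state$rates <- append(state$rates, sample(rates, 1L), after = pos)
      n <- n + 1L
    }
  }
  state
}

#' Bifurcate the seed branch to plant a long-branch paralog
#'
#' Replaces the seed leaf by a cherry: one copy keeps half the original
#' terminal branch length, the other gets `lba_multiplier` times the
#' original length, emulating a strongly accelerated paralog.
#'
#' @param gt A [gene_tree()] with branch lengths.
#' @param seed_leaf Leaf label to bifurcate.
#' @param cfg A [scenario_config()] (field `lba_multiplier`).
#' @return A [gene_tree()] with one additional leaf (`<seed_leaf>_c1`, the
#'   slow copy, and `<seed_leaf>_c2`, the accelerated one).
#' @export
apply_lba <- function(gt, seed_leaf, cfg) {
  stopifnot(inherits(gt, "gene_tree"))
  if (!seed_leaf %in% gt$tree$tip.label) {
    stop("seed leaf '", seed_leaf, "' not in tree", call. = FALSE)
  }
  m <- cfg$lba_multiplier
  nt <- nested_from_phylo(gt$tree)
  tip_id <- match(seed_leaf, gt$tree$tip.label)
  nt <- nested_replace(nt, tip_id, function(leaf) {
    L <- leaf$len
    # bifurcation at the branch midpoint: the original leaf keeps the far
    # half (its length "cut in half"), the new paralog evolves m times the
    # original branch length from the split
    list(
      children = list(
        list(label = paste0(leaf$label, "_c1"), len = L / 2),
        list(label = paste0(leaf$label, "_c2"), len = L * m)
      ),
      len = L / 2, label = NULL, id = NULL
    )
  })
  gene_tree(nested_to_phylo(nt), rule = species_rule(), tree_id = gt$tree_id)
}

#' Overwrite part of one paralog with its partner's homologous fragment
#'
#' Emulates partial gene conversion: a uniformly placed contiguous window
#' covering fraction `f` of the alignment columns of `copy1` is replaced
#' by `copy2`'s residues over the same columns. `f = 0` is the identity;
#' `f = 1` makes the two rows identical.
#'
#' @param aln A `sim_alignment` (or any character matrix with named rows).
#' @param copy1,copy2 Row names: the converted and donor sequences.
#' @param f Conversion fraction in `[0, 1]`.
#' @return The modified alignment.
#' @export
apply_gene_conversion <- function(aln, copy1, copy2, f) {
  stopifnot(is.matrix(aln), f >= 0, f <= 1)
  miss <- setdiff(c(copy1, copy2), rownames(aln))
  if (length(miss)) {
    stop("sequence id(s) not in alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  L <- ncol(aln)
  w <- round(f * L)
  if (w == 0L) return(aln)
  if (w > L) w <- L
  start <- if (w == L) 1L else sample.int(L - w + 1L, 1L)
  cols <- start:(start + w - 1L)
  aln[copy1, cols] <- aln[copy2, cols]
  aln
}

#' Simulate gene orders with planted clade-specific breaks
#'
#' Builds an ancestral gene order, keeps it intact in clade A, plants
#' `k_breaks` clade-B-specific rearrangements (suffix-segment
#' translocations to another chromosome end, each breaking exactly one
#' ancestral adjacency), and derives post-WGD genomes as single-copy
#' mosaics whose chromosomes descend from a recorded parent (optionally
#' retaining a fraction of genes in duplicate).
#'
#' @param cladeA,cladeB Character vectors of species codes.
#' @param postwgd Character vector of post-WGD species codes.
#' @param k_breaks Number of planted clade-B rearrangements.
#' @param n_genes,n_chromosomes Ancestral genome size.
#' @param dup_frac Fraction of genes retained in duplicate in post-WGD
#'   species (second copies placed on mirrored chromosomes).
#' @param seed Optional RNG seed.
#' @return List: `table` (a [gene_order_table()]) and `truth` (planted
#'   break adjacencies and per-species chromosome origins).
#' @export
simulate_gene_orders <- function(cladeA, cladeB, postwgd, k_breaks,
                                 n_genes = 100, n_chromosomes = 4,
                                 dup_frac = 0, seed = NULL) {
  stopifnot(k_breaks >= 0, n_genes >= n_chromosomes * 4)
  if (!is.null(seed)) set.seed(seed)
  groups <- sprintf("g%03d", seq_len(n_genes))
  chr_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
  ancestral <- split(groups, chr_of)          # list chr -> ordered groups
  names(ancestral) <- paste0("chr", seq_along(ancestral))
  anc_adj <- unlist(lapply(ancestral, function(g) {
    if (length(g) < 2L) character() else pair_key(g[-length(g)], g[-1L])
  }), use.names = FALSE)
  b_order <- ancestral
  planted <- tibble::tibble(left_group = character(), right_group = character())
  tries <- 0L
  while (nrow(planted) < k_breaks && tries < 1000L) {
    tries <- tries + 1L
    src <- sample(names(b_order), 1L)
    genes <- b_order[[src]]
    if (length(genes) < 4L) next
    cut <- sample(2:(length(genes) - 2L), 1L)   # segment genes[(cut+1):end]
    left <- genes[cut]; right <- genes[cut + 1L]
    if (!pair_key(left, right) %in% anc_adj) next          # already broken
    if (pair_key(left, right) %in% planted_keys(planted)) next
    dst <- sample(setdiff(names(b_order), src), 1L)
    recv_end <- b_order[[dst]][length(b_order[[dst]])]
    # the join must not recreate an ancestral adjacency
    if (pair_key(recv_end, right) %in% anc_adj) next
    seg <- genes[(cut + 1L):length(genes)]
    b_order[[src]] <- genes[seq_len(cut)]
    b_order[[dst]] <- c(b_order[[dst]], seg)
    planted <- dplyr::bind_rows(planted, tibble::tibble(
      left_group = left, right_group = right
    ))
  }
  if (nrow(planted) < k_breaks) {
    stop("could not plant ", k_breaks, " independent breaks; ",
         "increase n_genes or n_chromosomes", call. = FALSE)
  }
  # final clade-B chromosome carrying each break flank: with an A-origin
  # source chromosome a polyploid keeps the ancestral adjacency; with a
  # B-origin source it shows the rearranged arrangement when the
  # destination chromosome is B-derived too, and loses the right flank
  # when it is not
  # truth bookkeeping per break: the ancestral chromosome carries the
  # conserved (clade-A) arrangement; the final clade-B chromosomes of the
  # two flanks carry the rearranged context (flanks can be relocated again
  # by later events, so final positions are recorded, not the cut site)
  if (nrow(planted)) {
    chr_of_b <- function(g) {
      names(b_order)[vapply(b_order, function(x) g %in% x, TRUE)][1L]
    }
    chr_of_anc <- function(g) {
      names(ancestral)[vapply(ancestral, function(x) g %in% x, TRUE)][1L]
    }
    planted$ancestral_chromosome <- vapply(planted$left_group, chr_of_anc, "")
    planted$src_chromosome <- vapply(planted$left_group, chr_of_b, "")
    planted$dst_chromosome <- vapply(planted$right_group, chr_of_b, "")
  }
  rows <- list()
  emit <- function(sp, order_list, chr_prefix = "") {
    purrr::imap_dfr(order_list, function(genes, chr) {
      tibble::tibble(
        species = sp,
        gene_id = paste0(sp, "_", genes),
        chromosome = paste0(chr_prefix, chr),
        position = seq_along(genes) - 1L,
        group = genes
      )
    })
  }
  for (sp in cladeA) rows[[sp]] <- emit(sp, ancestral)
  for (sp in cladeB) rows[[sp]] <- emit(sp, b_order)
  origins <- list()
  for (sp in postwgd) {
    origin <- sample(c("A", "B"), length(ancestral), replace = TRUE)
    names(origin) <- names(ancestral)
    mosaic <- lapply(names(ancestral), function(chr) {
      if (origin[[chr]] == "A") ancestral[[chr]] else b_order[[chr]]
    })
    names(mosaic) <- names(ancestral)
    rows[[sp]] <- emit(sp, mosaic)
    if (dup_frac > 0) {
      dup_genes <- sample(groups, round(dup_frac * n_genes))
      extra <- lapply(mosaic, function(g) intersect(g, dup_genes))
      extra <- Filter(function(g) length(g) > 0L, extra)
      if (length(extra)) {
        dup_rows <- emit(sp, extra, chr_prefix = "dup_")
        dup_rows$gene_id <- paste0(dup_rows$gene_id, "_2")
        rows[[paste0(sp, "_dup")]] <- dup_rows
      }
    }
    origins[[sp]] <- tibble::tibble(species = sp,
                                    chromosome = names(origin),
                                    origin = unname(origin))
  }
  list(
    table = gene_order_table(dplyr::bind_rows(rows)),
    truth = list(breaks = planted,
                 origins = dplyr::bind_rows(origins))
  )
}

planted_keys <- function(planted) {
  if (nrow(planted) == 0L) return(character())
  pair_key(planted$left_group, planted$right_group)
}

#' Write a simulated alignment as FASTA
#'
#' @param aln A `sim_alignment` matrix.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(aln, file) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), file)
  invisible(file)
}

#' Read an aligned FASTA into a sim_alignment matrix
#'
#' @param file FASTA path (sequences must share one length).
#' @return Character matrix of class `sim_alignment`.
#' @export
read_alignment_fasta <- function(file) {
  s <- Biostrings::readAAStringSet(file)
  if (length(unique(Biostrings::width(s))) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(as.character(s), ""))
  rownames(m) <- names(s)
  structure(m, class = c("sim_alignment", class(m)))
}
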