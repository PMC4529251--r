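# shared fixtures, all built in code

toy_species_tree <- function() {
  species_tree("((A:1,B:1):1,C:2);", seed_species = "A")
}

# random binary gene tree over the given species, one gene per species
random_species_topology <- function(species) {
  phy <- ape::rtree(length(species), tip.label = paste0(species, "_g1"))
  gene_tree(phy)
}

# a small hybrid phylome on the reduced yeast tree
sim_hybrid <- function(n, seed, loss = 0.3) {
  st <- yeast_species_tree("reduced")
  cfg <- scenario_config("hybridization",
                         event_branch = st$lineage[length(st$lineage)],
                         parent_b = yeast_clades()$kle,
                         n_families = n, loss_prob = loss, seed = seed)
  list(st = st, sim = simulate_phylome(st, cfg), cfg = cfg)
}

sim_autowgd <- function(n, seed, loss = 0.3, taxa = "full") {
  st <- yeast_species_tree(taxa)
  w <- if (taxa == "full") "n5" else st$lineage[length(st$lineage)]
  cfg <- scenario_config("autoWGD", event_branch = w,
                         n_families = n, loss_prob = loss, seed = seed)
  list(st = st, sim = simulate_phylome(st, cfg), cfg = cfg, w = w)
}
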