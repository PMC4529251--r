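test_that("the same seed reproduces trees, truth, and alignments exactly", {
  st <- yeast_species_tree("full")
  cfg <- scenario_config("autoWGD", event_branch = "n5", n_families = 6,
                         loss_prob = 0.3, seed = 99)
  s1 <- simulate_phylome(st, cfg)
  s2 <- simulate_phylome(st, cfg)
  expect_identical(
    vapply(s1$phylome$trees, write_newick, ""),
    vapply(s2$phylome$trees, write_newick, "")
  )
  expect_identical(s1$truth, s2$truth)
  set.seed(5); a1 <- evolve_sequences(s1$phylome$trees[[1]], cfg)
  set.seed(5); a2 <- evolve_sequences(s2$phylome$trees[[1]], cfg)
  expect_identical(a1, a2)
})

test_that("autoWGD without loss gives every family two seed copies", {
  fix <- sim_autowgd(10, seed = 3, loss = 0)
  for (gt in fix$sim$phylome$trees) {
    expect_equal(sum(gt$species == "Scer"), 2L)
  }
  expect_true(all(fix$sim$truth$dup_observable))
})

test_that("total loss of the duplicate copies collapses to the no-event case", {
  st <- yeast_species_tree("full")
  cfg <- scenario_config("autoWGD", event_branch = "n5", n_families = 5,
                         loss_prob = 1, seed = 12)
  sim <- simulate_phylome(st, cfg)
  for (gt in sim$phylome$trees) {
    # every non-seed post-WGD species loses both copies; the seed keeps one
    expect_equal(sum(gt$species == "Scer"), 1L)
    expect_equal(length(gt$tree$tip.label), 12L)
    expect_equal(nrow(detect_duplications(gt, st)), 0L)
  }
  expect_false(any(sim$truth$dup_observable))
})

test_that("hybridization coalesces homeologs at the parental divergence", {
  fix <- sim_hybrid(12, seed = 8, loss = 0)
  st <- fix$st
  truth <- fix$sim$truth
  # apparent duplication maps to the pre-KLE analog, not the event branch
  expect_true(all(truth$true_branch == "n3"))
  expect_true(all(truth$event_branch == st$lineage[length(st$lineage)]))
  for (gt in fix$sim$phylome$trees) {
    ev <- detect_duplications(gt, st)
    expect_equal(ev$mapped_branch, "n3")
  }
})

test_that("zero branch lengths give identical sequences; indel 0 no gaps", {
  phy <- ape::read.tree(text = "((A_g1:0,B_g1:0):0,C_g1:0);")
  gt <- gene_tree(phy)
  cfg <- scenario_config("none", n_families = 1, seq_length = 50,
                         indel_freq = 0)
  set.seed(1)
  aln <- evolve_sequences(gt, cfg)
  expect_equal(ncol(aln), 50L)
  expect_true(all(aln[1, ] == aln[2, ]))
  expect_true(all(aln != "-"))

  long <- gene_tree(ape::read.tree(
    text = "((A_g1:0.5,B_g1:0.5):0.2,C_g1:0.7);"))
  cfg2 <- scenario_config("none", n_families = 1, seq_length = 200,
                          indel_freq = 0.01)
  set.seed(2)
  aln2 <- evolve_sequences(long, cfg2)
  expect_true(any(aln2 == "-"))  # indels leave tracked gaps
})

test_that("expected divergence grows with path length", {
  cfg <- scenario_config("none", n_families = 1, seq_length = 400,
                         indel_freq = 0)
  mean_D <- function(t, reps = 30) {
    phy <- ape::read.tree(text = sprintf("((A_g1:%f,B_g1:%f):0.1,C_g1:0.1);",
                                         t / 2, t / 2))
    gt <- gene_tree(phy)
    mean(vapply(seq_len(reps), function(i) {
      aln <- evolve_sequences(gt, cfg)
      mean(aln["A_g1", ] != aln["B_g1", ])
    }, 0))
  }
  set.seed(31)
  obs <- c(mean_D(0.1), mean_D(0.4), mean_D(1.0))
  expect_true(all(diff(obs) > 0))
  # replace-with-stationary model with gamma site rates: per site,
  # E[D] = (1 - E_r[exp(-r t)]) * P(redrawn state differs)
  p_diff <- 1 - sum(hybridscan:::aa_frequencies^2 /
                      sum(hybridscan:::aa_frequencies)^2)
  rates <- phangorn::discrete.gamma(1, 16)
  expected <- vapply(c(0.1, 0.4, 1.0),
                     function(t) (1 - mean(exp(-rates * t))) * p_diff, 0)
  expect_equal(obs, expected, tolerance = 0.1)
})

test_that("LBA bifurcation adds one leaf with the configured lengths", {
  gt <- gene_tree(ape::read.tree(text = "((A_g1:0.2,B_g1:0.3):0.1,C_g1:0.4);"))
  cfg <- scenario_config("none", n_families = 1, lba_multiplier = 10)
  out <- apply_lba(gt, "A_g1", cfg)
  expect_equal(length(out$tree$tip.label), 4L)
  el <- out$tree$edge.length
  labs <- out$tree$tip.label
  tip_len <- el[match(match(c("A_g1_c1", "A_g1_c2"), labs),
                      out$tree$edge[, 2])]
  expect_equal(tip_len, c(0.1, 2.0))

  cfg1 <- scenario_config("none", n_families = 1, lba_multiplier = 0.5)
  eq <- apply_lba(gt, "A_g1", cfg1)
  el2 <- eq$tree$edge.length
  tip_len2 <- el2[match(match(c("A_g1_c1", "A_g1_c2"), eq$tree$tip.label),
                        eq$tree$edge[, 2])]
  expect_equal(tip_len2[1], tip_len2[2])  # equal split at multiplier 1/2
})

test_that("gene conversion is the identity at f=0 and total at f=1", {
  set.seed(6)
  aln <- matrix(sample(c("A", "C", "D"), 60, TRUE), nrow = 3,
                dimnames = list(c("x", "y", "z"), NULL))
  expect_identical(apply_gene_conversion(aln, "x", "y", 0), aln)
  full <- apply_gene_conversion(aln, "x", "y", 1)
  expect_identical(full["x", ], full["y", ])
  expect_identical(full["z", ], aln["z", ])
  expect_error(apply_gene_conversion(aln, "x", "nope", 0.5), "not in alignment")
})

test_that("conversion makes paralogs monotonically more similar", {
  st <- yeast_species_tree("reduced")
  cfg <- scenario_config("hybridization",
                         event_branch = st$lineage[length(st$lineage)],
                         parent_b = yeast_clades()$kle,
                         n_families = 1, loss_prob = 0, seq_length = 300,
                         indel_freq = 0, seed = 44)
  sim <- simulate_phylome(st, cfg)
  aln <- evolve_sequences(sim$phylome$trees[[1]], cfg)
  pair <- rownames(aln)[startsWith(rownames(aln), "Scer_")]
  D_at <- function(f) {
    set.seed(10)
    mean(vapply(1:40, function(i) {
      a2 <- apply_gene_conversion(aln, pair[1], pair[2], f)
      mean(a2[pair[1], ] != a2[pair[2], ])
    }, 0))
  }
  Ds <- vapply(c(0, 0.25, 0.5, 0.75, 1), D_at, 0)
  expect_true(all(diff(Ds) < 0))
})
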