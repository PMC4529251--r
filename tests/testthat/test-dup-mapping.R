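test_that("species overlap calls duplications and maps their age", {
  st <- toy_species_tree()
  dup <- detect_duplications(parse_newick("((A_g1,B_g1),(A_g2,B_g2));"), st)
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$mapped_branch, "n1")  # branch above MRCA(A, B)

  none <- detect_duplications(parse_newick("((A_g1,B_g1),C_g1);"), st)
  expect_equal(nrow(none), 0L)

  expect_error(
    detect_duplications(gene_tree(ape::unroot(ape::rtree(4,
      tip.label = paste0(c("A", "B", "C", "A"), "_g", 1:4)))), st),
    "unrooted"
  )
})

test_that("LCA reconciliation agrees with hand-worked cases", {
  st <- toy_species_tree()
  dup <- lca_reconcile(parse_newick("((A_g1,B_g1),(A_g2,B_g2));"), st)
  expect_equal(dup$mapped_branch, "n1")

  # speciation-only tree congruent with the species tree
  expect_equal(nrow(lca_reconcile(parse_newick("((A_g1,B_g1),C_g1);"), st)), 0L)

  # with a loss: ((A,B),A) duplicates at MRCA(A,B)
  ev <- lca_reconcile(parse_newick("((A_g1,B_g1),A_g2);"), st)
  expect_equal(ev$mapped_branch, "n1")

  # polytomies are rejected by the reconciliation oracle only
  poly <- parse_newick("((A_g1,B_g1,C_g1),A_g2);")
  expect_error(lca_reconcile(poly, st), "polytomy")
  expect_silent(detect_duplications(poly, st))
})

test_that("support filtering drops weak and unannotated nodes", {
  st <- toy_species_tree()
  gt <- parse_newick("((A_g1,B_g1)0.5:1,(A_g2,B_g2));")
  expect_equal(nrow(detect_duplications(gt, st, min_support = 0)), 1L)
  # the duplication node is the (unlabelled) root: filtered at 0.95
  expect_equal(nrow(detect_duplications(gt, st, min_support = 0.95)), 0L)
})

test_that("species-overlap equals LCA reconciliation on binary loss-free trees", {
  fix <- sim_autowgd(60, seed = 101, loss = 0)
  fix2 <- sim_hybrid(40, seed = 102, loss = 0)
  trees <- c(fix$sim$phylome$trees, fix2$sim$phylome$trees)
  sts <- c(rep(list(fix$st), 60), rep(list(fix2$st), 40))
  for (i in seq_along(trees)) {
    a <- detect_duplications(trees[[i]], sts[[i]])
    b <- lca_reconcile(trees[[i]], sts[[i]])
    expect_equal(a$node, b$node)
    expect_equal(a$mapped_branch, b$mapped_branch)
  }
})

test_that("density profiles normalize by informative trees", {
  st <- toy_species_tree()
  gts <- list(parse_newick("((A_g1,B_g1),(A_g2,B_g2));", tree_id = "t1"),
              parse_newick("((A_g3,B_g3),C_g1);", tree_id = "t2"))
  prof <- density_profile(phylome(gts, "A"), st)
  expect_s3_class(prof, "density_profile")
  expect_equal(prof$branch_id, c("root", "n1", "n2"))
  # t1 has no species older than n1, so its dup does not enter n1's counts
  expect_equal(prof$dup_count[prof$branch_id == "n1"], 0L)
  expect_equal(prof$informative_trees[prof$branch_id == "n1"], 1L)

  zero <- density_profile(phylome(gts[2], "A"), st)
  expect_true(all(zero$dup_count == 0L))
  expect_true(all(zero$density == 0, na.rm = TRUE))
})

test_that("densities are invariant under leaf reordering", {
  fix <- sim_autowgd(10, seed = 7)
  prof1 <- density_profile(fix$sim$phylome, fix$st)
  rotated <- lapply(fix$sim$phylome$trees, function(gt) {
    phy <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
      gt$tree, rev(sort(gt$tree$tip.label)))))
    gene_tree(phy, tree_id = gt$tree_id)
  })
  prof2 <- density_profile(phylome(rotated, "Scer"), fix$st)
  expect_equal(tibble::as_tibble(prof1), tibble::as_tibble(prof2))
})

test_that("informative-tree counts grow from ancestral to recent branches", {
  fix <- sim_autowgd(40, seed = 21, loss = 0.5)
  prof <- density_profile(fix$sim$phylome, fix$st)
  inner <- prof$informative_trees[prof$branch_id != "root"]
  expect_true(all(diff(inner) >= 0))
})

test_that("total mapped events are conserved in the profile", {
  fix <- sim_autowgd(30, seed = 3, loss = 0)
  prof <- density_profile(fix$sim$phylome, fix$st)
  total <- sum(vapply(fix$sim$phylome$trees, function(gt) {
    nrow(detect_duplications(gt, fix$st))
  }, 0L))
  expect_equal(sum(prof$dup_count), total)
})

test_that("ohnolog subsets count only the pair's duplication node", {
  fix <- sim_autowgd(25, seed = 9, loss = 0)
  truth <- fix$sim$truth
  pairs <- tibble::tibble(
    gene1 = paste0("Scer_", truth$tree_id, "_c1"),
    gene2 = paste0("Scer_", truth$tree_id, "_c2")
  )
  prof <- density_profile(fix$sim$phylome, fix$st, ohnologs = pairs)
  expect_equal(sum(prof$dup_count), 25L)
  expect_equal(prof$dup_count[prof$branch_id == fix$w], 25L)

  empty <- density_profile(fix$sim$phylome, fix$st,
                           ohnologs = tibble::tibble(gene1 = character(),
                                                     gene2 = character()))
  expect_true(all(empty$dup_count == 0L))
})

test_that("mapping agreement is scored over shared trees", {
  a <- tibble::tibble(tree_id = c("t1", "t2"), mapped_branch = c("n1", "n2"))
  expect_equal(compare_mappings(a, a)$pct_agreement, 100)
  b <- tibble::tibble(tree_id = c("t3", "t4"), mapped_branch = c("n1", "n2"))
  res <- compare_mappings(a, b)
  expect_equal(res$n_shared, 0L)
  expect_true(is.na(res$pct_agreement))
  c_ <- tibble::tibble(tree_id = c("t1", "t2"), mapped_branch = c("n1", "n3"))
  expect_equal(compare_mappings(a, c_)$pct_agreement, 50)
})

test_that("ohnolog monophyly test compares rooted and outgroup-free trees", {
  # pair sister in both trees -> consistent
  rooted <- parse_newick("(((S_a,S_b)0.9,(Z_1,K_1)),O_1);")
  noout <- parse_newick("((S_a,S_b)0.9,(Z_1,K_1));")
  res <- ohnolog_monophyly_test(noout, rooted, c("S_a", "S_b"),
                                parental_species = c("Z", "K"))
  expect_equal(res$call, "consistent")
  expect_true(res$mono_rooted)

  # a parental leaf inside the pair clade in one tree only -> inconsistent
  noout2 <- parse_newick("(((S_a,Z_1)0.9,S_b)0.9,K_1);")
  res2 <- ohnolog_monophyly_test(noout2, rooted, c("S_a", "S_b"),
                                 parental_species = c("Z", "K"))
  expect_equal(res2$call, "inconsistent")

  # low support -> unfilterable
  weak <- parse_newick("(((S_a,S_b)0.3,(Z_1,K_1)),O_1);")
  res3 <- ohnolog_monophyly_test(noout, weak, c("S_a", "S_b"),
                                 parental_species = c("Z", "K"))
  expect_equal(res3$call, "unfilterable")

  expect_error(
    ohnolog_monophyly_test(noout, rooted, c("S_a", "S_missing"),
                           parental_species = c("Z", "K")),
    "missing"
  )
})
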