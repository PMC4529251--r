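test_that("parsing extracts species, supports, and lengths", {
  gt <- parse_newick("((A_g1:1,B_g1:1)0.99:1,C_g1:2);")
  expect_setequal(unname(gt$species), c("A", "B", "C"))
  expect_equal(length(gt$tree$tip.label), 3L)
  sup <- hybridscan:::gene_tree_supports(gt)
  expect_true(0.99 %in% sup)

  gt2 <- parse_newick("((A_g1,B_g1),(A_g2,B_g2));")
  expect_equal(sum(gt2$species == "A"), 2L)

  # bootstrap percentages are normalized to [0, 1]
  gt3 <- parse_newick("((A_g1:1,B_g1:1)95:1,C_g1:2);")
  expect_true(0.95 %in% hybridscan:::gene_tree_supports(gt3))
})

test_that("malformed input and unknown naming raise informative errors", {
  expect_error(parse_newick("((A_g1,B_g1"), "malformed")
  expect_error(extract_species(c("ok_1", ""), species_rule()), "species rule")
})

test_that("parse-write-parse is the identity on topology, supports, lengths", {
  txt <- "((A_g1:1.5,B_g1:0.5)0.87:1,(C_g1:2,D_g1:1)0.42:0.3);"
  gt <- parse_newick(txt)
  rt <- parse_newick(write_newick(gt))
  expect_true(ape::all.equal.phylo(gt$tree, rt$tree,
                                   use.edge.length = FALSE))
  expect_equal(sort(hybridscan:::gene_tree_supports(gt)),
               sort(hybridscan:::gene_tree_supports(rt)))
  expect_equal(sort(gt$tree$edge.length), sort(rt$tree$edge.length))
})

test_that("outgroup rooting places the root on the outgroup split", {
  gt <- parse_newick("((A_g1,B_g1),C_out);")
  rooted <- root_with_outgroup(gt, "C")
  phy <- rooted$tree
  root_children <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  tip_sets <- lapply(root_children, function(n) {
    if (n <= length(phy$tip.label)) phy$tip.label[n]
    else ape::extract.clade(phy, n)$tip.label
  })
  expect_true(any(vapply(tip_sets, function(s) identical(s, "C_out"), TRUE)))

  # already rooted on the outgroup: unchanged topology
  again <- root_with_outgroup(rooted, "C")
  expect_true(ape::all.equal.phylo(rooted$tree, again$tree,
                                   use.edge.length = FALSE))
})

test_that("rooting isolates a multi-leaf outgroup clade (randomized)", {
  set.seed(71)
  for (i in 1:10) {
    # build a tree guaranteed to contain an outgroup cherry
    ingroup <- ape::rtree(8, tip.label = paste0(LETTERS[1:8], "_g1"))
    out <- ape::read.tree(text = "(O_g1:1,O_g2:1):1;")
    phy <- ape::bind.tree(ingroup, out,
                          where = sample(seq_len(8), 1))
    gt <- gene_tree(ape::unroot(phy))
    rooted <- root_with_outgroup(gt, "O")
    phy2 <- rooted$tree
    root_children <- phy2$edge[phy2$edge[, 1] == length(phy2$tip.label) + 1L, 2]
    tip_sets <- lapply(root_children, function(n) {
      if (n <= length(phy2$tip.label)) phy2$tip.label[n]
      else ape::extract.clade(phy2, n)$tip.label
    })
    hit <- vapply(tip_sets, function(s) setequal(s, c("O_g1", "O_g2")), TRUE)
    expect_true(any(hit))
  }
})

test_that("pruning keeps additive path lengths and drops other species", {
  gt <- prune_to_species(parse_newick("((A_g1:1,C_g1:1):2,B_g1:1);"),
                         c("A", "B"))
  expect_setequal(gt$tree$tip.label, c("A_g1", "B_g1"))
  expect_equal(sum(gt$tree$edge.length), 4)

  # keep = all species is the identity up to representation
  full <- parse_newick("((A_g1:1,C_g1:1):2,B_g1:1);")
  same <- prune_to_species(full, c("A", "B", "C"))
  expect_true(ape::all.equal.phylo(full$tree, same$tree,
                                   use.edge.length = FALSE))

  expect_error(prune_to_species(full, "A"), "fewer than 2")
  expect_error(prune_to_species(full, "Z"), "no leaf")
})

test_that("rooting and pruning never change in-group leaf path lengths", {
  set.seed(13)
  for (i in 1:5) {
    phy <- ape::rtree(9, tip.label = c(paste0("S", 1:7, "_g1"),
                                       "Out_g1", "Out_g2"))
    gt <- gene_tree(phy)
    d0 <- ape::cophenetic.phylo(phy)
    rooted <- root_with_outgroup(gt, "Out")
    d1 <- ape::cophenetic.phylo(rooted$tree)
    ing <- paste0("S", 1:7, "_g1")
    expect_equal(d1[ing, ing], d0[ing, ing], tolerance = 1e-10)
    pruned <- prune_to_species(gt, paste0("S", 1:7))
    d2 <- ape::cophenetic.phylo(pruned$tree)
    expect_equal(d2[ing, ing], d0[ing, ing], tolerance = 1e-10)
  }
})

test_that("phylome validates seed-species presence and species maps load", {
  t1 <- parse_newick("((A_g1,B_g1),C_g1);", tree_id = "a")
  t2 <- parse_newick("((B_g2,C_g2),B_g3);", tree_id = "b")
  expect_error(phylome(list(t1, t2), "A"), "no leaf of the seed")
  p <- phylome(list(t1), "A")
  expect_equal(names(p$trees), "a")

  tmp <- tempfile(fileext = ".tsv")
  writeLines("leaf\tspecies\nx1\tA\nx2\tB", tmp)
  m <- read_species_map(tmp)
  expect_equal(m[["x1"]], "A")
})
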