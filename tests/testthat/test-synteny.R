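toy_orders <- function(orders) {
  # orders: named list species -> list(chromosome -> gene vector);
  # ortholog group = gene name
  rows <- purrr::imap_dfr(orders, function(chrs, sp) {
    purrr::imap_dfr(chrs, function(genes, chr) {
      tibble::tibble(species = sp, gene_id = paste0(sp, "_", genes),
                     chromosome = chr, position = seq_along(genes) - 1L,
                     group = genes)
    })
  })
  gene_order_table(rows)
}

test_that("conserved adjacency fractions are orientation-agnostic", {
  t <- toy_orders(list(
    s1 = list(c1 = c("g1", "g2", "g3", "g4", "g5")),
    s2 = list(c1 = c("g5", "g4", "g3", "g2", "g1"))
  ))
  res <- conserved_adjacent_pairs("s1", "s2", t)
  expect_equal(res$fraction, 1.0)
  expect_equal(res$n_pairs, 4L)

  ident <- conserved_adjacent_pairs("s1", "s1", t)
  expect_equal(ident$fraction, 1.0)
  expect_error(conserved_adjacent_pairs("s1", "zz", t), "not present")
})

test_that("a transposed gene breaks exactly the enumerated adjacencies", {
  g <- paste0("g", 1:10)
  moved <- c("g1", "g3", "g4", "g5", "g6", "g7", "g2", "g8", "g9", "g10")
  t <- toy_orders(list(s1 = list(c1 = g), s2 = list(c1 = moved)))
  # brute force: adjacencies of s1 absent from s2
  adj <- function(x) paste(pmin(x[-length(x)], x[-1]),
                           pmax(x[-length(x)], x[-1]), sep = "|")
  expected <- sum(!adj(g) %in% adj(moved))
  res <- conserved_adjacent_pairs("s1", "s2", t)
  expect_equal(res$n_pairs - res$n_conserved, expected)
})

test_that("clade-specific breaks are detected with their mirror adjacency", {
  t <- toy_orders(list(
    z1 = list(c1 = c("g1", "g2", "g3")),
    z2 = list(c1 = c("g1", "g2", "g3")),
    k1 = list(c1 = c("g1", "g3", "g2")),
    k2 = list(c1 = c("g1", "g3", "g2"))
  ))
  br <- detect_clade_breaks(c("z1", "z2"), c("k1", "k2"), t)
  expect_equal(sum(br$conserved_in == "A"), 1L)
  expect_equal(sum(br$conserved_in == "B"), 1L)
  expect_setequal(
    paste(br$left_group, br$right_group)[br$conserved_in == "A"], "g1 g2")

  # swapping the clades returns the same adjacency set, labels swapped
  br2 <- detect_clade_breaks(c("k1", "k2"), c("z1", "z2"), t)
  key <- function(b) sort(paste(b$left_group, b$right_group, b$type))
  expect_equal(key(br), key(br2))
  expect_equal(sort(br$conserved_in), sort(chartr("AB", "BA", br2$conserved_in)))

  none <- detect_clade_breaks(c("z1", "z2"), c("z1", "z2"), t)
  expect_equal(nrow(none), 0L)
})

test_that("single-gene translocations are reported separately", {
  # g5 moved to another chromosome in clade B; flanks g4-g6 rejoin
  t <- toy_orders(list(
    a1 = list(c1 = paste0("g", 1:8), c2 = c("h1", "h2", "h3")),
    a2 = list(c1 = paste0("g", 1:8), c2 = c("h1", "h2", "h3")),
    b1 = list(c1 = c("g1", "g2", "g3", "g4", "g6", "g7", "g8"),
              c2 = c("h1", "h2", "h3", "g5")),
    b2 = list(c1 = c("g1", "g2", "g3", "g4", "g6", "g7", "g8"),
              c2 = c("h1", "h2", "h3", "g5"))
  ))
  br <- detect_clade_breaks(c("a1", "a2"), c("b1", "b2"), t)
  a_side <- br[br$conserved_in == "A", ]
  expect_setequal(a_side$type[a_side$left_group %in% c("g4", "g5")],
                  "single_gene_translocation")
})

test_that("planted clade breaks are recovered and inheritance classified", {
  sim <- simulate_gene_orders(cladeA = c("z1", "z2"), cladeB = c("k1", "k2"),
                              postwgd = c("p1", "p2", "p3"), k_breaks = 5,
                              n_genes = 120, seed = 42)
  br <- detect_clade_breaks(c("z1", "z2"), c("k1", "k2"), sim$table)
  a_breaks <- br[br$conserved_in == "A" & br$type == "break", ]
  expect_equal(nrow(a_breaks), 5L)
  expect_setequal(
    paste(a_breaks$left_group, a_breaks$right_group),
    paste(sim$truth$breaks$left_group, sim$truth$breaks$right_group)
  )

  classed <- classify_break_inheritance(a_breaks, c("p1", "p2", "p3"),
                                        sim$table)
  # expected inheritance from the planted chromosome origins: an A-derived
  # source chromosome keeps the ancestral adjacency; a B-derived source
  # shows the rearrangement when the destination is B-derived too, and
  # loses the right flank otherwise
  truth_b <- sim$truth$breaks
  origin_of <- function(sp, chr) {
    o <- sim$truth$origins
    o$origin[o$species == sp & o$chromosome == chr]
  }
  n_ok <- 0L; n_scored <- 0L
  for (i in seq_len(nrow(classed))) {
    tr <- truth_b[truth_b$left_group == classed$left_group[i], ]
    for (sp in c("p1", "p2", "p3")) {
      anc_a <- origin_of(sp, tr$ancestral_chromosome) == "A"
      left_present <- anc_a || origin_of(sp, tr$src_chromosome) == "B"
      right_present <- anc_a || origin_of(sp, tr$dst_chromosome) == "B"
      want <- if (anc_a) {
        "conserving"  # species kept the ancestral-arrangement chromosome
      } else if (left_present && right_present) {
        "other"       # both flanks present, in their rearranged context
      } else {
        "missing"     # a flank was lost with an unchosen chromosome
      }
      n_scored <- n_scored + 1L
      if (classed[[sp]][i] == want) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_scored, 0.95)

  zero <- simulate_gene_orders(c("z1", "z2"), c("k1", "k2"), character(),
                               k_breaks = 0, n_genes = 60, seed = 1)
  expect_equal(nrow(detect_clade_breaks(c("z1", "z2"), c("k1", "k2"),
                                        zero$table)), 0L)
})

test_that("breakpoint distance counts hand-enumerated breakpoints", {
  g <- paste0("g", sprintf("%02d", 1:10))
  inv <- g; inv[4:6] <- rev(inv[4:6])
  t <- toy_orders(list(s1 = list(c1 = g), s2 = list(c1 = inv)))
  expect_equal(breakpoint_distance("s1", "s1", t), 0L)
  expect_equal(breakpoint_distance("s1", "s2", t), 2L)
  expect_equal(breakpoint_distance("s2", "s1", t), 2L)

  few <- toy_orders(list(s1 = list(c1 = "g1"), s2 = list(c1 = "g1")))
  expect_error(breakpoint_distance("s1", "s2", few), "fewer than 2")
})

test_that("breakpoint distance is a metric on loss-free permutations", {
  set.seed(17)
  g <- paste0("g", sprintf("%02d", 1:12))
  perms <- list(g, sample(g), sample(g), sample(g))
  orders <- stats::setNames(
    lapply(perms, function(p) list(c1 = p)),
    paste0("s", seq_along(perms))
  )
  t <- toy_orders(orders)
  n <- length(perms)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) d[i, j] <- breakpoint_distance(paste0("s", i),
                                               paste0("s", j), t)
  }
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("gene order tables validate their invariants", {
  bad <- tibble::tibble(species = "s", gene_id = c("a", "b"),
                        chromosome = "c1", position = c(0L, 0L),
                        group = c("g1", "g2"))
  expect_error(gene_order_table(bad), "duplicated positions")
  expect_error(gene_order_table(bad[, 1:4]), "missing column")
})
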