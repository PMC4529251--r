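#' Gene-order table
#'
#' Tidy per-gene genome coordinates plus ortholog-group membership, the
#' generic stand-in for pillar-style gene-order resources. Positions are
#' 0-based indices along a chromosome; adjacency is orientation-agnostic
#' and chromosome ends are not adjacencies.
#'
#' @param df Data frame with columns `species`, `gene_id`, `chromosome`,
#'   `position` (integer, unique within species x chromosome), `group`
#'   (ortholog group id; `NA` allowed).
#' @return The validated tibble with class `gene_order_table`.
#' @export
gene_order_table <- function(df) {
  need <- c("species", "gene_id", "chromosome", "position", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene order table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  dup <- df |>
    dplyr::count(.data$species, .data$chromosome, .data$position) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicated positions within a chromosome (e.g. ",
         dup$species[1L], " ", dup$chromosome[1L], ":", dup$position[1L], ")",
         call. = FALSE)
  }
  multi <- df |>
    dplyr::distinct(.data$species, .data$gene_id, .data$group) |>
    dplyr::count(.data$species, .data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    stop("gene(s) assigned to more than one ortholog group", call. = FALSE)
  }
  structure(df, class = c("gene_order_table", class(df)))
}

#' Read a gene-order TSV
#'
#' @param path TSV with columns species, gene_id, chromosome, position,
#'   group.
#' @return A [gene_order_table()].
#' @export
read_gene_order <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    species = "c", gene_id = "c", chromosome = "c",
    position = "i", group = "c"
  ))
  gene_order_table(df)
}

# adjacency list of a species: one row per consecutive gene pair
species_adjacencies <- function(t, species) {
  sub <- dplyr::filter(t, .data$species == !!species)
  if (nrow(sub) == 0L) {
    stop("species '", species, "' not present in the gene order table",
         call. = FALSE)
  }
  sub |>
    dplyr::arrange(.data$chromosome, .data$position) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::reframe(
      gene1 = .data$gene_id[-dplyr::n()], gene2 = .data$gene_id[-1L],
      group1 = .data$group[-dplyr::n()], group2 = .data$group[-1L]
    ) |>
    dplyr::ungroup()
}

# unordered group-pair keys for a species' adjacencies (NA groups dropped)
adjacency_keys <- function(t, species) {
  adj <- species_adjacencies(t, species)
  adj <- dplyr::filter(adj, !is.na(.data$group1), !is.na(.data$group2))
  pair_key(adj$group1, adj$group2)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

groups_of <- function(t, species) {
  unique(stats::na.omit(dplyr::filter(t, .data$species == !!species)$group))
}

#' Conserved adjacent gene pairs between two genomes
#'
#' For every pair of genes adjacent in species `a` whose ortholog groups
#' are both represented in species `b`, checks whether some orthologs are
#' also adjacent in `b` (orientation-agnostic).
#'
#' @param a,b Species codes present in the table.
#' @param t A [gene_order_table()].
#' @return One-row tibble: `species_a`, `species_b`, `n_pairs` (scorable
#'   adjacencies of `a`), `n_conserved`, `fraction`.
#' @export
conserved_adjacent_pairs <- function(a, b, t) {
  stopifnot(inherits(t, "gene_order_table"))
  adj_a <- species_adjacencies(t, a)
  adj_a <- dplyr::filter(adj_a, !is.na(.data$group1), !is.na(.data$group2))
  groups_b <- groups_of(t, b)
  scorable <- adj_a$group1 %in% groups_b & adj_a$group2 %in% groups_b
  keys_b <- adjacency_keys(t, b)
  conserved <- pair_key(adj_a$group1, adj_a$group2) %in% keys_b & scorable
  n <- sum(scorable)
  tibble::tibble(
    species_a = a, species_b = b,
    n_pairs = n, n_conserved = sum(conserved),
    fraction = if (n > 0) sum(conserved) / n else NA_real_
  )
}

#' Clade-specific synteny breaks
#'
#' Scans reference orderings from both clades for adjacencies conserved in
#' every scorable member of one clade and present in no scorable member of
#' the other. Adjacencies unscorable in a species (an ortholog group
#' missing) do not count against the all-members requirement. Single-gene
#' translocations -- a gene whose two flanking adjacencies are clade-broken
#' while its flanks are adjacent to each other in the other clade -- are
#' reported with `type = "single_gene_translocation"`; plain breaks with
#' `type = "break"`.
#'
#' @param cladeA,cladeB Character vectors of species codes (>= 2 per clade
#'   recommended).
#' @param t A [gene_order_table()].
#' @param reference Reference species per clade; defaults to the first
#'   member of each.
#' @return Tibble with one row per clade-specific adjacency: `left_group`,
#'   `right_group`, `conserved_in` (`"A"` or `"B"`), `type`, and the other
#'   clade's local neighbours `alt_left`, `alt_right` (the group adjacent
#'   to `left_group`/`right_group` in the other clade's reference, used by
#'   [classify_break_inheritance()]).
#' @export
detect_clade_breaks <- function(cladeA, cladeB, t,
                                reference = c(cladeA[1L], cladeB[1L])) {
  stopifnot(inherits(t, "gene_order_table"))
  scan_one <- function(ref, own, other, label, other_ref) {
    adj <- species_adjacencies(t, ref)
    adj <- dplyr::filter(adj, !is.na(.data$group1), !is.na(.data$group2))
    own_keys <- lapply(own, adjacency_keys, t = t)
    other_keys <- lapply(other, adjacency_keys, t = t)
    own_groups <- lapply(own, groups_of, t = t)
    other_groups <- lapply(other, groups_of, t = t)
    keys <- pair_key(adj$group1, adj$group2)
    keep <- logical(nrow(adj))
    for (i in seq_len(nrow(adj))) {
      g <- c(adj$group1[i], adj$group2[i])
      cons_own <- vapply(seq_along(own), function(j) {
        if (!all(g %in% own_groups[[j]])) return(NA)
        keys[i] %in% own_keys[[j]]
      }, NA)
      cons_other <- vapply(seq_along(other), function(j) {
        if (!all(g %in% other_groups[[j]])) return(NA)
        keys[i] %in% other_keys[[j]]
      }, NA)
      keep[i] <- any(cons_own %in% TRUE) && !any(cons_own %in% FALSE) &&
        any(cons_other %in% FALSE) && !any(cons_other %in% TRUE)
    }
    if (!any(keep)) {
      return(tibble::tibble(left_group = character(), right_group = character(),
                            conserved_in = character(),
                            alt_left = character(), alt_right = character()))
    }
    hits <- adj[keep, ]
    other_adj <- species_adjacencies(t, other_ref)
    neighbour <- function(grp, not_grp) {
      n <- c(other_adj$group2[other_adj$group1 %in% grp],
             other_adj$group1[other_adj$group2 %in% grp])
      n <- setdiff(stats::na.omit(n), not_grp)
      if (length(n)) n[1L] else NA_character_
    }
    tibble::tibble(
      left_group = hits$group1, right_group = hits$group2,
      conserved_in = label,
      alt_left = vapply(seq_len(nrow(hits)), function(i) {
        neighbour(hits$group1[i], hits$group2[i])
      }, ""),
      alt_right = vapply(seq_len(nrow(hits)), function(i) {
        neighbour(hits$group2[i], hits$group1[i])
      }, "")
    )
  }
  out <- dplyr::bind_rows(
    scan_one(reference[1L], cladeA, cladeB, "A", reference[2L]),
    scan_one(reference[2L], cladeB, cladeA, "B", reference[1L])
  )
  if (nrow(out) == 0L) {
    out$type <- character()
    return(structure(out, class = c("synteny_breaks", class(out))))
  }
  # single-gene translocation: gene g with both flank adjacencies (w,g),
  # (g,y) clade-broken while (w,y) is adjacent in the other clade
  out$type <- "break"
  for (lab in c("A", "B")) {
    rows <- which(out$conserved_in == lab)
    if (length(rows) < 2L) next
    other_ref <- if (lab == "A") reference[2L] else reference[1L]
    other_keys <- adjacency_keys(t, other_ref)
    grp <- c(out$left_group[rows], out$right_group[rows])
    for (g in unique(grp[duplicated(grp)])) {
      touching <- rows[out$left_group[rows] == g | out$right_group[rows] == g]
      if (length(touching) != 2L) next
      flanks <- setdiff(c(out$left_group[touching], out$right_group[touching]), g)
      if (length(flanks) == 2L && pair_key(flanks[1L], flanks[2L]) %in% other_keys) {
        out$type[touching] <- "single_gene_translocation"
      }
    }
  }
  structure(out, class = c("synteny_breaks", class(out)))
}

#' Classify how polyploid genomes inherited a clade-specific break
#'
#' For each post-WGD species, tests whether its (possibly duplicated)
#' orthologs around the break follow the arrangement of the clade that
#' conserves the adjacency (`A-like`/`B-like` relative to the break's
#' `conserved_in` clade) or the other clade's local arrangement; duplicated
#' regions match when either copy matches.
#'
#' @param breaks Output of [detect_clade_breaks()].
#' @param postwgd Character vector of post-WGD species codes.
#' @param t A [gene_order_table()].
#' @return `breaks` with one added column per post-WGD species, values in
#'   `conserving`, `other`, `neither`, `missing` -- `conserving` means the
#'   species keeps the adjacency of the clade listed in `conserved_in`.
#' @export
classify_break_inheritance <- function(breaks, postwgd, t) {
  stopifnot(inherits(t, "gene_order_table"))
  keys_by_sp <- lapply(postwgd, adjacency_keys, t = t)
  groups_by_sp <- lapply(postwgd, groups_of, t = t)
  names(keys_by_sp) <- names(groups_by_sp) <- postwgd
  for (sp in postwgd) {
    vals <- character(nrow(breaks))
    for (i in seq_len(nrow(breaks))) {
      g <- c(breaks$left_group[i], breaks$right_group[i])
      if (!all(g %in% groups_by_sp[[sp]])) {
        vals[i] <- "missing"
        next
      }
      conserving <- pair_key(g[1L], g[2L]) %in% keys_by_sp[[sp]]
      alt_keys <- stats::na.omit(c(
        if (!is.na(breaks$alt_left[i])) pair_key(g[1L], breaks$alt_left[i]),
        if (!is.na(breaks$alt_right[i])) pair_key(g[2L], breaks$alt_right[i])
      ))
      other <- length(alt_keys) > 0L && any(alt_keys %in% keys_by_sp[[sp]])
      vals[i] <- if (conserving && !other) "conserving"
        else if (other && !conserving) "other"
        else if (conserving && other) "conserving"  # either copy matching the
        # conserved arrangement is taken as evidence for it
        else "neither"
    }
    breaks[[sp]] <- vals
  }
  breaks
}

#' Unsigned breakpoint distance between two genomes
#'
#' Restricted to ortholog groups single-copy in both species, counts the
#' adjacencies of `a`'s reduced gene order that are absent from `b`'s -- a
#' desk-scale substitute for rearrangement-scenario counting.
#'
#' @inheritParams conserved_adjacent_pairs
#' @return Integer breakpoint count.
#' @export
breakpoint_distance <- function(a, b, t) {
  stopifnot(inherits(t, "gene_order_table"))
  single_copy <- function(sp) {
    dplyr::filter(t, .data$species == !!sp, !is.na(.data$group)) |>
      dplyr::add_count(.data$group) |>
      dplyr::filter(.data$n == 1L) |>
      dplyr::select(-"n")
  }
  ta <- single_copy(a); tb <- single_copy(b)
  shared <- intersect(ta$group, tb$group)
  if (length(shared) < 2L) {
    stop("fewer than 2 shared single-copy ortholog groups", call. = FALSE)
  }
  reduced_keys <- function(sub) {
    sub |>
      dplyr::filter(.data$group %in% shared) |>
      dplyr::arrange(.data$chromosome, .data$position) |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::reframe(g1 = .data$group[-dplyr::n()], g2 = .data$group[-1L]) |>
      (\(d) pair_key(d$g1, d$g2))()
  }
  ka <- reduced_keys(ta); kb <- reduced_keys(tb)
  sum(!ka %in% kb)
}
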