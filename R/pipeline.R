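#' Read a phylome from a directory or multi-tree Newick file
#'
#' Accepts either a directory of `*.nwk`/`*.newick`/`*.tree` files (tree id
#' = file name) or a single file with one Newick per line (tree id =
#' `tree<line>`).
#'
#' @param path Directory or file path.
#' @param seed_species Seed species code.
#' @param rule A [species_rule()].
#' @return A [phylome()].
#' @export
read_phylome <- function(path, seed_species, rule = species_rule()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(nwk|newick|tree)$",
                        full.names = TRUE)
    if (length(files) == 0L) {
      stop("no Newick files found in ", path, call. = FALSE)
    }
    trees <- lapply(files, function(f) {
      parse_newick(f, rule = rule, file = TRUE,
                   tree_id = sub("\\.[^.]+$", "", basename(f)))
    })
  } else if (file.exists(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty phylome file", call. = FALSE)
    trees <- lapply(seq_along(lines), function(i) {
      parse_newick(lines[i], rule = rule, tree_id = paste0("tree", i))
    })
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
  phylome(trees, seed_species)
}

#' Write a phylome to a multi-tree Newick file
#'
#' One tree per line plus a companion `<file>.ids.tsv` mapping line to
#' tree id.
#'
#' @param p A [phylome()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_phylome <- function(p, file) {
  txt <- vapply(p$trees, write_newick, "")
  writeLines(txt, file)
  readr::write_tsv(
    tibble::tibble(line = seq_along(txt), tree_id = names(p$trees)),
    paste0(file, ".ids.tsv")
  )
  invisible(file)
}

# run manifest: config snapshot + seed + outputs, for bit-exact re-runs
write_manifest <- function(out_dir, stage, params, outputs, seed = NULL) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("hybridscan")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    params = params,
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Run the simulation stage and write its artifacts
#'
#' @param cfg A [scenario_config()] or the path to a YAML file with its
#'   fields (plus optional `species_tree`: `"full"`/`"reduced"` or a
#'   Newick string with `seed_species`).
#' @param out_dir Output directory (created if needed).
#' @param st Species tree; overrides any YAML setting.
#' @return The `sim_phylome`, invisibly. Writes `gene_trees.nwk`,
#'   `truth.tsv`, and a JSON run manifest.
#' @export
run_simulation <- function(cfg, out_dir, st = NULL) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    if (is.null(st)) {
      st_spec <- y$species_tree %||% "full"
      st <- if (st_spec %in% c("full", "reduced")) {
        yeast_species_tree(st_spec)
      } else {
        species_tree(st_spec, seed_species = y$seed_species)
      }
    }
    y$species_tree <- NULL; y$seed_species <- NULL
    cfg <- do.call(scenario_config, y)
  }
  if (is.null(st)) st <- yeast_species_tree("full")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_phylome(st, cfg)
  trees_path <- file.path(out_dir, "gene_trees.nwk")
  write_phylome(sim$phylome, trees_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path)
  write_manifest(out_dir, "simulate", unclass(cfg),
                 c(trees_path, truth_path), seed = cfg$seed)
  message("simulate: ", length(sim$phylome$trees), " gene trees written")
  invisible(sim)
}

#' Run the duplication-density stage
#'
#' @param p A [phylome()] or a path accepted by [read_phylome()].
#' @param st A [species_tree()].
#' @param out_dir Output directory.
#' @param ohnologs Optional ohnolog-pair TSV path (columns gene1, gene2) or
#'   tibble.
#' @param min_support Support filter.
#' @param seed_species Needed when `p` is a path.
#' @return The [density_profile()], invisibly. Writes `density.tsv` and a
#'   manifest.
#' @export
run_density <- function(p, st, out_dir, ohnologs = NULL, min_support = 0,
                        seed_species = st$seed_species) {
  if (is.character(p)) p <- read_phylome(p, seed_species)
  if (length(p$trees) == 0L) stop("empty phylome", call. = FALSE)
  if (is.character(ohnologs)) {
    ohnologs <- readr::read_tsv(ohnologs,
                                col_types = readr::cols(.default = "c"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- density_profile(p, st, ohnologs = ohnologs,
                          min_support = min_support)
  path <- file.path(out_dir, "density.tsv")
  readr::write_tsv(prof, path)
  write_manifest(out_dir, "density",
                 list(min_support = min_support,
                      subset = !is.null(ohnologs),
                      n_trees = attr(prof, "n_trees")),
                 path)
  message("density: ", attr(prof, "n_trees"), " trees used, peak at ",
          prof$branch_id[which.max(prof$density)])
  invisible(prof)
}

#' Run the topology-scanning stage
#'
#' @inheritParams run_density
#' @param parentA,parentB,outgroups Species-code vectors.
#' @param min_support Support filter (default 0.95).
#' @return The calls tibble, invisibly. Writes `topology_calls.tsv`,
#'   `topology_frequencies.csv`, and a manifest.
#' @export
run_toposcan <- function(p, st, out_dir, parentA, parentB, outgroups,
                         min_support = 0.95,
                         seed_species = st$seed_species) {
  if (is.character(p)) p <- read_phylome(p, seed_species)
  if (length(p$trees) == 0L) stop("empty phylome", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- scan_phylome_topologies(p, parentA, parentB, outgroups,
                                   min_support = min_support)
  dist <- topology_distribution(calls)
  calls_path <- file.path(out_dir, "topology_calls.tsv")
  freq_path <- file.path(out_dir, "topology_frequencies.csv")
  readr::write_tsv(calls, calls_path)
  readr::write_csv(tibble::as_tibble(dist), freq_path)
  write_manifest(out_dir, "toposcan",
                 list(parentA = parentA, parentB = parentB,
                      outgroups = outgroups, min_support = min_support,
                      n_passing = attr(dist, "n_passing"),
                      n_total = attr(dist, "n_total")),
                 c(calls_path, freq_path))
  message("toposcan: ", attr(dist, "n_passing"), "/", attr(dist, "n_total"),
          " trees pass filters")
  invisible(calls)
}

#' Run the synteny-break stage
#'
#' @param gene_order A [gene_order_table()] or TSV path.
#' @param cladeA,cladeB,postwgd Species-code vectors.
#' @param out_dir Output directory.
#' @return The classified breaks tibble, invisibly. Writes `breaks.tsv`,
#'   `adjacency_stats.tsv`, and a manifest.
#' @export
run_synteny <- function(gene_order, cladeA, cladeB, postwgd, out_dir) {
  t <- if (is.character(gene_order)) read_gene_order(gene_order) else gene_order
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  breaks <- detect_clade_breaks(cladeA, cladeB, t)
  if (length(postwgd) > 0L && nrow(breaks) > 0L) {
    breaks <- classify_break_inheritance(breaks, postwgd, t)
  }
  stats <- purrr::map_dfr(cladeA, function(a) {
    purrr::map_dfr(cladeB, function(b) conserved_adjacent_pairs(a, b, t))
  })
  breaks_path <- file.path(out_dir, "breaks.tsv")
  stats_path <- file.path(out_dir, "adjacency_stats.tsv")
  readr::write_tsv(tibble::as_tibble(breaks), breaks_path)
  readr::write_tsv(stats, stats_path)
  write_manifest(out_dir, "synteny",
                 list(cladeA = cladeA, cladeB = cladeB, postwgd = postwgd,
                      n_breaks = nrow(breaks)),
                 c(breaks_path, stats_path))
  message("synteny: ", sum(breaks$type == "break"), " breaks, ",
          sum(breaks$type == "single_gene_translocation"),
          " single-gene translocations")
  invisible(breaks)
}

#' Run the gene-conversion sweep stage
#'
#' @param out_dir Output directory.
#' @param ... Passed to [conversion_sweep()].
#' @return The sweep tibble, invisibly. Writes `conversion_sweep.tsv` and a
#'   manifest recording the threshold fraction.
#' @export
run_conversion_sweep <- function(out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sweep <- conversion_sweep(...)
  path <- file.path(out_dir, "conversion_sweep.tsv")
  readr::write_tsv(tibble::as_tibble(sweep), path)
  write_manifest(out_dir, "conversion_sweep",
                 list(threshold_f = attr(sweep, "threshold_f"),
                      true_branch = attr(sweep, "true_branch"),
                      n_families = attr(sweep, "n_families")),
                 path)
  message("conversion sweep: majority-younger threshold f = ",
          attr(sweep, "threshold_f"))
  invisible(sweep)
}
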