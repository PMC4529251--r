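#' Plot a duplication-density profile
#'
#' Dots per seed-lineage branch, ancestral to recent, in the style of
#' per-branch duplication-density figures.
#'
#' @param object A [density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$branch_id <- factor(df$branch_id, levels = df$branch_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch_id, y = .data$density)) +
    ggplot2::geom_point(size = 3, colour = "#2c7fb8", na.rm = TRUE) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$branch_id, yend = 0),
      colour = "#2c7fb8", linewidth = 0.3, na.rm = TRUE
    ) +
    ggplot2::labs(x = "species-tree branch (ancestral → recent)",
                  y = "duplications per gene") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.density_profile
#' @param x A [density_profile()].
#' @export
plot.density_profile <- function(x, ...) print(autoplot.density_profile(x, ...))

#' Plot a topology-call distribution
#'
#' @param object A [topology_distribution()].
#' @param ... Unused.
#' @return A ggplot bar chart of call percentages.
#' @export
autoplot.topology_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call, y = .data$pct)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "topology", y = "% of trees passing filters",
                  caption = paste0("n passing = ", attr(object, "n_passing"),
                                   " / ", attr(object, "n_total"))) +
    ggplot2::theme_minimal()
}

#' Plot a gene-conversion sweep
#'
#' @param object A [conversion_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of P(younger mapping) against the conversion fraction.
#' @export
autoplot.conversion_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$p_younger)) +
    ggplot2::geom_line(colour = "#d95f0e") +
    ggplot2::geom_point(colour = "#d95f0e") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "conversion fraction f",
                  y = "P(mapped younger than truth)") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a density profile
#'
#' @param x A [density_profile()].
#' @param ... Unused.
#' @return A plain tibble of per-branch rows.
#' @export
tidy.density_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a density profile
#'
#' @param x A [density_profile()].
#' @param ... Unused.
#' @return Tibble: `peak_branch`, `peak_density`, `total_duplications`,
#'   `n_trees`, `min_support`, `method`.
#' @export
glance.density_profile <- function(x, ...) {
  i <- which.max(x$density)
  tibble::tibble(
    peak_branch = if (length(i)) x$branch_id[i] else NA_character_,
    peak_density = if (length(i)) x$density[i] else NA_real_,
    total_duplications = sum(x$dup_count),
    n_trees = attr(x, "n_trees"),
    min_support = attr(x, "min_support"),
    method = attr(x, "method")
  )
}

#' One-row summary of a conversion sweep
#'
#' @param x A [conversion_sweep()] result.
#' @param ... Unused.
#' @return Tibble: `threshold_f` (smallest conversion fraction with a
#'   majority of younger-than-truth mappings), `true_branch`, `n_families`.
#' @export
glance.conversion_sweep <- function(x, ...) {
  tibble::tibble(
    threshold_f = attr(x, "threshold_f"),
    true_branch = attr(x, "true_branch"),
    n_families = attr(x, "n_families")
  )
}

#' One-row summary of a topology distribution
#'
#' @param x A [topology_distribution()].
#' @param ... Unused.
#' @return Tibble with the top call and filter pass-through.
#' @export
glance.topology_distribution <- function(x, ...) {
  tibble::tibble(
    top_call = if (nrow(x)) x$call[1L] else NA_character_,
    top_pct = if (nrow(x)) x$pct[1L] else NA_real_,
    n_passing = attr(x, "n_passing"),
    n_total = attr(x, "n_total")
  )
}
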