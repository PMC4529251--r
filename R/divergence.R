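#' Kimura protein distance between two aligned sequences
#'
#' The fraction of differing sites `D` is computed over gap-free columns
#' (columns with a gap in either sequence are excluded), then corrected for
#' multiple hits with the protdist formula `d = -ln(1 - D - D^2/5)`.
#' The correction saturates when `1 - D - D^2/5 <= 0` (around D = 0.85),
#' which raises an error.
#'
#' @param a,b Aligned sequences of equal length: single strings or
#'   character vectors of residues, `-` for gaps.
#' @return Non-negative distance in substitutions/site.
#' @examples
#' kimura_distance("ACDEFGHIKL", "ACDEFGHIKV")
#' @export
kimura_distance <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no gap-free columns in the alignment", call. = FALSE)
  D <- mean(a[keep] != b[keep])
  arg <- 1 - D - D^2 / 5
  if (arg <= 0) {
    stop("distance saturated (D = ", signif(D, 3),
         "); Kimura correction undefined", call. = FALSE)
  }
  -log(arg)
}

as_residues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  toupper(as.character(x))
}

#' Alignment score of a pair normalized by the seed's self-score
#'
#' Global protein alignment score (BLOSUM62, affine gaps, open 11 extend 1
#' by default) of `seed` vs `other`, divided by the score of `seed` aligned
#' to itself. Identical sequences score 1; the ratio, not the raw score, is
#' the quantity of interest.
#'
#' @param seed,other Amino-acid sequences (plain strings, gaps removed
#'   internally).
#' @param matrix Substitution matrix name understood by
#'   [Biostrings::pairwiseAlignment()].
#' @param gap_opening,gap_extension Affine gap penalties (matrix units).
#' @return The score ratio (1 for identical sequences).
#' @examples
#' normalized_score("MKTLLVAAGL", "MKTLLVAAGL")
#' @export
normalized_score <- function(seed, other, matrix = "BLOSUM62",
                             gap_opening = 11, gap_extension = 1) {
  seed <- gsub("-", "", paste(as_residues(seed), collapse = ""))
  other <- gsub("-", "", paste(as_residues(other), collapse = ""))
  if (nchar(seed) == 0L || nchar(other) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  score <- function(x, y) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y),
      substitutionMatrix = matrix, gapOpening = gap_opening,
      gapExtension = gap_extension, type = "global", scoreOnly = TRUE
    )
  }
  self <- score(seed, seed)
  if (self <= 0) {
    stop("non-positive self-alignment score; check the substitution matrix",
         call. = FALSE)
  }
  score(seed, other) / self
}

#' Compare two populations of divergence values
#'
#' Two-sample Kolmogorov-Smirnov test, e.g. to compare the divergences of
#' ohnolog pairs mapped to an ancestral branch against pairs mapped to the
#' WGD branch.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return One-row tibble: `statistic`, `p_value`, `n_x`, `n_y`.
#' @export
compare_populations <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both populations need at least 2 values", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(x, y))
  tibble::tibble(statistic = unname(ks$statistic),
                 p_value = ks$p.value,
                 n_x = length(x), n_y = length(y))
}

#' Divergence measures for a table of sequence pairs
#'
#' Convenience wrapper computing, per pair, the raw difference fraction
#' `D`, the Kimura distance, and the normalized alignment score. Input
#' pairs must be pre-aligned (equal length, gaps as `-`); saturated pairs
#' get `d_kimura = NA` with a warning rather than an error so a whole
#' table survives a few saturated pairs.
#'
#' @param pairs Tibble with columns `pair_id`, `seq1`, `seq2` (aligned
#'   strings).
#' @return Tibble: `pair_id`, `D`, `d_kimura`, `norm_score`.
#' @export
pair_divergence <- function(pairs) {
  stopifnot(all(c("pair_id", "seq1", "seq2") %in% names(pairs)))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- as_residues(pairs$seq1[[i]]); b <- as_residues(pairs$seq2[[i]])
    keep <- a != "-" & b != "-"
    D <- if (any(keep)) mean(a[keep] != b[keep]) else NA_real_
    dk <- tryCatch(kimura_distance(a, b), error = function(e) {
      warning("pair ", pairs$pair_id[[i]], ": ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    tibble::tibble(
      pair_id = pairs$pair_id[[i]], D = D, d_kimura = dk,
      norm_score = normalized_score(pairs$seq1[[i]], pairs$seq2[[i]])
    )
  })
}
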