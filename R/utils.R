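#' Leaf-name species extraction rule
#'
#' Gene-tree leaves carry a species code inside the leaf label. The default
#' convention is `<SPECIES>_<geneid>` (species code first), but phylome
#' databases differ, so the delimiter and which field holds the code are
#' configurable.
#'
#' @param delimiter Single character separating fields in a leaf label.
#' @param field `"first"` or `"last"`: which delimited field is the species
#'   code.
#' @return An object of class `species_rule`.
#' @examples
#' rule <- species_rule()
#' extract_species("Scer_f1_c2", rule)
#' @export
species_rule <- function(delimiter = "_", field = c("first", "last")) {
  field <- match.arg(field)
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  structure(list(delimiter = delimiter, field = field), class = "species_rule")
}

#' Extract species codes from leaf labels
#'
#' @param labels Character vector of leaf labels.
#' @param rule A [species_rule()].
#' @return Character vector of species codes.
#' @export
extract_species <- function(labels, rule = species_rule()) {
  stopifnot(inherits(rule, "species_rule"))
  parts <- strsplit(labels, rule$delimiter, fixed = TRUE)
  bad <- lengths(parts) == 0L | labels == ""
  if (any(bad)) {
    stop("leaf label(s) do not match the species rule: ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  vapply(parts, function(p) if (rule$field == "first") p[[1L]] else p[[length(p)]], "")
}

# normalize support labels to [0, 1]; percentages (values > 1) divided by 100
normalize_support <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & v > 1] <- v[!is.na(v) & v > 1] / 100
  v
}

# derive a child RNG seed (< 2^31) from the current RNG stream
derive_seed <- function() sample.int(.Machine$integer.max, 1L)
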