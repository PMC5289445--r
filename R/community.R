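#' Per-colony clade proportions
#'
#' Converts each colony's detected-clade S/H ratios into relative
#' proportions (percent of the colony's total symbiont density). Colonies
#' with no detected clade yield no rows and are reported in the
#' `undetected` attribute.
#'
#' @param quant Quantification table from [quantify_samples()] (or any
#'   tibble with `sample_id`, `clade`, and an abundance column).
#' @param abundance Column used as the abundance measure (default
#'   `sh_ratio`; proportions are invariant to the per-sample scale, so
#'   `copies` gives identical results when host units are shared).
#' @return One row per (sample, detected clade): `sample_id`, `clade`,
#'   `proportion` (percent; sums to 100 within a sample).
#' @examples
#' q <- tibble::tibble(sample_id = "s1", clade = c("C", "D"),
#'                     sh_ratio = c(3, 1))
#' clade_proportions(q)
#' @export
clade_proportions <- function(quant, abundance = "sh_ratio") {
  stopifnot(abundance %in% names(quant))
  detected <- quant |>
    dplyr::filter(is.finite(.data[[abundance]]), .data[[abundance]] > 0)
  undetected <- setdiff(unique(quant$sample_id), unique(detected$sample_id))
  if (length(undetected) > 0) {
    warn(paste0(length(undetected),
                " sample(s) with no detected clade were dropped."))
  }
  out <- detected |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = 100 * .data[[abundance]] /
                    sum(.data[[abundance]])) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("sample_id", "species", "site")),
                  "clade", "proportion")
  attr(out, "undetected") <- undetected
  out
}

#' Dominant versus background classification
#'
#' A clade is *dominant* in a colony when it exceeds the threshold share of
#' the community (default 5%), and *background* when present at or below
#' it (the boundary is inclusive: exactly 5% is background). Calls within
#' `near` percentage points of the threshold are flagged, since sharp
#' thresholds on continuous proportions are sensitive to rounding.
#'
#' @param proportions Tibble from [clade_proportions()].
#' @param threshold_pct Dominance threshold in percent (default 5).
#' @param near Half-width of the near-boundary flag band (default 0.1).
#' @return The input with `class` (`"dominant"` / `"background"`) and
#'   `near_boundary` columns.
#' @export
classify_dominant_background <- function(proportions, threshold_pct = 5,
                                         near = 0.1) {
  stopifnot(threshold_pct > 0)
  proportions |>
    dplyr::mutate(
      class = ifelse(.data$proportion > threshold_pct,
                     "dominant", "background"),
      near_boundary = abs(.data$proportion - threshold_pct) <= near
    )
}

#' Canonical clade-pattern label
#'
#' The community pattern of a colony is the alphabetically sorted
#' concatenation of its detected clade labels ("ACD", "BCD", ...).
#'
#' @param clades Character vector of clade labels (non-empty).
#' @return A single canonical pattern string.
#' @examples
#' pattern_label(c("D", "C", "A"))  # "ACD"
#' @export
pattern_label <- function(clades) {
  clades <- unique(as.character(clades))
  if (length(clades) == 0 || any(is.na(clades) | clades == "")) {
    abort("`clades` must be a non-empty set of clade labels.")
  }
  paste(sort(clades), collapse = "")
}

#' All theoretical clade patterns
#'
#' Every non-empty subset of a clade set, as canonical pattern strings,
#' ordered by pattern size then alphabetically. Four clades yield
#' 2^4 - 1 = 15 theoretical patterns.
#'
#' @param clades Character vector of clade labels.
#' @return Character vector of 2^k - 1 pattern strings.
#' @examples
#' enumerate_patterns(c("A", "B", "C", "D"))
#' @export
enumerate_patterns <- function(clades) {
  clades <- sort(unique(as.character(clades)))
  if (length(clades) == 0) abort("`clades` must be non-empty.")
  k <- length(clades)
  subsets <- purrr::map(seq_len(k), function(size) {
    combos <- utils::combn(clades, size, simplify = FALSE)
    sort(purrr::map_chr(combos, paste, collapse = ""))
  })
  unlist(subsets)
}

#' Per-colony community profiles
#'
#' Chains [clade_proportions()], [classify_dominant_background()] and
#' [pattern_label()] into the per-colony community description used for
#' all downstream summaries.
#'
#' @inheritParams clade_proportions
#' @inheritParams classify_dominant_background
#' @param metadata Optional tibble mapping `sample_id` to `species` (and
#'   `site`), joined in when `quant` lacks those columns.
#' @return One row per (colony, detected clade): proportions, class,
#'   near-boundary flag, and the colony's canonical `pattern`.
#' @export
community_profiles <- function(quant, metadata = NULL,
                               abundance = "sh_ratio", threshold_pct = 5,
                               near = 0.1) {
  props <- clade_proportions(quant, abundance = abundance)
  if (!is.null(metadata)) {
    keep <- intersect(c("sample_id", "species", "site"), names(metadata))
    props <- dplyr::left_join(
      props[, setdiff(names(props), c("species", "site"))],
      dplyr::distinct(metadata[, keep]), by = "sample_id"
    )
  }
  props |>
    classify_dominant_background(threshold_pct = threshold_pct,
                                 near = near) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(pattern = pattern_label(.data$clade)) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::any_of(c("sample_id", "species", "site")),
                    "clade", "proportion", "class", "near_boundary",
                    "pattern")
}

#' Species-level pattern summary
#'
#' Tallies community patterns within each species and the share of
#' mono-clade versus multi-clade colonies. Percentages are returned
#' unrounded; whole-sample shares are conventionally printed as integers
#' and pattern-group shares to one decimal (see [round_percent()]).
#'
#' @param profiles Community profiles from [community_profiles()].
#' @return A tibble, one row per (species, pattern): `n` colonies, species
#'   sample size `n_species`, `pattern_pct`, and the species-level
#'   `mono_clade_pct` / `multi_clade_pct`.
#' @export
species_summary <- function(profiles) {
  if (!"species" %in% names(profiles)) {
    abort("`profiles` must carry a `species` column (pass metadata).")
  }
  per_colony <- profiles |>
    dplyr::distinct(.data$species, .data$sample_id, .data$pattern) |>
    dplyr::mutate(mono = nchar(.data$pattern) == 1)
  per_colony |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(n_species = dplyr::n(),
                  mono_clade_pct = 100 * mean(.data$mono),
                  multi_clade_pct = 100 * mean(!.data$mono)) |>
    dplyr::group_by(.data$species, .data$pattern, .data$n_species,
                    .data$mono_clade_pct, .data$multi_clade_pct) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pattern_pct = 100 * .data$n / .data$n_species) |>
    dplyr::relocate("species", "pattern", "n", "n_species", "pattern_pct")
}

#' Share of a species' colonies in a set of patterns
#'
#' Arbitrary pattern-group queries against the profiles, e.g. the share of
#' colonies exhibiting either an "AD" or an "ACD" community.
#'
#' @param profiles Community profiles from [community_profiles()].
#' @param species Species to query.
#' @param patterns Character vector of canonical patterns forming the
#'   group.
#' @param digits Decimals for the rounded value (default 1, the
#'   pattern-group printing convention).
#' @return A one-row tibble: `species`, `n_match`, `n_species`, `pct`
#'   (unrounded) and `pct_rounded`.
#' @export
pattern_group_pct <- function(profiles, species, patterns, digits = 1) {
  if (!species %in% profiles$species) {
    abort(paste0("Unknown species: ", species))
  }
  per_colony <- profiles |>
    dplyr::filter(.data$species == !!species) |>
    dplyr::distinct(.data$sample_id, .data$pattern)
  n <- nrow(per_colony)
  n_match <- sum(per_colony$pattern %in% patterns)
  pct <- 100 * n_match / n
  tibble::tibble(species = species, n_match = n_match, n_species = n,
                 pct = pct, pct_rounded = round(pct, digits))
}
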