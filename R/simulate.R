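#' Draw synthetic colony-level symbiont communities
#'
#' Generates the ground truth for a simulated survey: for each colony of
#' each species, which Symbiodinium clades it hosts and how many 28S copies
#' of each, plus its host 18S units. Dominant clades are always (or with a
#' per-profile probability) present and share the community remaining after
#' backgrounds; each background clade occurs independently with its
#' occurrence probability, at a relative abundance drawn log-uniformly
#' within its range.
#'
#' @param profiles Species profile table, see [species_profiles()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param sites Site labels assigned uniformly at random to colonies.
#' @param total_log10_range Range of log10 total symbiont 28S copies per
#'   colony (uniform draw; default \[5, 6.5\]).
#' @param host_log10_range Range of log10 host 18S units per colony
#'   (default \[3.5, 4.5\]).
#' @return A tidy truth table: one row per (colony, clade) with columns
#'   `sample_id`, `species`, `site`, `clade`, `true_copies`. Host 18S units
#'   appear as rows with `clade == "host"`. Per-clade copies of a colony
#'   sum to its total symbiont copies.
#' @examples
#' truth <- design_communities(species_profiles(), seed = 1)
#' dplyr::count(truth, species)
#' @export
design_communities <- function(profiles = species_profiles(), seed = NULL,
                               sites = c("Va", "Te", "Ma", "Ti", "Li"),
                               total_log10_range = c(5, 6.5),
                               host_log10_range = c(3.5, 4.5)) {
  validate_profiles(profiles)
  if (!is.null(seed)) set.seed(seed)

  species_tbl <- dplyr::distinct(profiles, .data$species, .data$n_colonies)
  rows <- purrr::pmap(species_tbl, function(species, n_colonies) {
    prof <- dplyr::filter(profiles, .data$species == !!species)
    purrr::map(seq_len(n_colonies), function(i) {
      draw_colony(prof, species, i, sites,
                  total_log10_range, host_log10_range)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  tibble::as_tibble(out)
}

draw_colony <- function(prof, species, idx, sites,
                        total_log10_range, host_log10_range) {
  site <- sample(sites, 1)
  sample_id <- sprintf("%s_%02d", gsub("[. ]+", "", species), idx)

  present <- runif(nrow(prof)) < prof$prob
  dom <- prof$role == "dominant"
  # every colony needs at least one dominant clade
  if (!any(present & dom)) present[which(dom)[1]] <- TRUE

  bg_idx <- which(present & !dom)
  bg_frac <- 10^runif(length(bg_idx),
                      log10(prof$w_min[bg_idx]), log10(prof$w_max[bg_idx]))
  dom_idx <- which(present & dom)
  dom_w <- runif(length(dom_idx), prof$w_min[dom_idx], prof$w_max[dom_idx])
  dom_frac <- (1 - sum(bg_frac)) * dom_w / sum(dom_w)

  frac <- c(setNames(bg_frac, prof$clade[bg_idx]),
            setNames(dom_frac, prof$clade[dom_idx]))
  # a clade can appear in both roles; collapse to one fraction per clade
  frac <- tapply(frac, names(frac), sum)

  total <- 10^runif(1, total_log10_range[1], total_log10_range[2])
  host <- 10^runif(1, host_log10_range[1], host_log10_range[2])

  tibble::tibble(
    sample_id = sample_id,
    species = species,
    site = site,
    clade = c(names(frac), HOST_ASSAY),
    true_copies = c(unname(frac) * total, host)
  )
}

#' Simulate qPCR plates from a community truth table
#'
#' Forward model of the qPCR assay panel: every colony is assayed with all
#' primer sets on one plate, in duplicate wells. Each replicate Ct is
#' `intercept + slope * log10(copies) + plate offset + Gaussian noise`;
#' wells whose expected (noise-free) Ct exceeds the run length, or whose
#' template is absent, are censored ("no amplification"). Melting
#' temperatures are drawn per assay. Every plate additionally carries an
#' interplate calibrator — a fixed reference template amplified in
#' triplicate with every assay — from which plate-to-plate Ct offsets can
#' later be removed.
#'
#' @param truth Truth table from [design_communities()].
#' @param assays Per-assay parameter table, see [default_assay_params()].
#'   Every clade present in `truth` (and the host) must have a row.
#' @param samples_per_plate Colonies per plate (default 12).
#' @param plate_offset_sd Sd of the additive per-plate Ct shift
#'   (default 0.3; set 0 for offset-free plates).
#' @param calibrator_copies Template copies per assay in the calibrator mix
#'   (default 1e5).
#' @param seed Integer seed for reproducibility.
#' @return A tibble of wells: `plate_id`, `well_id`, `sample_id`, `role`
#'   (`"sample"` or `"calibrator"`), `assay`, `ct_rep1`, `ct_rep2`
#'   (calibrator wells are single-replicate, `ct_rep2` is `NA`), `tm`,
#'   `censored`. Attributes `plate_offsets` (tibble) and
#'   `calibrator_reference` (offset-free expected calibrator Ct per assay)
#'   carry the simulation truth for calibration tests.
#' @export
simulate_plates <- function(truth, assays = default_assay_params(),
                            samples_per_plate = 12, plate_offset_sd = 0.3,
                            calibrator_copies = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  req <- c("sample_id", "species", "site", "clade", "true_copies")
  if (!all(req %in% names(truth))) {
    abort("`truth` must come from design_communities().")
  }
  missing_assay <- setdiff(unique(truth$clade), assays$assay)
  if (length(missing_assay) > 0) {
    abort(paste0("No assay parameters for clade(s): ",
                 paste(missing_assay, collapse = ", ")))
  }
  if (!HOST_ASSAY %in% assays$assay) {
    abort("The assay table must include the host 18S assay.")
  }

  samples <- dplyr::distinct(truth, .data$sample_id, .data$species, .data$site)
  n <- nrow(samples)
  n_plates <- ceiling(n / samples_per_plate)
  samples$plate_id <- sprintf("P%02d", rep(seq_len(n_plates),
                                           each = samples_per_plate)[seq_len(n)])
  offsets <- tibble::tibble(
    plate_id = sprintf("P%02d", seq_len(n_plates)),
    offset = rnorm(n_plates, 0, plate_offset_sd)
  )

  grid <- tidyr::crossing(samples, assays["assay"]) |>
    dplyr::left_join(truth[, c("sample_id", "clade", "true_copies")],
                     by = c(sample_id = "sample_id", assay = "clade")) |>
    dplyr::mutate(copies = tidyr::replace_na(.data$true_copies, 0),
                  role = "sample") |>
    dplyr::select(-"true_copies")

  cal <- tidyr::crossing(
    offsets["plate_id"], assays["assay"],
    tibble::tibble(cal_rep = 1:3)
  ) |>
    dplyr::mutate(sample_id = "calibrator", role = "calibrator",
                  copies = calibrator_copies,
                  species = NA_character_, site = NA_character_)

  wells <- dplyr::bind_rows(grid, cal) |>
    dplyr::left_join(assays, by = "assay") |>
    dplyr::left_join(offsets, by = "plate_id") |>
    dplyr::mutate(
      expected_ct = ifelse(
        .data$copies > 0,
        .data$true_intercept + .data$true_slope * log10(.data$copies) +
          .data$offset,
        Inf
      )
    )

  # optional cross-amplification: off-target template amplifies delta Ct late
  has_cross <- is.finite(wells$cross_amp_delta) & wells$role == "sample"
  if (any(has_cross)) {
    off <- truth |>
      dplyr::filter(.data$clade != HOST_ASSAY) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(total_sym = sum(.data$true_copies), .groups = "drop")
    wells <- dplyr::left_join(wells, off, by = "sample_id")
    off_copies <- pmax(wells$total_sym - wells$copies, 0)
    cross_ct <- ifelse(
      has_cross & off_copies > 0 & wells$assay != HOST_ASSAY,
      wells$true_intercept + wells$true_slope * log10(pmax(off_copies, 1e-12)) +
        wells$cross_amp_delta + wells$offset,
      Inf
    )
    wells$expected_ct <- pmin(wells$expected_ct, cross_ct)
    wells$total_sym <- NULL
  }

  m <- nrow(wells)
  wells <- wells |>
    dplyr::mutate(
      censored = !is.finite(.data$expected_ct) |
        .data$expected_ct > .data$max_cycles,
      ct_rep1 = ifelse(.data$censored, NA_real_,
                       .data$expected_ct + rnorm(m, 0, .data$ct_noise_sd)),
      ct_rep2 = ifelse(.data$censored | .data$role == "calibrator", NA_real_,
                       .data$expected_ct + rnorm(m, 0, .data$ct_noise_sd)),
      tm = ifelse(.data$censored, NA_real_,
                  rnorm(m, .data$tm_mean, .data$tm_sd))
    ) |>
    dplyr::arrange(.data$plate_id, .data$role, .data$sample_id, .data$assay) |>
    dplyr::mutate(well_id = sprintf("%s_W%03d", .data$plate_id,
                                    stats::ave(seq_len(m), .data$plate_id,
                                               FUN = seq_along))) |>
    dplyr::select("plate_id", "well_id", "sample_id", "role", "assay",
                  "ct_rep1", "ct_rep2", "tm", "censored")

  reference <- assays |>
    dplyr::mutate(reference_ct = .data$true_intercept +
                    .data$true_slope * log10(calibrator_copies)) |>
    dplyr::select("assay", "reference_ct")

  attr(wells, "plate_offsets") <- offsets
  attr(wells, "calibrator_reference") <- reference
  attr(wells, "seed") <- seed
  wells
}
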