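#' Default per-assay simulation parameters
#'
#' One row per assay (clade-specific 28S sets A–F plus the coral-host 18S
#' set). Slopes and intercepts for the clade assays derive from the
#' published exponential standard-curve fits `q = A * exp(-k * Ct)` on
#' purified 28S products (converted with [decay_to_slope()] /
#' [decay_to_intercept()]); the host assay uses the multi-species coral
#' curve shape. Melting temperatures for most assays are not published;
#' the defaults are synthetic values spaced >= 0.5 degC apart so that
#' amplicon identity checks are exercised (clade C uses the C1-type Tm
#' ~82.95 degC).
#'
#' @param ct_noise_sd Replicate-level Gaussian Ct noise sd (default 0.15).
#' @param max_cycles Run length; wells whose expected Ct exceeds it are
#'   censored (default 40).
#' @return A tibble with columns `assay`, `true_slope`, `true_intercept`,
#'   `tm_mean`, `tm_sd`, `ct_noise_sd`, `max_cycles`, `cross_amp_delta`.
#' @export
default_assay_params <- function(ct_noise_sd = 0.15, max_cycles = 40) {
  decay <- c(A = 0.681, B = 0.676, C = 0.687, D = 0.694, E = 0.663, F = 0.694)
  amp <- c(A = 1e11, B = 1e11, C = 1e12, D = 1e12, E = 6e10, F = 8e10)
  tm <- c(A = 80.5, B = 81.6, C = 82.95, D = 84.1, E = 85.0, F = 85.8)
  clades <- tibble::tibble(
    assay = names(decay),
    true_slope = decay_to_slope(unname(decay)),
    true_intercept = decay_to_intercept(unname(decay), unname(amp)),
    tm_mean = unname(tm)
  )
  host <- tibble::tibble(
    assay = HOST_ASSAY,
    true_slope = decay_to_slope(0.694),
    # Ct ~ 20 at 1e4 18S units: keeps host wells comfortably quantifiable.
    true_intercept = 20 + -decay_to_slope(0.694) * 4,
    tm_mean = 87.0
  )
  dplyr::bind_rows(clades, host) |>
    dplyr::mutate(
      tm_sd = 0.05,
      ct_noise_sd = ct_noise_sd,
      max_cycles = max_cycles,
      cross_amp_delta = NA_real_
    )
}

#' Default coral species community profiles
#'
#' The simulated study design: five coral species sampled across five
#' fringing-reef sites, 6–27 colonies each, every colony hosting one or two
#' dominant Symbiodinium clades (>5% of the community) plus occasional
#' background clades (<=5%, spanning relative abundances down to 1e-6).
#' One row per (species, clade, role). For dominant rows the weight range
#' is on the share of the community left after backgrounds; for background
#' rows it is the log-uniform range of the relative abundance itself.
#'
#' @return A tibble with columns `species`, `n_colonies`, `clade`, `role`
#'   (`"dominant"` or `"background"`), `prob` (per-colony occurrence
#'   probability), `w_min`, `w_max`.
#' @export
species_profiles <- function() {
  tibble::tribble(
    ~species,         ~n_colonies, ~clade, ~role,        ~prob,   ~w_min, ~w_max,
    "P. damicornis",  27L,         "D",    "dominant",   1,       1,      1,
    "P. damicornis",  27L,         "C",    "dominant",   1 / 27,  0.4,    0.6,
    "P. damicornis",  27L,         "B",    "background", 2 / 27,  2e-6,   1e-5,
    "P. damicornis",  27L,         "C",    "background", 1 / 27,  2e-4,   8e-4,
    "P. damicornis",  27L,         "A",    "background", 1 / 27,  1e-6,   5e-6,
    "P. rus",         21L,         "C",    "dominant",   1,       1,      1,
    "P. rus",         21L,         "A",    "background", 2 / 21,  1e-6,   5e-5,
    "P. rus",         21L,         "D",    "background", 1 / 21,  1e-4,   5e-4,
    "A. cytherea",    16L,         "A",    "dominant",   1,       1,      1,
    "A. cytherea",    16L,         "D",    "dominant",   11 / 16, 0.3,    0.6,
    "A. cytherea",    16L,         "C",    "background", 2 / 16,  1e-2,   3.1e-2,
    "A. cytherea",    16L,         "A",    "background", 0,       1e-5,   1.6e-2,
    "A. pulchra",     6L,          "A",    "dominant",   1,       1,      1,
    "A. pulchra",     6L,          "C",    "dominant",   4 / 6,   0.2,    0.5,
    "A. pulchra",     6L,          "D",    "background", 1 / 6,   5e-3,   8e-3,
    "P. cactus",      7L,          "C",    "dominant",   1,       1,      1,
    "P. cactus",      7L,          "D",    "background", 2 / 7,   1e-5,   1e-2
  )
}

validate_profiles <- function(profiles) {
  req <- c("species", "n_colonies", "clade", "role", "prob", "w_min", "w_max")
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("`profiles` must be a non-empty data frame of species profiles.")
  }
  if (!all(req %in% names(profiles))) {
    abort(paste0("`profiles` must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(profiles$w_min > profiles$w_max)) {
    abort("Inverted abundance range: `w_min` must not exceed `w_max`.")
  }
  if (any(profiles$prob < 0 | profiles$prob > 1)) {
    abort("Occurrence probabilities must lie in [0, 1].")
  }
  bg <- profiles$role == "background"
  if (any(profiles$w_max[bg] > 0.05)) {
    abort("Background relative abundances must not exceed 0.05 (5%).")
  }
  if (!all(profiles$role %in% c("dominant", "background"))) {
    abort("`role` must be \"dominant\" or \"background\".")
  }
  invisible(profiles)
}
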