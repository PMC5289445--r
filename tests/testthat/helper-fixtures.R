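# Shared fixtures, built in code at test time.

# A perfect decade dilution series on the curve Ct = intercept + slope*log10(q)
perfect_series <- function(slope = -3.322, intercept = 40, decades = 1:7,
                           reps = 2, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rep(10^decades, each = reps)
  tibble::tibble(
    quantity = q,
    ct = intercept + slope * log10(q) + rnorm(length(q), 0, noise_sd)
  )
}

# Standard curves matching the simulator's true assay parameters exactly
# (host LOQ of 1 unit: the 200-copy limit applies to the 28S clade assays).
true_curves <- function(assays = default_assay_params(), clade_loq = 200) {
  curves <- purrr::pmap(assays, function(assay, true_slope, true_intercept,
                                         ...) {
    standard_curve(true_slope, true_intercept, assay = assay,
                   loq = if (assay == "host") 1 else clade_loq)
  })
  setNames(curves, assays$assay)
}

# Expected-Tm table matching the simulator's assay parameters.
true_tm <- function(assays = default_assay_params()) {
  tibble::tibble(assay = assays$assay, expected_tm = assays$tm_mean)
}

# Small single-species truth table with fully controlled copy numbers.
manual_truth <- function(copies_by_clade, host_units = 1e4, n = 1,
                         species = "Sp1", site = "Va") {
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      sample_id = sprintf("%s_%02d", species, i),
      species = species, site = site,
      clade = c(names(copies_by_clade), "host"),
      true_copies = c(unname(copies_by_clade), host_units)
    )
  })
}

# Closed-form ordinary-least-squares oracle via the normal equations,
# independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
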