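#' Default replicate noise for the simulated uptake study
#'
#' The source study reports no residual variance, so the generator's default
#' per-metal replicate standard deviation is set to 10% of the magnitude of
#' that metal's model intercept — a coefficient-of-variation scale typical
#' of replicated pot experiments — which also typically reproduces the
#' reference significance pattern when the simulated study is refitted.
#'
#' @return Named numeric vector, mg/kg: Cd 0.31, Cr 0.014, Pb 0.59,
#'   Cu 0.32, Zn 3.3.
#' @export
default_noise_sd <- function() {
  c(Cd = 0.31, Cr = 0.014, Pb = 0.59, Cu = 0.32, Zn = 3.3)
}

#' Construct a calibration line directly from known parameters
#'
#' Builds an `aas_calibration` without fitting, for use as the instrument
#' ground truth in forward simulations and tests.
#'
#' @param metal Metal label.
#' @param slope,intercept Line parameters (signal per concentration unit;
#'   signal).
#' @param standard_range Two-element concentration range of the standards.
#' @param blank_mean Mean blank peak area.
#' @param lod Limit of detection on the standard scale.
#' @param unit_scale Factor converting the standard scale to mg/L.
#' @param residual_sd Residual sd of the line (signal units).
#' @return An `aas_calibration` object.
#' @export
make_calibration <- function(metal, slope, intercept = 0,
                             standard_range = c(2, 25), blank_mean = 0,
                             lod = 0, unit_scale = 1e-3, residual_sd = 0) {
  if (slope <= 0) stop("slope must be positive")
  structure(list(metal = metal, slope = slope, intercept = intercept,
                 residual_sd = residual_sd, lod = lod,
                 lod_ok = lod <= min(standard_range),
                 standard_range = range(standard_range),
                 blank_mean = blank_mean, unit_scale = unit_scale,
                 n_standards = NA_integer_),
            class = "aas_calibration")
}

# deterministic per-response substream seed from one master seed
substream_seed <- function(seed, index) {
  (as.integer(seed) %% 1000000L) * 1009L + 97L * as.integer(index)
}

#' Simulate shoot metal concentrations over a design
#'
#' Generates replicate shoot concentrations from the quadratic surface
#' evaluated at each run's true coded levels plus independent Gaussian
#' replicate noise: `y = x0' b_true + e`, `e ~ N(0, sd^2)`. The mean is
#' computed through the same model-matrix construction used by the fitting
#' code, so generator and fitted model share one definition of the surface.
#' Noise draws use one deterministic substream per response, so adding a
#' response never perturbs the draws of another.
#'
#' @param design A (replicated) `doe_design` table.
#' @param coefficients Named list of named 10-term coefficient vectors, one
#'   per response (default [aviculare_coefficients()]). Names must match the
#'   model-matrix columns for the design's factors.
#' @param noise_sd Named numeric vector of replicate standard deviations
#'   (mg/kg), one per response; default [default_noise_sd()].
#' @param seed Master seed for reproducibility, or `NULL` to use the current
#'   RNG state.
#' @param truncate_at_zero Clamp negative draws to 0. Keep `FALSE` (default)
#'   for inference studies — truncation biases OLS — and use `TRUE` only for
#'   realistic-looking demonstration data.
#' @return An uptake tibble: `run_id`, `replicate`, the design's `coded_*`
#'   columns, and one mg/kg column per response.
#' @export
#' @examples
#' d <- replicate_design(full_factorial(aviculare_factors()), 3)
#' u <- simulate_uptake(d, seed = 1)
simulate_uptake <- function(design, coefficients = aviculare_coefficients(),
                            noise_sd = default_noise_sd(), seed = NULL,
                            truncate_at_zero = FALSE) {
  X <- build_model_matrix(design)
  responses <- names(coefficients)
  if (is.null(responses)) stop("coefficients must be a named list")
  if (is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep_len(noise_sd, length(responses)), responses)
  }
  missing_sd <- setdiff(responses, names(noise_sd))
  if (length(missing_sd)) stop("no noise_sd for: ",
                               paste(missing_sd, collapse = ", "))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")

  fnames <- design_factor_names(design)
  out <- tibble::as_tibble(design[c("run_id", "replicate",
                                    paste0("coded_", fnames))])
  n <- nrow(X)
  for (i in seq_along(responses)) {
    r <- responses[i]
    b <- coefficients[[r]]
    if (length(b) != ncol(X)) {
      stop("coefficient vector for ", r, " has length ", length(b),
           ", model matrix has ", ncol(X), " columns")
    }
    if (!is.null(names(b))) {
      if (!setequal(names(b), colnames(X))) {
        stop("coefficient names for ", r, " do not match model terms")
      }
      b <- b[colnames(X)]
    }
    mu <- unname(drop(X %*% b))
    if (!is.null(seed)) set.seed(substream_seed(seed, i))
    y <- mu + stats::rnorm(n, mean = 0, sd = noise_sd[[r]])
    if (truncate_at_zero) y <- pmax(y, 0)
    out[[r]] <- y
  }
  out
}

#' Simulate the full hydroponic bioindication study
#'
#' One call reproducing the study conditions the package emulates: the
#' 3-factor, 3-level full factorial over the Cd/Pb/Cr nutrient-solution
#' levels (27 runs), three pot replicates (81 samples), and all five shoot
#' responses drawn from the reference coefficient surfaces.
#'
#' @param seed Master seed.
#' @param replicates Pot replicates per run; default 3.
#' @param noise_sd Per-response replicate sd; default [default_noise_sd()].
#' @param truncate_at_zero See [simulate_uptake()].
#' @return List with elements `design` (81-row `doe_design`) and `uptake`.
#' @export
#' @examples
#' study <- simulate_study(seed = 42)
#' nrow(study$uptake) # 81
simulate_study <- function(seed = 1, replicates = 3,
                           noise_sd = default_noise_sd(),
                           truncate_at_zero = FALSE) {
  design <- replicate_design(full_factorial(aviculare_factors()), replicates)
  uptake <- simulate_uptake(design, aviculare_coefficients(),
                            noise_sd = noise_sd, seed = seed,
                            truncate_at_zero = truncate_at_zero)
  list(design = design, uptake = uptake)
}

#' Forward-simulate AAS records from a tissue uptake table
#'
#' The instrumental forward model for testing the quantification chain:
#' each tissue concentration is converted to its digest-solution
#' concentration under the 100 mg / 4 mL protocol, expressed on the metal's
#' calibration scale, diluted (when needed) to sit inside the standard
#' range, and turned into a peak area through the calibration line plus the
#' blank level and optional Gaussian signal noise.
#'
#' @param uptake Uptake table from [simulate_uptake()] (metal columns in
#'   mg/kg).
#' @param calibrations Named list of `aas_calibration` objects (the "true"
#'   instrument lines), one per metal column to simulate.
#' @param seed Master seed, or `NULL`.
#' @param signal_sd Sd of additive peak-area noise (default 0: noise-free
#'   identity with [quantify_aas()]).
#' @param mass_g,volume_ml Digest protocol; defaults 0.1 g and 4 mL.
#' @param fill_fraction Target fraction of the top standard used when
#'   choosing dilution factors; default 0.8.
#' @return A records tibble in the [quantify_aas()] input schema.
#' @export
simulate_aas_records <- function(uptake, calibrations, seed = NULL,
                                 signal_sd = 0, mass_g = 0.1, volume_ml = 4,
                                 fill_fraction = 0.8) {
  metals <- intersect(names(calibrations), names(uptake))
  if (!length(metals)) stop("no uptake column matches a calibration")
  if (!is.null(seed)) set.seed(substream_seed(seed, 1L))
  rows <- lapply(metals, function(m) {
    cal <- calibrations[[m]]
    if (cal$slope <= 0) stop("calibration slope must be positive for ", m)
    tissue <- uptake[[m]]
    c_mg_l <- tissue * (mass_g / 1000) / (volume_ml / 1000)
    c_units <- c_mg_l / cal$unit_scale
    top <- max(cal$standard_range) * fill_fraction
    dilution <- pmax(1, ceiling(c_units / top))
    measured <- c_units / dilution
    signal <- cal$blank_mean + cal$intercept + cal$slope * measured +
      stats::rnorm(length(measured), 0, signal_sd)
    tibble::tibble(
      sample_id = sprintf("run%02d_rep%d", uptake$run_id, uptake$replicate),
      metal = m,
      peak_area = signal,
      peak_height_au = pmin(0.55, 0.5 * measured / max(cal$standard_range)),
      blank_area = cal$blank_mean,
      dilution = dilution,
      mass_g = mass_g,
      volume_ml = volume_ml,
      is_control = FALSE,
      is_spiked = FALSE,
      spike_added = 0
    )
  })
  do.call(rbind, rows)
}
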