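#' Calibration standard sets for the five analysed metals
#'
#' Three-point standard series used for the AAS calibration lines, with the
#' instrument's linear range per metal: Cd 2-4-6 ug/L, Cr 2-10-25 ug/L,
#' Cu 2.5-10-25 ug/L, Pb 5-20-40 ug/L, Zn 0.1-0.5-0.8 mg/L. `unit_scale` is
#' the factor converting one unit of the standard scale to mg/L.
#'
#' @return A tibble with columns `metal`, `c1`, `c2`, `c3`, `units`,
#'   `unit_scale`.
#' @export
aviculare_standards <- function() {
  tibble::tibble(
    metal = c("Cd", "Cr", "Cu", "Pb", "Zn"),
    c1 = c(2, 2, 2.5, 5, 0.1),
    c2 = c(4, 10, 10, 20, 0.5),
    c3 = c(6, 25, 25, 40, 0.8),
    units = c("ug/L", "ug/L", "ug/L", "ug/L", "mg/L"),
    unit_scale = c(1e-3, 1e-3, 1e-3, 1e-3, 1)
  )
}

#' Fit an AAS calibration line
#'
#' Ordinary least squares of blank-corrected peak area on standard
#' concentration. The mean blank area is subtracted from every standard
#' signal before fitting, so the intercept captures only residual curvature
#' near zero. The limit of detection is `3 * sd(blanks) / slope` when three
#' or more blank readings are available, falling back to
#' `3.3 * residual_sd / slope` otherwise. A LoD above the lowest standard
#' concentration invalidates the line (`lod_ok = FALSE`, with a warning):
#' the instrument cannot then distinguish its own lowest standard from
#' blank noise.
#'
#' @param standards Data frame with columns `concentration` (standard scale
#'   units) and `signal` (mean peak area), one row per standard.
#' @param blanks Numeric vector of blank peak areas (>= 1 reading).
#' @param metal Metal label.
#' @param unit_scale Factor converting the standard scale to mg/L (1e-3 for
#'   ug/L standards); carried for downstream tissue conversion.
#' @return An object of class `aas_calibration`: list with `metal`, `slope`,
#'   `intercept`, `residual_sd`, `lod`, `lod_ok`, `standard_range`,
#'   `blank_mean`, `unit_scale`, `n_standards`.
#' @export
#' @examples
#' std <- data.frame(concentration = c(2, 4, 6), signal = c(4.1, 8.0, 12.1))
#' fit_calibration(std, blanks = c(0.02, 0.01, 0.03), metal = "Cd")
fit_calibration <- function(standards, blanks, metal = "metal",
                            unit_scale = 1e-3) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "signal") %in% names(standards))) {
    stop("standards needs columns concentration and signal")
  }
  if (length(unique(standards$concentration)) < 2L) {
    stop("need at least two distinct standard concentrations")
  }
  if (!length(blanks)) stop("need at least one blank reading")

  blank_mean <- mean(blanks)
  y <- standards$signal - blank_mean
  x <- standards$concentration
  line <- stats::lm(y ~ x)
  slope <- unname(stats::coef(line)[2])
  intercept <- unname(stats::coef(line)[1])
  if (slope <= 0) stop("non-positive calibration slope for ", metal)
  residual_sd <- if (stats::df.residual(line) > 0) {
    sqrt(sum(stats::residuals(line)^2) / stats::df.residual(line))
  } else 0

  lod <- if (length(blanks) >= 3L) {
    3 * stats::sd(blanks) / slope
  } else {
    3.3 * residual_sd / slope
  }
  lod_ok <- lod <= min(x)
  if (!lod_ok) {
    warning(sprintf("%s: LoD (%.3g) exceeds the lowest standard (%.3g)",
                    metal, lod, min(x)))
  }
  structure(list(metal = metal, slope = slope, intercept = intercept,
                 residual_sd = residual_sd, lod = lod, lod_ok = lod_ok,
                 standard_range = range(x), blank_mean = blank_mean,
                 unit_scale = unit_scale, n_standards = nrow(standards)),
            class = "aas_calibration")
}

#' @export
print.aas_calibration <- function(x, ...) {
  cat(sprintf(
    "AAS calibration [%s]: signal = %.4g * c %+.4g; LoD = %.3g (%s), standards %.3g-%.3g\n",
    x$metal, x$slope, x$intercept, x$lod,
    if (x$lod_ok) "ok" else "ABOVE lowest standard",
    x$standard_range[1], x$standard_range[2]))
  invisible(x)
}

#' Convert a peak area to a solution concentration
#'
#' Applies blank subtraction, the calibration line, and the dilution factor:
#' `((peak_area - blank_area) - intercept) / slope * dilution`. Readings
#' whose undiluted equivalent falls below the LoD — including negative
#' blank-corrected signals — are flagged `below_lod`, not rejected.
#'
#' @param peak_area,blank_area Numeric vectors of peak areas (recycled).
#' @param cal An `aas_calibration`.
#' @param dilution Dilution factor(s) >= 1 applied before measurement.
#' @return A tibble with `concentration` (standard scale units) and
#'   `below_lod`.
#' @export
signal_to_solution <- function(peak_area, blank_area, cal, dilution = 1) {
  stopifnot(inherits(cal, "aas_calibration"))
  if (any(dilution < 1)) stop("dilution factors must be >= 1")
  net <- (peak_area - blank_area) - cal$intercept
  measured <- net / cal$slope          # concentration as analysed
  concentration <- measured * dilution # back to the undiluted solution
  tibble::tibble(concentration = concentration,
                 below_lod = measured < cal$lod)
}

#' Convert a digest solution concentration to a tissue concentration
#'
#' The dried, ground shoot sample (`sample_mass`, kg) is ashed and the ash
#' dissolved in `digest_volume` (L) of dilute nitric acid; the metal mass in
#' that volume divided by the sample mass gives the tissue concentration:
#' `c_solution * digest_volume / sample_mass`. With the standard protocol of
#' 100 mg of powder in 4 mL of digest, 1 mg/L in solution is 40 mg/kg in
#' tissue.
#'
#' @param c_solution Solution concentration, mg/L.
#' @param digest_volume Digest volume, L (default 0.004).
#' @param sample_mass Sample dry mass, kg (default 1e-4).
#' @return Tissue concentration, mg/kg.
#' @export
solution_to_tissue <- function(c_solution, digest_volume = 0.004,
                               sample_mass = 1e-4) {
  if (any(digest_volume <= 0) || any(sample_mass <= 0)) {
    stop("digest_volume and sample_mass must be positive")
  }
  c_solution * digest_volume / sample_mass
}

qc_result <- function(kind, percent, limits) {
  # closed interval; absorb floating-point dust at the boundaries
  tol <- 1e-9 * max(1, abs(limits))
  structure(list(kind = kind, percent = percent, limits = limits,
                 pass = percent >= limits[1] - tol & percent <= limits[2] + tol),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("%s: %.1f%% [%g-%g%%] -> %s\n", x$kind, x$percent,
              x$limits[1], x$limits[2], if (all(x$pass)) "pass" else "FAIL"))
  invisible(x)
}

#' Spike-recovery accuracy check
#'
#' Recovery of a known analyte addition through the whole preparation chain
#' (incineration included): `(measured_spiked - measured_base) / spike_added
#' * 100`, accepted in the closed interval 90-110%.
#'
#' @param measured_spiked,measured_base Measured concentrations with and
#'   without the spike (same units as `spike_added`).
#' @param spike_added Known added concentration (> 0).
#' @param limits Acceptance window in percent; default `c(90, 110)`.
#' @return A `qc_result` with `kind = "spike_recovery"`.
#' @export
#' @examples
#' spike_recovery(1100, 100, 1000)
spike_recovery <- function(measured_spiked, measured_base, spike_added,
                           limits = c(90, 110)) {
  if (any(spike_added <= 0)) stop("spike_added must be positive")
  qc_result("spike_recovery",
            (measured_spiked - measured_base) / spike_added * 100, limits)
}

#' Control-solution stability check
#'
#' A control solution at a known standard concentration is re-measured every
#' few samples; `measured / nominal * 100` must stay inside the closed
#' 95-105% window, otherwise the calibration line must be recomputed.
#'
#' @param measured Measured control concentration.
#' @param nominal Nominal control concentration (> 0).
#' @param limits Acceptance window in percent; default `c(95, 105)`.
#' @return A `qc_result` with `kind = "control"`.
#' @export
#' @examples
#' control_check(9.5, 10)
control_check <- function(measured, nominal, limits = c(95, 105)) {
  if (any(nominal <= 0)) stop("nominal must be positive")
  qc_result("control", measured / nominal * 100, limits)
}

#' Quantify a table of AAS records into tissue concentrations
#'
#' Applies [signal_to_solution()] and [solution_to_tissue()] to every
#' record, converting the calibration-scale solution concentration to mg/L
#' via the calibration's `unit_scale`. Records flagged `is_control` or
#' `is_spiked` are passed through with their solution concentration for QC
#' evaluation, and the peak-height linearity guard (height above `max_au`)
#' is reported as a QC flag.
#'
#' @param records Data frame with columns `sample_id`, `metal`, `peak_area`,
#'   `blank_area`, `dilution`, `mass_g`, `volume_ml`; optionally
#'   `peak_height_au`, `is_control`, `is_spiked`.
#' @param calibrations Named list of `aas_calibration` objects, one per
#'   metal present.
#' @param max_au Peak-height linearity limit in absorbance units
#'   (default 0.6).
#' @return A tibble: `sample_id`, `metal`, `solution_conc` (calibration
#'   units), `tissue_mg_per_kg`, `below_lod`, `height_ok`.
#' @export
quantify_aas <- function(records, calibrations, max_au = 0.6) {
  records <- as.data.frame(records)
  need <- c("sample_id", "metal", "peak_area", "blank_area", "dilution",
            "mass_g", "volume_ml")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(records, factor(records$metal, unique(records$metal))),
                function(d) {
    cal <- calibrations[[d$metal[1]]]
    if (is.null(cal)) stop("no calibration for metal ", d$metal[1])
    sol <- signal_to_solution(d$peak_area, d$blank_area, cal, d$dilution)
    c_mg_l <- sol$concentration * cal$unit_scale
    tibble::tibble(
      sample_id = d$sample_id,
      metal = d$metal,
      solution_conc = sol$concentration,
      tissue_mg_per_kg = solution_to_tissue(c_mg_l, d$volume_ml / 1000,
                                            d$mass_g / 1000),
      below_lod = sol$below_lod,
      height_ok = if ("peak_height_au" %in% names(d)) {
        d$peak_height_au <= max_au
      } else NA
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$sample_id, records$sample_id)), , drop = FALSE]
}
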