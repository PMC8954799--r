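#' Define design factors (metals with low / central / high medium levels)
#'
#' A factor is a metal whose concentration in the nutrient solution is varied
#' across the design. Each factor carries three natural levels in micromolar
#' units: a "low" level (countryside soil), a "central" level (average urban
#' soil) and a "high" level (heavily polluted soil). The central level need
#' not be the arithmetic midpoint of low and high, so its coded value is in
#' general not 0 (see [code_level()]).
#'
#' @param name Character vector of metal identifiers (e.g. `"Cd"`).
#' @param low,central,high Numeric vectors of concentrations in uM. Must
#'   satisfy `0 < low < central < high` elementwise.
#'
#' @return A tibble of class `doe_factors` with columns `name`, `low`,
#'   `central`, `high`.
#' @seealso [aviculare_factors()] for the built-in Cd/Pb/Cr set.
#' @export
#' @examples
#' metal_factors(c("Cd", "Pb"), low = c(0.01, 1.83),
#'               central = c(0.07, 14.5), high = c(0.14, 29.0))
metal_factors <- function(name, low, central, high) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate factor names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  lengths <- c(length(name), length(low), length(central), length(high))
  if (length(unique(lengths)) != 1L) {
    stop("name, low, central and high must have equal length")
  }
  if (any(!is.finite(low) | !is.finite(central) | !is.finite(high))) {
    stop("factor levels must be finite")
  }
  if (any(low <= 0)) stop("factor levels must be strictly positive")
  if (any(low >= central | central >= high)) {
    stop("factor levels must satisfy low < central < high")
  }
  out <- tibble::tibble(name = name, low = as.numeric(low),
                        central = as.numeric(central), high = as.numeric(high))
  class(out) <- c("doe_factors", class(out))
  out
}

#' Nutrient-solution levels for the Cd/Pb/Cr hydroponic bioindication study
#'
#' The built-in factor table of the uptake experiment the package emulates:
#' Cd, Pb and Cr varied in half-strength Hoagland's solution at concentrations
#' representative of countryside (low), urban (central) and heavily polluted
#' (high) soils. Cu (0.5 uM) and Zn (2 uM) are part of the base medium, held
#' constant, and therefore appear only as responses, never as factors.
#'
#' @return A `doe_factors` tibble with rows Cd, Pb, Cr (uM).
#' @export
#' @examples
#' aviculare_factors()
aviculare_factors <- function() {
  metal_factors(
    name    = c("Cd", "Pb", "Cr"),
    low     = c(0.0100, 1.83, 6.92),
    central = c(0.0700, 14.5, 23.1),
    high    = c(0.140, 29.0, 46.2)
  )
}

as_one_factor <- function(factor) {
  # accept a one-row doe_factors tibble or a list with low/high
  if (is.data.frame(factor)) {
    if (nrow(factor) != 1L) stop("expected a single factor (one row)")
    factor <- as.list(factor)
  }
  if (is.null(factor$low) || is.null(factor$high)) {
    stop("factor must carry 'low' and 'high' levels")
  }
  if (factor$high - factor$low <= 0) {
    stop("invalid factor: zero or negative level range")
  }
  factor
}

#' Code a natural concentration onto the [-1, +1] scale
#'
#' Applies the affine map that sends a factor's low level to -1 and its high
#' level to +1, making coefficients comparable across factors whose natural
#' units differ by orders of magnitude. The central level maps to 0 only when
#' it is the arithmetic midpoint; for the built-in factors it codes to
#' -0.0769 (Cd), -0.0674 (Pb) and -0.1762 (Cr), conventionally rounded to
#' -0.08, -0.07 and -0.18 in reports.
#'
#' @param value Numeric vector of concentrations (uM).
#' @param factor A single factor: one row of a `doe_factors` table.
#' @return Coded levels (dimensionless), same length as `value`.
#' @seealso [decode_level()] for the inverse map.
#' @export
#' @examples
#' cd <- aviculare_factors()[1, ]
#' code_level(c(0.0100, 0.0700, 0.140), cd)
code_level <- function(value, factor) {
  factor <- as_one_factor(factor)
  # endpoint-exact form: low gives exactly -1, high exactly +1
  2 * (value - factor$low) / (factor$high - factor$low) - 1
}

#' Decode a coded level back to a natural concentration
#'
#' Inverse of [code_level()]: -1 recovers the factor's low level, +1 its high
#' level.
#'
#' @param coded Numeric vector of coded (dimensionless) levels.
#' @param factor A single factor: one row of a `doe_factors` table.
#' @return Concentrations in uM.
#' @export
#' @examples
#' decode_level(c(-1, 0, 1), aviculare_factors()[2, ])
decode_level <- function(coded, factor) {
  factor <- as_one_factor(factor)
  factor$low + (coded + 1) / 2 * (factor$high - factor$low)
}
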