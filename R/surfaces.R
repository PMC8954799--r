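#' Evaluate a fitted model over a two-factor coded grid
#'
#' Produces the "response plot" lattice: a regular grid over the coded square
#' [-1, +1]^2 spanned by two factors, with every remaining factor held at a
#' fixed coded value (0, the display convention for the central level, unless
#' overridden). Each node is an application of [predict.rsm_fit()].
#'
#' @param fit An `rsm_fit`.
#' @param axes Character vector of two distinct factor names: first is the
#'   abscissa, second the ordinate.
#' @param fixed Named numeric vector of coded values for the remaining
#'   factors; unnamed factors default to 0.
#' @param resolution Number of nodes per axis (>= 2); default 41.
#' @return A tibble of class `surface_grid` with columns `x`, `y`,
#'   `response`, and attributes `axes`, `fixed`, `resolution`, `response_name`.
#' @export
#' @examples
#' fits <- fit_uptake_models(simulate_study(seed = 1)$design,
#'                           simulate_study(seed = 1)$uptake)
#' g <- response_grid(fits$Cd, c("Cd", "Cr"), resolution = 11)
response_grid <- function(fit, axes, fixed = NULL, resolution = 41L) {
  pts <- surface_points(fit, axes, fixed, resolution)
  pred <- stats::predict(fit, pts$coded)
  grid_tbl(pts, response = pred$fit, fit = fit)
}

#' 95% confidence semiamplitude over a two-factor coded grid
#'
#' The semiamplitude at a node is the half-width of the (1 - alpha)
#' confidence interval for the mean response there:
#' `t(1 - alpha/2, df) * se(yhat)`. Comparing it with the response surface
#' shows where the predicted response differs significantly from zero.
#'
#' @inheritParams response_grid
#' @param alpha Significance level; default 0.05 (95% intervals).
#' @param interval `"confidence"` for the mean response (default) or
#'   `"prediction"` for a single new observation.
#' @return A `surface_grid` tibble with columns `x`, `y`, `semiamplitude`.
#' @export
semiamplitude_grid <- function(fit, axes, fixed = NULL, resolution = 41L,
                               alpha = 0.05,
                               interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  pts <- surface_points(fit, axes, fixed, resolution)
  pred <- stats::predict(fit, pts$coded, interval = interval)
  t_crit <- stats::qt(1 - alpha / 2, df = fit$df_residual)
  grid_tbl(pts, semiamplitude = t_crit * pred$se_fit, fit = fit)
}

#' Nodes where the response differs significantly from zero
#'
#' Node-wise rule: the mean response is significantly non-zero when its
#' absolute predicted value exceeds the confidence semiamplitude,
#' `|yhat| > semiamplitude`.
#'
#' @param response A `surface_grid` from [response_grid()].
#' @param semi A `surface_grid` from [semiamplitude_grid()] on the same
#'   lattice.
#' @return A `surface_grid` tibble with columns `x`, `y`, `significant`.
#' @export
significance_mask <- function(response, semi) {
  if (!isTRUE(all.equal(response[c("x", "y")], semi[c("x", "y")],
                        check.attributes = FALSE))) {
    stop("response and semiamplitude grids are on different lattices")
  }
  out <- response[c("x", "y")]
  out$significant <- abs(response$response) > semi$semiamplitude
  copy_grid_attrs(out, response)
}

#' Combined surface table for one factor pair
#'
#' One call computing the response, semiamplitude and significance columns on
#' a shared lattice; this is the long-format table the pipeline exports.
#'
#' @inheritParams semiamplitude_grid
#' @return A `surface_grid` tibble with columns `x`, `y`, `response`,
#'   `semiamplitude`, `significant`.
#' @export
surface_table <- function(fit, axes, fixed = NULL, resolution = 41L,
                          alpha = 0.05) {
  resp <- response_grid(fit, axes, fixed, resolution)
  semi <- semiamplitude_grid(fit, axes, fixed, resolution, alpha)
  out <- resp
  out$semiamplitude <- semi$semiamplitude
  out$significant <- abs(out$response) > out$semiamplitude
  out
}

surface_points <- function(fit, axes, fixed, resolution) {
  stopifnot(inherits(fit, "rsm_fit"))
  fnames <- fit$factor_names
  axes <- as.character(axes)
  if (length(axes) != 2L || axes[1] == axes[2]) {
    stop("axes must name two distinct factors")
  }
  if (!all(axes %in% fnames)) {
    stop("unknown factor(s): ", paste(setdiff(axes, fnames), collapse = ", "))
  }
  if (resolution < 2L) stop("resolution must be >= 2")
  others <- setdiff(fnames, axes)
  fixed_full <- stats::setNames(rep(0, length(others)), others)
  if (length(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% others)) {
      stop("fixed must be a named vector over the non-axis factors")
    }
    fixed_full[names(fixed)] <- fixed
  }
  s <- seq(-1, 1, length.out = resolution)
  nodes <- expand.grid(y = s, x = s, KEEP.OUT.ATTRS = FALSE)[, c("x", "y")]
  coded <- matrix(0, nrow(nodes), length(fnames),
                  dimnames = list(NULL, fnames))
  coded[, axes[1]] <- nodes$x
  coded[, axes[2]] <- nodes$y
  for (f in others) coded[, f] <- fixed_full[[f]]
  list(nodes = nodes, coded = coded, axes = axes, fixed = fixed_full,
       resolution = as.integer(resolution))
}

grid_tbl <- function(pts, ..., fit) {
  out <- tibble::tibble(x = pts$nodes$x, y = pts$nodes$y, ...)
  attr(out, "axes") <- pts$axes
  attr(out, "fixed") <- pts$fixed
  attr(out, "resolution") <- pts$resolution
  attr(out, "response_name") <- fit$response
  class(out) <- c("surface_grid", class(out))
  out
}

copy_grid_attrs <- function(out, ref) {
  for (a in c("axes", "fixed", "resolution", "response_name")) {
    attr(out, a) <- attr(ref, a)
  }
  class(out) <- unique(c("surface_grid", class(out)))
  out
}

#' Render a surface as a filled contour plot
#'
#' Draws the lattice as a raster with iso-response contour lines at
#' `n_levels` evenly spaced values across the surface range (the degenerate
#' constant surface is drawn without contour lines). Axes are in coded units,
#' abscissa = first axis factor, ordinate = second.
#'
#' @param surface A `surface_grid` tibble.
#' @param value Column to draw; default the grid's value column
#'   (`response` or `semiamplitude`).
#' @param n_levels Number of evenly spaced contour levels; default 10.
#' @param path Optional file path; if given the plot is saved there
#'   (format from the extension, e.g. `.png`, `.svg`).
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly when saved.
#' @export
render_surface <- function(surface, value = NULL, n_levels = 10,
                           path = NULL, width = 5, height = 4) {
  stopifnot(inherits(surface, "surface_grid"))
  if (is.null(value)) {
    value <- intersect(c("response", "semiamplitude", "significant"),
                       names(surface))[1]
  }
  axes <- attr(surface, "axes")
  v <- surface[[value]]
  if (is.logical(v)) v <- as.numeric(v)
  df <- data.frame(x = surface$x, y = surface$y, z = v)
  rng <- range(df$z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      x = paste0(axes[1], " (coded)"), y = paste0(axes[2], " (coded)"),
      title = paste0(attr(surface, "response_name"), ": ", value)
    ) +
    ggplot2::theme_minimal()
  if (diff(rng) > .Machine$double.eps^0.5) {
    breaks <- seq(rng[1], rng[2], length.out = n_levels + 2)[-c(1, n_levels + 2)]
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$z), breaks = breaks,
                                   colour = "white", linewidth = 0.3)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
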