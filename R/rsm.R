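#' Build the quadratic response-surface model matrix
#'
#' Expands the coded factor levels of a design into the fixed-order columns
#' of the ten-term quadratic model (for F = 3 factors):
#' intercept, linear effects, binary interactions, squared effects,
#'
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j +
#'       \sum_i b_{ii} x_i^2}
#'
#' Columns are named `(Intercept)`, then each factor name, then `A:B` for
#' every ordered pair (i < j in factor order), then `A^2` per factor. The
#' construction generalizes to any number of factors >= 1.
#'
#' @param design A `doe_design` table with `coded_*` columns, or a plain
#'   numeric matrix/data frame of coded levels (one column per factor).
#' @param factor_names Optional character vector overriding the factor names.
#' @return Numeric matrix, one row per observation.
#' @export
#' @examples
#' d <- full_factorial(aviculare_factors(), c("low", "high"))
#' head(build_model_matrix(d))
build_model_matrix <- function(design, factor_names = NULL) {
  if (is.data.frame(design) && any(grepl("^coded_", names(design)))) {
    if (is.null(factor_names)) factor_names <- design_factor_names(design)
    coded <- as.matrix(design[paste0("coded_", factor_names)])
    colnames(coded) <- factor_names
  } else {
    coded <- as.matrix(design)
    if (!is.null(factor_names)) colnames(coded) <- factor_names
    if (is.null(colnames(coded))) {
      colnames(coded) <- paste0("x", seq_len(ncol(coded)))
    }
  }
  if (!is.numeric(coded)) stop("coded levels must be numeric")
  nm <- colnames(coded)
  n_f <- ncol(coded)

  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (i in seq_len(n_f)) cols[[nm[i]]] <- coded[, i]
  if (n_f >= 2L) {
    for (i in seq_len(n_f - 1L)) {
      for (j in seq((i + 1L), n_f)) {
        cols[[paste0(nm[i], ":", nm[j])]] <- coded[, i] * coded[, j]
      }
    }
  }
  for (i in seq_len(n_f)) cols[[paste0(nm[i], "^2")]] <- coded[, i]^2

  X <- do.call(cbind, cols)
  attr(X, "factor_names") <- nm
  X
}

#' Fit the quadratic response-surface model by ordinary least squares
#'
#' Solves the least-squares problem through a QR decomposition (no normal
#' equations), then derives per-coefficient standard errors from the residual
#' variance and the inverse information matrix, two-sided Student-t p-values,
#' and the conventional significance stars. The inverse information matrix
#' is retained so that the prediction variance at any coded point can be
#' computed downstream.
#'
#' All replicate observations are fitted individually by default (the pot
#' replicates contribute pure-error information to the residual variance);
#' averaging to run means first is the caller's choice via
#' [fit_uptake_models()].
#'
#' @param X Model matrix from [build_model_matrix()].
#' @param y Numeric response vector (shoot concentration, mg/kg).
#' @param response_name Label for the response metal.
#' @return An object of class `rsm_fit`: a list with elements
#'   `coefficients`, `se`, `t_value`, `p_value`, `stars` (named vectors),
#'   `residual_sd`, `df_residual`, `xtx_inv`, `factor_names`, `n_obs`,
#'   `response`, `fitted`, `residuals`.
#' @export
fit_rsm <- function(X, y, response_name = "response") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  p <- ncol(X)
  n <- nrow(X)
  if (n - p <= 0L) stop("no residual degrees of freedom (n <= number of terms)")

  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, p)]]
    stop("singular design: aliased column(s) ", paste(bad, collapse = ", "))
  }
  b <- qr.coef(qr_x, y)
  fitted <- drop(X %*% b)
  res <- y - fitted
  dof <- n - p
  rss <- sum(res^2)
  sigma <- sqrt(rss / dof)

  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)
  piv <- qr_x$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))

  se <- sigma * sqrt(diag(xtx_inv))
  t_value <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  p_value <- 2 * stats::pt(-abs(t_value), df = dof)

  fit <- structure(list(
    response = response_name,
    coefficients = b,
    se = se,
    t_value = t_value,
    p_value = p_value,
    stars = p_stars(p_value),
    residual_sd = sigma,
    df_residual = dof,
    xtx_inv = xtx_inv,
    factor_names = attr(X, "factor_names"),
    n_obs = n,
    fitted = fitted,
    residuals = res
  ), class = "rsm_fit")
  fit
}

#' Significance stars for p-values
#'
#' Conventional labelling: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  names(out) <- names(p)
  out
}

#' Annotate a fit with significance flags at a chosen level
#'
#' Adds a per-term `significant` flag (p < alpha) alongside the fixed-star
#' convention, and records the alpha used. No multiple-testing correction is
#' applied across the ten terms.
#'
#' @param fit An `rsm_fit`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The fit with elements `significant` and `alpha` added.
#' @export
coefficient_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  fit$significant <- fit$p_value < alpha
  fit$alpha <- alpha
  fit
}

#' Coefficient table of a response-surface fit
#'
#' @param fit An `rsm_fit`.
#' @return A tibble with columns `term`, `estimate`, `se`, `t`, `p`, `stars`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    t = unname(fit$t_value),
    p = unname(fit$p_value),
    stars = unname(fit$stars)
  )
}

#' @export
print.rsm_fit <- function(x, digits = 3, ...) {
  cat("Quadratic response-surface fit:", x$response, "\n")
  cat(sprintf("n = %d observations, %d terms, residual sd = %s on %d df\n",
              x$n_obs, length(x$coefficients),
              format(x$residual_sd, digits = digits), x$df_residual))
  tab <- as.data.frame(coef_table(x))
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$t <- signif(tab$t, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict the mean response at coded factor settings
#'
#' Evaluates the fitted quadratic at coded points, with the standard error of
#' the mean response `se = residual_sd * sqrt(x0' (X'X)^-1 x0)` or, when
#' `interval = "prediction"`, the standard error of a new single observation
#' (adds the residual variance term). Points outside the coded cube
#' [-1, +1]^F are extrapolations and trigger a warning, not an error.
#'
#' @param object An `rsm_fit`.
#' @param points Matrix or data frame of coded levels, one column per factor
#'   in factor order (a single point may be a bare numeric vector).
#' @param interval `"confidence"` (default) for the mean response or
#'   `"prediction"` for a new observation.
#' @param ... Unused.
#' @return A tibble with columns `fit` and `se_fit`.
#' @export
predict.rsm_fit <- function(object, points,
                            interval = c("confidence", "prediction"), ...) {
  interval <- match.arg(interval)
  if (is.null(dim(points))) {
    points <- matrix(as.numeric(points), nrow = 1L)
  }
  points <- as.matrix(points)
  n_f <- length(object$factor_names)
  if (ncol(points) != n_f) {
    stop("expected ", n_f, " coded coordinates per point (factors: ",
         paste(object$factor_names, collapse = ", "), ")")
  }
  colnames(points) <- object$factor_names
  if (any(abs(points) > 1 + 1e-8)) {
    warning("some points lie outside the coded cube [-1, +1]^F; ",
            "predictions there are extrapolations")
  }
  X0 <- build_model_matrix(points)
  yhat <- unname(drop(X0 %*% object$coefficients))
  quad <- rowSums((X0 %*% object$xtx_inv) * X0) # x0' (X'X)^-1 x0
  quad <- pmax(quad, 0)
  if (interval == "prediction") quad <- quad + 1
  se <- object$residual_sd * sqrt(quad)
  tibble::tibble(fit = yhat, se_fit = unname(se))
}

#' Fit one quadratic model per response metal
#'
#' Convenience wrapper joining a design with an uptake table and fitting
#' [fit_rsm()] for each response column, optionally on run means instead of
#' individual replicates.
#'
#' @param design A `doe_design` table (replicated).
#' @param uptake A table with `run_id`, `replicate` and one numeric column
#'   per response metal (mg/kg), as produced by [simulate_uptake()].
#' @param responses Character vector of response columns; default: all
#'   non-key, non-design columns of `uptake`.
#' @param use_run_means If `TRUE`, average replicates within run before
#'   fitting (27 observations instead of 81 for the default study).
#' @param alpha Significance level passed to [coefficient_tests()].
#' @return Named list of `rsm_fit` objects.
#' @export
fit_uptake_models <- function(design, uptake, responses = NULL,
                              use_run_means = FALSE, alpha = 0.05) {
  keys <- c("run_id", "replicate")
  if (!all(keys %in% names(uptake))) stop("uptake needs run_id and replicate")
  if (is.null(responses)) {
    responses <- setdiff(names(uptake),
                         c(keys, grep("^(coded|conc|level)_", names(uptake),
                                      value = TRUE)))
  }
  dat <- merge(as.data.frame(design)[c(keys, grep("^coded_", names(design), value = TRUE))],
               as.data.frame(uptake)[c(keys, responses)],
               by = keys, sort = FALSE)
  dat <- dat[order(dat$replicate, dat$run_id), , drop = FALSE]
  fnames <- design_factor_names(design)
  if (use_run_means) {
    coded_cols <- paste0("coded_", fnames)
    dat <- stats::aggregate(dat[c(coded_cols, responses)],
                            by = list(run_id = dat$run_id), FUN = mean)
  }
  coded <- as.matrix(dat[paste0("coded_", fnames)])
  colnames(coded) <- fnames
  X <- build_model_matrix(coded)
  fits <- lapply(responses, function(r) {
    coefficient_tests(fit_rsm(X, dat[[r]], response_name = r), alpha = alpha)
  })
  names(fits) <- responses
  fits
}
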