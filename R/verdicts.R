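#' Reference quadratic-model coefficients for the P. aviculare uptake study
#'
#' The fitted coefficient tables (coded units) of the five shoot-metal
#' responses — Cd, Cr, Pb, Cu, Zn — from the hydroponic full-factorial study
#' the package emulates, with factor order Cd, Pb, Cr. These serve two roles:
#' default ground truth for the synthetic-data generator, and worked input
#' for the verdict rules.
#'
#' Exact p-values are carried where they were reported; for the remaining
#' terms the p-value is a synthetic representative of the reported
#' significance band (0.0005 for `***`, 0.005 for `**`, 0.03 for `*`, 0.5
#' for non-significant terms), sufficient for any rule that only thresholds
#' p at conventional levels.
#'
#' @return A tibble with columns `response`, `term`, `estimate` (coded
#'   units, mg/kg), `p`, `stars`.
#' @seealso [aviculare_coefficients()] for the estimates reshaped into named
#'   vectors; [classify()] for the verdict rules.
#' @export
#' @examples
#' subset(aviculare_models(), response == "Cd")
aviculare_models <- function() {
  terms10 <- c("(Intercept)", "Cd", "Pb", "Cr",
               "Cd:Pb", "Cd:Cr", "Pb:Cr", "Cd^2", "Pb^2", "Cr^2")
  band <- function(stars) {
    c("***" = 0.0005, "**" = 0.005, "*" = 0.03)[stars]
  }
  col <- function(response, estimate, stars, p_exact = NULL) {
    p <- ifelse(stars == "", 0.5, band(stars))
    if (!is.null(p_exact)) p[match(names(p_exact), terms10)] <- p_exact
    tibble::tibble(response = response, term = terms10,
                   estimate = estimate, p = unname(p), stars = stars)
  }
  rbind(
    col("Cd",
        c(3.1, 0.87, 0.12, -0.0073, -0.050, -0.58, -0.30, -0.32, -0.043, -0.55),
        c("", "***", "", "", "", "*", "", "", "", ""),
        p_exact = c("Cd:Cr" = 0.0118)),
    col("Cr",
        c(0.14, -0.081, 0.12, 0.53, -0.12, -0.046, 0.12, 0.23, 0.32, 0.23),
        c("", "", "", "***", "", "", "", "", "*", ""),
        p_exact = c("Pb^2" = 0.0354)),
    col("Pb",
        c(5.9, 0.22, 1.6, -1.7, -3.6, 8.9, 0.20, 4.6, -0.65, 5.8),
        c("", "", "", "", "", "***", "", "", "", "*")),
    col("Cu",
        c(3.2, 0.49, 0.65, 0.82, 0.49, 2.9, -0.80, 3.6, 3.1, 3.0),
        c("", "", "", "", "", "***", "", "**", "**", "**"),
        p_exact = c("Cd^2" = 0.001, "Pb^2" = 0.0044, "Cr^2" = 0.0077)),
    col("Zn",
        c(33, -1.4, 3.4, 1.9, 0.64, -2.0, -3.4, 9.5, 9.7, 9.3),
        c("", "", "**", "", "", "", "*", "***", "***", "***"),
        p_exact = c("Pb" = 0.0089, "Pb:Cr" = 0.0306))
  )
}

#' Reference coefficients as named vectors
#'
#' @return Named list (one element per response metal) of 10-term named
#'   coefficient vectors in model-matrix column order.
#' @export
aviculare_coefficients <- function() {
  m <- aviculare_models()
  out <- lapply(split(m, factor(m$response, unique(m$response))), function(d) {
    stats::setNames(d$estimate, d$term)
  })
  out
}

#' Which metals does a model term involve?
#'
#' Parses term labels of the quadratic model: `"Cd"` involves Cd, `"Cd:Cr"`
#' involves Cd and Cr, `"Pb^2"` involves Pb, and the intercept involves none.
#'
#' @param term Character vector of term labels.
#' @return List of character vectors.
#' @keywords internal
term_metals <- function(term) {
  lapply(term, function(t) {
    if (t == "(Intercept)") return(character(0))
    unique(sub("\\^2$", "", strsplit(t, ":", fixed = TRUE)[[1]]))
  })
}

#' Classify a metal's bioindication potential from its fitted model
#'
#' A bioindicator accumulates an element in proportion to its level in the
#' growing medium, without interference from the other metals present. The
#' rules formalize that reading of a fitted coefficient table, applied in
#' order:
#'
#' 1. If the metal was a varied factor (`own_factor` given), it is a
#'    candidate only when its own linear term is significant with a positive
#'    estimate (more metal in the medium, more in the shoot); otherwise
#'    `not_bioindicator`.
#' 2. Among candidates, look at significant terms involving any *other*
#'    metal (their linear, interaction and squared terms — interactions with
#'    the own factor count too). None significant: `bioindicator`. All of
#'    them smaller in magnitude than `interference_ratio` times the own
#'    linear estimate: `bioindicator_minor_interference` (still a positive
#'    verdict). Any larger: `not_bioindicator`.
#' 3. A metal that was held constant in the medium (`own_factor = NULL`,
#'    e.g. Cu and Zn here) can only "bioindicate" if its uptake ignores the
#'    varied metals entirely: it is `bioindicator` when no non-intercept
#'    term is significant, `not_bioindicator` otherwise.
#'
#' @param fit An `rsm_fit`, or a data frame with columns `term`, `estimate`,
#'   `p` (e.g. one response of [aviculare_models()]).
#' @param own_factor Name of the design factor for this metal, or `NULL` if
#'   the metal was not varied.
#' @param alpha Significance level for "significant"; default 0.05.
#' @param interference_ratio Maximum tolerated ratio of an interfering
#'   term's |estimate| to the own linear |estimate|; default 1.
#' @param metal Label for the verdict; defaults to the fit's response name.
#' @return An object of class `bioverdict`: list with `metal`, `status`
#'   (one of `"bioindicator"`, `"bioindicator_minor_interference"`,
#'   `"not_bioindicator"`), `positive`, and `evidence` (tibble of the
#'   triggering terms with their role).
#' @export
#' @examples
#' cd <- subset(aviculare_models(), response == "Cd")
#' classify(cd, own_factor = "Cd")
classify <- function(fit, own_factor = NULL, alpha = 0.05,
                     interference_ratio = 1, metal = NULL) {
  if (inherits(fit, "rsm_fit")) {
    if (is.null(metal)) metal <- fit$response
    tab <- coef_table(fit)[c("term", "estimate", "p")]
  } else {
    tab <- as.data.frame(fit)
    if (!all(c("term", "estimate", "p") %in% names(tab))) {
      stop("fit must be an rsm_fit or have columns term, estimate, p")
    }
    if (is.null(metal)) {
      metal <- if ("response" %in% names(tab)) tab$response[1] else "response"
    }
  }
  if (!is.null(own_factor) && !own_factor %in% tab$term) {
    stop("own_factor '", own_factor, "' is not a term of the fit")
  }

  metals_per_term <- term_metals(tab$term)
  sig <- tab$p < alpha & tab$term != "(Intercept)"

  evidence <- function(rows, role) {
    ev <- tibble::tibble(term = tab$term[rows], estimate = tab$estimate[rows],
                         p = tab$p[rows], role = role)
    ev
  }

  if (is.null(own_factor)) {
    # rule 3: constant-medium metal
    if (any(sig)) {
      status <- "not_bioindicator"
      ev <- evidence(which(sig), "external_influence")
    } else {
      status <- "bioindicator"
      ev <- evidence(integer(0), character(0))
    }
  } else {
    own_row <- match(own_factor, tab$term)
    own_est <- tab$estimate[own_row]
    if (!sig[own_row] || own_est <= 0) {
      status <- "not_bioindicator"
      ev <- evidence(own_row, "own_linear_not_positive_significant")
    } else {
      interfering <- which(sig & vapply(metals_per_term, function(m) {
        length(setdiff(m, own_factor)) > 0
      }, logical(1)))
      if (!length(interfering)) {
        status <- "bioindicator"
        ev <- evidence(own_row, "own_linear")
      } else if (all(abs(tab$estimate[interfering]) <
                     interference_ratio * abs(own_est))) {
        status <- "bioindicator_minor_interference"
        ev <- rbind(evidence(own_row, "own_linear"),
                    evidence(interfering, "minor_interference"))
      } else {
        status <- "not_bioindicator"
        ev <- rbind(evidence(own_row, "own_linear"),
                    evidence(interfering, "dominant_interference"))
      }
    }
  }
  structure(list(metal = metal, status = status,
                 positive = status != "not_bioindicator",
                 own_factor = own_factor, alpha = alpha,
                 interference_ratio = interference_ratio,
                 evidence = ev),
            class = "bioverdict")
}

#' @export
print.bioverdict <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$metal, x$status,
              if (x$positive) " (positive verdict)" else ""))
  if (nrow(x$evidence)) {
    ev <- as.data.frame(x$evidence)
    ev$estimate <- signif(ev$estimate, 3)
    ev$p <- signif(ev$p, 3)
    print(ev, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a set of verdicts
#'
#' @param verdicts List of `bioverdict` objects.
#' @return A tibble with one row per metal: `metal`, `status`, `positive`,
#'   and a compact `evidence` string.
#' @export
summarize_verdicts <- function(verdicts) {
  if (inherits(verdicts, "bioverdict")) verdicts <- list(verdicts)
  if (!length(verdicts)) stop("need at least one verdict")
  rows <- lapply(verdicts, function(v) {
    ev <- if (nrow(v$evidence)) {
      paste(sprintf("%s=%.3g (p=%.3g, %s)", v$evidence$term,
                    v$evidence$estimate, v$evidence$p, v$evidence$role),
            collapse = "; ")
    } else ""
    tibble::tibble(metal = v$metal, status = v$status,
                   positive = v$positive, evidence = ev)
  })
  do.call(rbind, rows)
}
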