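#' Run the full bioindication analysis pipeline
#'
#' Chains every stage of the study: factorial design generation, shoot
#' responses (simulated from the reference surfaces, or supplied), one
#' quadratic fit per response metal, response/semiamplitude surfaces for the
#' requested factor pairs, and a bioindication verdict per metal. The
#' returned bundle embeds the configuration and seed needed to regenerate it
#' exactly.
#'
#' @param factors A `doe_factors` table; default [aviculare_factors()].
#' @param replicates Pot replicates per run; default 3.
#' @param seed Master seed for simulation; default 1.
#' @param responses Optional uptake table (`run_id`, `replicate`, one column
#'   per response metal). When supplied, simulation is skipped.
#' @param noise_sd Per-response replicate sd for simulation.
#' @param alpha Significance level throughout; default 0.05.
#' @param interference_ratio Verdict tolerance, see [classify()].
#' @param own_factors Named character vector mapping each response metal to
#'   its design factor (or `NA` for constant-medium metals). Defaults to
#'   matching response names against factor names.
#' @param surface_axes Named list mapping response metals to factor pairs
#'   for surface evaluation; default: Cd and Pb over (Cd, Cr), Cr over
#'   (Cr, Pb), Cu over (Cd, Cr), Zn over (Pb, Cd), mirroring the reported
#'   response plots, for whichever of these metals are present.
#' @param resolution Surface grid resolution; default 41.
#' @param out_dir Optional directory; when given, the design, uptake,
#'   coefficient tables, surface tables and verdict summary are written
#'   there as CSV (plus `verdicts.json` if jsonlite is installed).
#' @return List with `design`, `uptake`, `fits`, `coef_tables`, `surfaces`,
#'   `verdicts`, `verdict_summary`, `config`.
#' @export
#' @examples
#' report <- run_pipeline(seed = 7, resolution = 11)
#' report$verdict_summary
run_pipeline <- function(factors = aviculare_factors(), replicates = 3,
                         seed = 1, responses = NULL,
                         noise_sd = default_noise_sd(), alpha = 0.05,
                         interference_ratio = 1, own_factors = NULL,
                         surface_axes = NULL, resolution = 41L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- stage("design",
                  replicate_design(full_factorial(factors), replicates))

  uptake <- if (is.null(responses)) {
    stage("simulate", simulate_uptake(design, noise_sd = noise_sd,
                                      seed = seed))
  } else {
    stage("responses", {
      if (!all(c("run_id", "replicate") %in% names(responses))) {
        stop("responses must have run_id and replicate columns")
      }
      tibble::as_tibble(responses)
    })
  }

  fits <- stage("fit", fit_uptake_models(design, uptake, alpha = alpha))
  coef_tables <- lapply(fits, coef_table)

  if (is.null(surface_axes)) {
    defaults <- list(Cd = c("Cd", "Cr"), Cr = c("Cr", "Pb"),
                     Pb = c("Cd", "Cr"), Cu = c("Cd", "Cr"),
                     Zn = c("Pb", "Cd"))
    surface_axes <- defaults[intersect(names(defaults), names(fits))]
  }
  surfaces <- stage("surfaces", lapply(names(surface_axes), function(m) {
    surface_table(fits[[m]], surface_axes[[m]], resolution = resolution,
                  alpha = alpha)
  }))
  names(surfaces) <- names(surface_axes)

  if (is.null(own_factors)) {
    own_factors <- stats::setNames(
      ifelse(names(fits) %in% factors$name, names(fits), NA_character_),
      names(fits))
  }
  verdicts <- stage("verdict", lapply(names(fits), function(m) {
    own <- own_factors[[m]]
    classify(fits[[m]], own_factor = if (is.na(own)) NULL else own,
             alpha = alpha, interference_ratio = interference_ratio)
  }))
  names(verdicts) <- names(fits)
  verdict_summary <- summarize_verdicts(verdicts)

  config <- list(factors = factors, replicates = replicates, seed = seed,
                 simulated = is.null(responses), noise_sd = noise_sd,
                 alpha = alpha, interference_ratio = interference_ratio,
                 resolution = resolution)
  report <- list(design = design, uptake = uptake, fits = fits,
                 coef_tables = coef_tables, surfaces = surfaces,
                 verdicts = verdicts, verdict_summary = verdict_summary,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design(design, file.path(out_dir, "design.csv"))
    utils::write.csv(as.data.frame(uptake),
                     file.path(out_dir, "uptake.csv"), row.names = FALSE)
    for (m in names(coef_tables)) {
      utils::write.csv(as.data.frame(coef_tables[[m]]),
                       file.path(out_dir, paste0("fit_", m, ".csv")),
                       row.names = FALSE)
    }
    for (m in names(surfaces)) {
      utils::write.csv(as.data.frame(surfaces[[m]]),
                       file.path(out_dir, paste0("surface_", m, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(as.data.frame(verdict_summary),
                     file.path(out_dir, "verdicts.csv"), row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(seed = seed, alpha = alpha,
             verdicts = as.data.frame(verdict_summary)),
        file.path(out_dir, "verdicts.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  report
}

#' Validate pipeline input files
#'
#' Schema and invariant checks on a factor CSV and/or a responses CSV,
#' returning diagnostics instead of raising errors, so a caller can report
#' all problems at once.
#'
#' @param factors_path Path to a factor CSV (`name, low_uM, central_uM,
#'   high_uM`), or `NULL`.
#' @param responses_path Path to a responses CSV (`run_id`, `replicate`,
#'   numeric response columns), or `NULL`.
#' @return A tibble of diagnostics: `file`, `problem`. Zero rows when
#'   everything checks out.
#' @export
validate_inputs <- function(factors_path = NULL, responses_path = NULL) {
  probs <- list()
  note <- function(file, problem) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(file = file,
                                                   problem = problem)
  }

  if (!is.null(factors_path)) {
    if (!file.exists(factors_path)) {
      note(factors_path, "file does not exist")
    } else {
      d <- utils::read.csv(factors_path, stringsAsFactors = FALSE)
      need <- c("name", "low_uM", "central_uM", "high_uM")
      miss <- setdiff(need, names(d))
      if (length(miss)) {
        note(factors_path, paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
      } else {
        for (i in seq_len(nrow(d))) {
          lev <- c(d$low_uM[i], d$central_uM[i], d$high_uM[i])
          if (any(!is.finite(lev)) || any(lev <= 0)) {
            note(factors_path, sprintf(
              "row %d (%s): levels must be finite and positive", i, d$name[i]))
          } else if (!(lev[1] < lev[2] && lev[2] < lev[3])) {
            note(factors_path, sprintf(
              "row %d (%s): levels must satisfy low < central < high",
              i, d$name[i]))
          }
        }
        if (anyDuplicated(d$name)) {
          note(factors_path, "duplicate factor names")
        }
      }
    }
  }

  if (!is.null(responses_path)) {
    if (!file.exists(responses_path)) {
      note(responses_path, "file does not exist")
    } else {
      d <- utils::read.csv(responses_path, stringsAsFactors = FALSE)
      for (col in c("run_id", "replicate")) {
        if (!col %in% names(d)) {
          note(responses_path, paste("missing column:", col))
        }
      }
      value_cols <- setdiff(names(d), c("run_id", "replicate",
                                        grep("^(coded|conc|level)_", names(d),
                                             value = TRUE)))
      if (!length(value_cols)) {
        note(responses_path, "no response columns found")
      }
      for (col in value_cols) {
        if (!is.numeric(d[[col]])) {
          note(responses_path, paste("non-numeric response column:", col))
        }
      }
    }
  }

  if (!length(probs)) {
    return(tibble::tibble(file = character(0), problem = character(0)))
  }
  do.call(rbind, probs)
}
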