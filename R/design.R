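#' Generate a full-factorial design
#'
#' Enumerates every combination of the requested levels of every factor,
#' exactly once, in a deterministic order: runs are sorted lexicographically
#' by factor order (the first factor varies slowest) with levels ordered
#' low < central < high. With F factors at L levels each, the design has
#' L^F unique runs. No run-order randomization is applied: the runs are a
#' catalogue of growth conditions executed in parallel, not a measurement
#' sequence.
#'
#' The design stores, for every factor, the level label (`level_<name>`), the
#' natural concentration in uM (`conc_<name>`) and the true coded value
#' (`coded_<name>`) obtained from [code_level()]. Central levels keep their
#' true (generally non-zero) coded value; see [display_coded()] for the
#' plotting convention that shows them at 0.
#'
#' @param factors A `doe_factors` table (see [metal_factors()]).
#' @param levels Character vector naming which of `"low"`, `"central"`,
#'   `"high"` to use for every factor. Default all three.
#' @return A tibble of class `doe_design` with columns `run_id`, `replicate`
#'   (all 1), then `level_*`, `conc_*`, `coded_*` per factor. The factor
#'   names are kept in `attr(, "factors")`.
#' @export
#' @examples
#' full_factorial(aviculare_factors())                  # 27 runs
#' full_factorial(aviculare_factors(), c("low", "high")) # 2^3 = 8 runs
full_factorial <- function(factors, levels = c("low", "central", "high")) {
  if (!is.data.frame(factors) || nrow(factors) < 1L) {
    stop("need at least one factor")
  }
  if (anyDuplicated(factors$name)) stop("duplicate factor names")
  levels <- match.arg(levels, c("low", "central", "high"), several.ok = TRUE)
  levels <- levels[order(match(levels, c("low", "central", "high")))]
  if (length(levels) < 2L) stop("need at least two levels per factor")

  n_f <- nrow(factors)
  n_l <- length(levels)
  n_runs <- n_l^n_f

  # first factor varies slowest: lexicographic enumeration
  idx <- lapply(seq_len(n_f), function(i) {
    rep(rep(seq_len(n_l), each = n_l^(n_f - i)), times = n_l^(i - 1))
  })

  out <- tibble::tibble(run_id = seq_len(n_runs), replicate = 1L)
  for (i in seq_len(n_f)) {
    f <- factors[i, ]
    lab <- levels[idx[[i]]]
    conc <- vapply(lab, function(l) as.numeric(f[[l]]), numeric(1))
    out[[paste0("level_", f$name)]] <- unname(lab)
    out[[paste0("conc_", f$name)]] <- unname(conc)
    out[[paste0("coded_", f$name)]] <- unname(code_level(conc, f))
  }
  attr(out, "factors") <- factors$name
  class(out) <- c("doe_design", class(out))
  out
}

#' Replicate every run of a design
#'
#' Appends k full copies of the design, block by block: block r contains all
#' unique runs in their original order with `replicate = r`. This mirrors pot
#' replicates cultivated in parallel for every growth condition.
#'
#' @param design A `doe_design` table.
#' @param k Number of replicates (>= 1).
#' @return A `doe_design` tibble with `k * nrow(unique runs)` rows.
#' @export
#' @examples
#' nrow(replicate_design(full_factorial(aviculare_factors()), 3)) # 81
replicate_design <- function(design, k) {
  stopifnot(is.data.frame(design))
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1")
  }
  k <- as.integer(k)
  base <- design[design$replicate == design$replicate[1L], , drop = FALSE]
  if (k == 1L) return(design)
  blocks <- lapply(seq_len(k), function(r) {
    b <- base
    b$replicate <- r
    b
  })
  out <- do.call(rbind, blocks)
  attr(out, "factors") <- attr(design, "factors")
  class(out) <- unique(c("doe_design", class(out)))
  out
}

#' Map central levels to coded 0 for display
#'
#' Reporting convention for response plots: the central level is drawn at the
#' coded origin even when its true coded value is non-zero. Model fitting
#' always uses the true coded values; this helper only rewrites the
#' `coded_*` columns of a design for presentation.
#'
#' @param design A `doe_design` table.
#' @return The design with `coded_<name>` set to 0 wherever
#'   `level_<name> == "central"`.
#' @export
display_coded <- function(design) {
  for (f in design_factor_names(design)) {
    central <- design[[paste0("level_", f)]] == "central"
    design[[paste0("coded_", f)]][central] <- 0
  }
  design
}

design_factor_names <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) f <- sub("^coded_", "", grep("^coded_", names(design), value = TRUE))
  f
}

#' Read and write factor and design tables
#'
#' Factors are exchanged as a CSV with header `name, low_uM, central_uM,
#' high_uM`; designs as the CSV produced by [write_design()].
#'
#' @param path File path.
#' @return `read_factors()` returns a `doe_factors` tibble.
#' @export
read_factors <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "low_uM", "central_uM", "high_uM")
  if (!all(need %in% names(d))) {
    stop("factor file must have columns: ", paste(need, collapse = ", "))
  }
  metal_factors(d$name, d$low_uM, d$central_uM, d$high_uM)
}

#' @rdname read_factors
#' @param factors A `doe_factors` table.
#' @export
write_factors <- function(factors, path) {
  out <- data.frame(name = factors$name, low_uM = factors$low,
                    central_uM = factors$central, high_uM = factors$high)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_factors
#' @param design A `doe_design` table.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_factors
#' @export
read_design <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("run_id", "replicate") %in% names(d))) {
    stop("design file must have run_id and replicate columns")
  }
  attr(d, "factors") <- sub("^coded_", "", grep("^coded_", names(d), value = TRUE))
  class(d) <- c("doe_design", class(d))
  d
}
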