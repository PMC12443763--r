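#' Per-bin deposition selection ratios
#'
#' The deposition selection ratio of size bin *i* is
#' `DSR_i = f_i(lungs) / f_i(exposure)`: values above 1 indicate
#' preferential retention of that size class in lung tissue, values below 1
#' deselection. By default the ratio is taken on the percent columns as
#' stored (`normalize = "none"`), which reproduces the published per-bin
#' values; `normalize = "column"` first rescales each column to sum to 1,
#' which changes every ratio by the same factor (the ratio of column sums,
#' within 1% for the packaged tables). Bins with zero exposure frequency are
#' `NA`; bins with zero lung frequency but positive exposure get DSR 0.
#'
#' @param lung A [size_matrix()] for the lung-burden medium.
#' @param exposure A [size_matrix()] for the exposure medium, same mineral.
#' @param normalize `"none"` (ratio of stored percents) or `"column"`
#'   (ratio of column-sum-normalized fractions).
#' @return A list of class `dsr_table`: `mineral`, `exposure_source`, and
#'   `dsr`, a named vector of 32 ratios (with `NA`).
#' @examples
#' d <- compute_dsr(load_size_matrix("crocidolite/lung"),
#'                  load_size_matrix("crocidolite/airborne_pooley"))
#' round(d$dsr[["<1|<0.125"]], 2)  # 0.63
#' @export
compute_dsr <- function(lung, exposure, normalize = c("none", "column")) {
  stopifnot(inherits(lung, "size_matrix"), inherits(exposure, "size_matrix"))
  normalize <- match.arg(normalize)
  if (!identical(lung$mineral, exposure$mineral)) {
    stop("mineral mismatch: lung is ", lung$mineral, ", exposure is ",
         exposure$mineral)
  }
  fl <- lung$percent
  fe <- exposure$percent
  if (normalize == "column") {
    fl <- fl / sum(fl)
    fe <- fe / sum(fe)
  }
  dsr <- ifelse(fe == 0, NA_real_, fl / fe)
  structure(list(mineral = lung$mineral,
                 exposure_source = exposure$medium, dsr = dsr),
            class = "dsr_table")
}

#' @export
print.dsr_table <- function(x, ...) {
  cat("dsr_table:", x$mineral, "lung /", x$exposure_source,
      sprintf("(%d defined bins)\n", sum(!is.na(x$dsr))))
  m <- matrix(round(x$dsr, 2), nrow = 8,
              dimnames = list(length_bin_labels(), width_bin_labels()))
  print(m)
  invisible(x)
}

#' Offset log transform of DSR values
#'
#' `log10(DSR + 0.001)`; the offset keeps fully deselected bins (DSR = 0)
#' finite at -3. `NA` (undefined exposure) propagates.
#'
#' @param dsr Nonnegative DSR value(s) or `NA`.
#' @return `log10(dsr + 0.001)`.
#' @export
log_dsr <- function(dsr) {
  if (any(dsr < 0, na.rm = TRUE)) stop("DSR values must be nonnegative")
  log10(dsr + 0.001)
}

#' Project per-bin DSR values onto individual particles
#'
#' Each particle receives the DSR of the bin containing it: a non-parametric,
#' piecewise-constant estimate of its deposition propensity. Particles
#' falling in bins with undefined DSR receive `NA` (counted in the
#' `n_undefined` attribute) and should be excluded from summaries.
#'
#' @param fibers A filtered [fiber_set()].
#' @param table A [dsr_table()] (see [compute_dsr()]).
#' @return Numeric vector of per-particle DSR values with attribute
#'   `n_undefined`.
#' @export
project_dsr <- function(fibers, table) {
  stopifnot(inherits(fibers, "fiber_set"), inherits(table, "dsr_table"))
  check_nonempty(fibers, "projected DSR")
  v <- unname(table$dsr[bin_for(fibers$length_um, fibers$width_um)])
  attr(v, "n_undefined") <- sum(is.na(v))
  v
}

#' Threshold summary of projected DSR values
#'
#' For each threshold, the fractions of particles strictly below and
#' strictly above it (undefined values dropped). Used for deselection
#' claims such as "all non-criteria particles have DSR < 0.5".
#'
#' @param values Numeric DSR values (possibly with `NA`).
#' @param thresholds Numeric thresholds (default `c(0.5, 1)`).
#' @return Data frame with columns `threshold`, `frac_below`, `frac_above`,
#'   `n`.
#' @export
dsr_summary <- function(values, thresholds = c(0.5, 1)) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined DSR values to summarize")
  data.frame(threshold = thresholds,
             frac_below = vapply(thresholds, function(t) mean(v < t),
                                 numeric(1)),
             frac_above = vapply(thresholds, function(t) mean(v > t),
                                 numeric(1)),
             n = length(v))
}

#' All four packaged DSR tables
#'
#' Convenience wrapper computing the lung-to-airborne and
#' lung-to-dimensional-database DSR tables for both packaged minerals.
#'
#' @inheritParams compute_dsr
#' @return Named list of four `dsr_table` objects:
#'   `"crocidolite/airborne_pooley"`, `"crocidolite/dimensional_db"`,
#'   `"amosite/airborne_pooley"`, `"amosite/dimensional_db"`.
#' @export
packaged_dsr_tables <- function(normalize = c("none", "column")) {
  normalize <- match.arg(normalize)
  out <- list()
  for (m in c("crocidolite", "amosite")) {
    lung <- load_size_matrix(paste0(m, "/lung"))
    for (e in c("airborne_pooley", "dimensional_db")) {
      out[[paste(m, e, sep = "/")]] <-
        compute_dsr(lung, load_size_matrix(paste0(m, "/", e)),
                    normalize = normalize)
    }
  }
  out
}
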