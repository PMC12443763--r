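#' Construct a fiber-level particle set
#'
#' A `fiber_set` is a data frame of individual elongate mineral particles
#' with columns `length_um`, `width_um`, `aspect_ratio` and `mineral`, plus a
#' `provenance` attribute recording where the records came from (a fixture
#' id, a CSV path, or a simulation seed).
#'
#' @param length_um,width_um Particle dimensions, um; must be positive.
#' @param mineral Mineral label(s), recycled.
#' @param provenance Free-text provenance string.
#' @return A data frame of class `fiber_set`.
#' @export
fiber_set <- function(length_um, width_um, mineral = NA_character_,
                      provenance = "") {
  stopifnot(length(length_um) == length(width_um))
  if (any(length_um <= 0) || any(width_um <= 0)) {
    stop("particle dimensions must be positive")
  }
  d <- data.frame(length_um = as.numeric(length_um),
                  width_um = as.numeric(width_um),
                  aspect_ratio = as.numeric(length_um) / as.numeric(width_um),
                  mineral = rep_len(mineral, length(length_um)),
                  stringsAsFactors = FALSE)
  attr(d, "provenance") <- provenance
  class(d) <- c("fiber_set", "data.frame")
  d
}

#' Read a fiber list from CSV
#'
#' Expects columns `length_um,width_um` and optionally `mineral`, one
#' particle per row, header required.
#'
#' @param path CSV path.
#' @param mineral Mineral label override when the file has no such column.
#' @return A [fiber_set()].
#' @export
read_fiber_csv <- function(path, mineral = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("length_um", "width_um") %in% names(d))) {
    stop("fiber CSV must have columns length_um,width_um")
  }
  if (is.null(mineral)) {
    mineral <- if ("mineral" %in% names(d)) d$mineral else NA_character_
  }
  fiber_set(d$length_um, d$width_um, mineral, provenance = path)
}

#' Write a fiber set to CSV
#'
#' @param fibers A [fiber_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(fibers, path) {
  stopifnot(inherits(fibers, "fiber_set"))
  utils::write.csv(fibers[c("length_um", "width_um", "mineral")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the global dimensional filter to a fiber set
#'
#' Retains elongate mineral particles in the analytic domain: aspect ratio
#' >= 3, width between 0.05 and 3 um, and, when `min_length` is given,
#' length strictly greater than `min_length` (the population statistics for
#' habit classification use `min_length = 2`; some particle-level analyses
#' use 5). Record order is preserved. The result may be empty; downstream
#' statistics raise an error on empty sets.
#'
#' @param fibers A [fiber_set()].
#' @param min_length Optional strict lower length bound, um.
#' @return The filtered [fiber_set()].
#' @export
filter_fibers <- function(fibers, min_length = NULL) {
  stopifnot(inherits(fibers, "fiber_set"))
  keep <- fibers$aspect_ratio >= 3 &
    fibers$width_um >= 0.05 & fibers$width_um <= 3
  if (!is.null(min_length)) keep <- keep & fibers$length_um > min_length
  out <- fibers[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(fibers, "provenance")
  class(out) <- c("fiber_set", "data.frame")
  out
}

check_nonempty <- function(fibers, what) {
  if (nrow(fibers) == 0) {
    stop("empty fiber set: cannot compute ", what)
  }
}

#' Per-bin fractions of a fiber set
#'
#' Counts particles in each of the 32 size bins and divides by the total.
#'
#' @param fibers A nonempty, filtered [fiber_set()].
#' @return 32 nonnegative fractions summing to 1, in [emp_bins()] order.
#' @export
fractions <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  check_nonempty(fibers, "bin fractions")
  ids <- bin_for(fibers$length_um, fibers$width_um)
  tabulate(ids, nbins = 32L) / nrow(fibers)
}
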