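#' The 8 x 4 length-by-width size bin scheme
#'
#' The dimensional analysis uses 32 size categories: length categories
#' `<1`, `1-2`, `2-3`, `3-4`, `4-6`, `6-8`, `8-10`, `>10` um and width
#' categories `<0.125`, `0.125-0.250`, `0.250-0.375`, `>0.375` um. All
#' intervals are half-open and lower-inclusive, `[lo, hi)`, so a width of
#' exactly 0.125 um falls in `0.125-0.250` and a length of exactly 2 um in
#' `2-3`. Because only structures longer than 0.5 um and wider than 0.05 um
#' are measured, the `<1` length bin is `[0.5, 1)` and the `<0.125` width bin
#' is `[0.05, 0.125)`. The open-ended top bins carry finite sampling caps
#' (used when a representative dimension or a random draw is needed):
#' `length_cap` for `>10` and `width_cap` for `>0.375` (the global width
#' filter ceiling).
#'
#' Bins are ordered as in the published frequency tables: width category
#' varies slowest, length category fastest, so bin ids 1-8 are the `<0.125`
#' width column top to bottom.
#'
#' @param length_cap Finite upper sampling bound for the open `>10` um length
#'   bin, in um. Default 40, a conservative TEM-visible maximum.
#' @param width_cap Finite upper sampling bound for the open `>0.375` um width
#'   bin, in um. Default 3, the global width filter ceiling.
#' @return A data frame with 32 rows and columns `bin` (integer id 1-32),
#'   `length_bin`, `width_bin` (labels), `length_lo`, `length_hi`, `width_lo`,
#'   `width_hi` (interval bounds; `Inf` for open bins), `length_hi_cap`,
#'   `width_hi_cap` (bounds with caps substituted), `rep_length`, `rep_width`
#'   (geometric midpoints of the capped intervals).
#' @examples
#' b <- emp_bins()
#' b[b$length_bin == "2-3" & b$width_bin == "<0.125", ]
#' @export
emp_bins <- function(length_cap = 40, width_cap = 3) {
  stopifnot(length_cap > 10, width_cap > 0.375)
  llo <- c(0.5, 1, 2, 3, 4, 6, 8, 10)
  lhi <- c(1, 2, 3, 4, 6, 8, 10, Inf)
  llab <- c("<1", "1-2", "2-3", "3-4", "4-6", "6-8", "8-10", ">10")
  wlo <- c(0.05, 0.125, 0.25, 0.375)
  whi <- c(0.125, 0.25, 0.375, Inf)
  wlab <- c("<0.125", "0.125-0.250", "0.250-0.375", ">0.375")
  b <- data.frame(
    bin = seq_len(32L),
    length_bin = rep(llab, 4),
    width_bin = rep(wlab, each = 8),
    length_lo = rep(llo, 4),
    length_hi = rep(lhi, 4),
    width_lo = rep(wlo, each = 8),
    width_hi = rep(whi, each = 8),
    stringsAsFactors = FALSE
  )
  b$length_hi_cap <- ifelse(is.finite(b$length_hi), b$length_hi, length_cap)
  b$width_hi_cap <- ifelse(is.finite(b$width_hi), b$width_hi, width_cap)
  b$rep_length <- sqrt(b$length_lo * b$length_hi_cap)
  b$rep_width <- sqrt(b$width_lo * b$width_hi_cap)
  b
}

# canonical label vectors, used by loaders and validators
length_bin_labels <- function() c("<1", "1-2", "2-3", "3-4", "4-6", "6-8", "8-10", ">10")
width_bin_labels <- function() c("<0.125", "0.125-0.250", "0.250-0.375", ">0.375")

# en-dash and surrounding whitespace are accepted as aliases for the ASCII form
normalize_bin_label <- function(x) {
  x <- gsub("–|—", "-", x)
  trimws(x)
}

#' Locate the size bin containing a particle
#'
#' Maps particle dimensions to the unique half-open, lower-inclusive bin of
#' the 32-bin scheme (see [emp_bins()]). Open-ended top bins contain all
#' larger values.
#'
#' @param length Particle length(s), um. Must be >= 0.5 (the measurement
#'   floor).
#' @param width Particle width(s), um. Must be >= 0.05.
#' @return Integer vector of bin ids (1-32) into [emp_bins()].
#' @examples
#' bin_for(1.5, 0.10)   # (1-2, <0.125)
#' bin_for(2.0, 0.125)  # lower-inclusive: (2-3, 0.125-0.250)
#' @export
bin_for <- function(length, width) {
  if (length(length) != length(width)) {
    stop("'length' and 'width' must have equal length")
  }
  if (any(!is.finite(length)) || any(!is.finite(width))) {
    stop("non-finite particle dimensions")
  }
  if (any(length < 0.5)) {
    stop("length below the 0.5 um measurement floor: ",
         paste(utils::head(length[length < 0.5], 3), collapse = ", "))
  }
  if (any(width < 0.05)) {
    stop("width below the 0.05 um measurement floor: ",
         paste(utils::head(width[width < 0.05], 3), collapse = ", "))
  }
  li <- findInterval(length, c(0.5, 1, 2, 3, 4, 6, 8, 10))
  wi <- findInterval(width, c(0.05, 0.125, 0.25, 0.375))
  as.integer((wi - 1L) * 8L + li)
}
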