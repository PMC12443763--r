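#' Construct a binned size-frequency matrix
#'
#' A `size_matrix` holds the percent frequency of particles in each of the 32
#' length-by-width bins for one mineral in one medium (lung burden or an
#' exposure source). Frequencies are stored as printed (percent, typically
#' 2 d.p.); because printed columns rarely sum to exactly 100, consumers that
#' need fractions divide by the column sum.
#'
#' @param mineral Mineral label, e.g. `"crocidolite"` or `"amosite"`.
#' @param medium One of `"lung"`, `"airborne_pooley"`, `"dimensional_db"`, or
#'   another free-text source label.
#' @param percent Numeric vector of 32 percent frequencies in [emp_bins()]
#'   order (width category slowest, length fastest).
#' @return An object of class `size_matrix`: a list with elements `mineral`,
#'   `medium` and `percent` (named by `"length|width"` bin labels).
#' @seealso [load_size_matrix()], [compute_dsr()], [reconstruct_fibers()]
#' @export
size_matrix <- function(mineral, medium, percent) {
  b <- emp_bins()
  if (length(percent) != 32L) {
    stop("'percent' must have 32 entries, got ", length(percent))
  }
  if (any(!is.finite(percent))) {
    bad <- which(!is.finite(percent))[1]
    stop("non-finite frequency in bin (", b$length_bin[bad], ", ",
         b$width_bin[bad], ")")
  }
  if (any(percent < 0)) {
    bad <- which(percent < 0)[1]
    stop("negative frequency in bin (", b$length_bin[bad], ", ",
         b$width_bin[bad], ")")
  }
  s <- sum(percent)
  if (s < 99 || s > 101) {
    stop("frequencies sum to ", format(s),
         "; expected a percent column in [99, 101]")
  }
  names(percent) <- paste(b$length_bin, b$width_bin, sep = "|")
  structure(list(mineral = mineral, medium = medium, percent = percent),
            class = "size_matrix")
}

#' @export
print.size_matrix <- function(x, ...) {
  cat("size_matrix:", x$mineral, "/", x$medium,
      sprintf("(sum %.2f%%)\n", sum(x$percent)))
  m <- matrix(x$percent, nrow = 8, dimnames = list(length_bin_labels(),
                                                   width_bin_labels()))
  print(m)
  invisible(x)
}

#' Per-bin fractions of a size matrix
#'
#' @param m A [size_matrix()].
#' @return 32 fractions summing to 1 (percent divided by the column sum).
#' @export
matrix_fractions <- function(m) {
  stopifnot(inherits(m, "size_matrix"))
  m$percent / sum(m$percent)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "empdsr")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

fixture_combos <- function() {
  expand.grid(mineral = c("crocidolite", "amosite"),
              medium = c("lung", "airborne_pooley", "dimensional_db"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Load a size matrix from a packaged fixture or a CSV file
#'
#' Fixture ids have the form `"mineral/medium"`, e.g. `"crocidolite/lung"` or
#' `"amosite/dimensional_db"`; these are the six Pooley-Clark-derived
#' frequency columns shipped with the package. Any other string is treated as
#' a path to a CSV with columns `length_bin,width_bin,percent` (and optional
#' `mineral`, `medium` columns); bin labels may use en-dash or ASCII hyphen.
#'
#' @param source Fixture id or CSV path.
#' @param mineral,medium Metadata overrides when loading a bare CSV.
#' @return A validated [size_matrix()].
#' @examples
#' m <- load_size_matrix("crocidolite/lung")
#' m$percent[["<1|<0.125"]]  # 11.91
#' @export
load_size_matrix <- function(source, mineral = NULL, medium = NULL) {
  combos <- fixture_combos()
  ids <- paste(combos$mineral, combos$medium, sep = "/")
  if (source %in% ids) {
    i <- match(source, ids)
    d <- utils::read.csv(fixture_path("size_frequencies.csv"),
                         stringsAsFactors = FALSE)
    d <- d[d$mineral == combos$mineral[i] & d$medium == combos$medium[i], ]
    mineral <- combos$mineral[i]
    medium <- combos$medium[i]
  } else {
    if (!file.exists(source)) {
      stop("'", source, "' is neither a packaged fixture id (",
           paste(ids, collapse = ", "), ") nor an existing file")
    }
    d <- utils::read.csv(source, stringsAsFactors = FALSE)
    need <- c("length_bin", "width_bin", "percent")
    if (!all(need %in% names(d))) {
      stop("size-matrix CSV must have columns ",
           paste(need, collapse = ", "))
    }
    if (is.null(mineral)) mineral <- if ("mineral" %in% names(d)) d$mineral[1] else "unknown"
    if (is.null(medium)) medium <- if ("medium" %in% names(d)) d$medium[1] else "unknown"
  }
  d$length_bin <- normalize_bin_label(d$length_bin)
  d$width_bin <- normalize_bin_label(d$width_bin)
  b <- emp_bins()
  key_b <- paste(b$length_bin, b$width_bin, sep = "|")
  key_d <- paste(d$length_bin, d$width_bin, sep = "|")
  missing <- setdiff(key_b, key_d)
  if (length(missing)) {
    stop("missing bin(s) in size-matrix CSV: ",
         paste(utils::head(missing, 4), collapse = "; "))
  }
  dup <- key_d[duplicated(key_d)]
  if (length(dup)) {
    stop("duplicated bin(s) in size-matrix CSV: ",
         paste(unique(dup), collapse = "; "))
  }
  unknown <- setdiff(key_d, key_b)
  if (length(unknown)) {
    stop("unrecognized bin label(s): ", paste(unknown, collapse = "; "))
  }
  percent <- d$percent[match(key_b, key_d)]
  size_matrix(mineral, medium, percent)
}

#' Write a size matrix to CSV
#'
#' The output round-trips through [load_size_matrix()] to an identical
#' object: columns `mineral,medium,length_bin,width_bin,percent`.
#'
#' @param m A [size_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_size_matrix <- function(m, path) {
  stopifnot(inherits(m, "size_matrix"))
  b <- emp_bins()
  d <- data.frame(mineral = m$mineral, medium = m$medium,
                  length_bin = b$length_bin, width_bin = b$width_bin,
                  percent = unname(m$percent), stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged per-mineral potency, biopersistence and average DSR values
#'
#' Literature values for seven mineral fiber types: the mesothelioma potency
#' factor R_M (percent excess mesothelioma mortality per unit cumulative
#' exposure), biopersistence under acellular dissolution in Gamble's solution
#' (years), and the average deposition selection ratio with its standard
#' error.
#'
#' @return Data frame with columns `mineral`, `r_m_percent`,
#'   `biopersistence_years`, `avg_dsr`, `avg_dsr_se`.
#' @export
emp_mineral_profiles <- function() {
  utils::read.csv(fixture_path("mineral_profiles.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged MPPD pulmonary deposition rates per size bin
#'
#' Pulmonary deposition fractions from the US EPA Multiple-Path Particle
#' Dosimetry model (v3.04, Yeh/Schum symmetric lung, nasal breathing) for the
#' 32 size bins of amosite and crocidolite, together with the geometric-mean
#' width and average aspect ratio that parameterized each MPPD run. These are
#' consumed as data; the deposition physics itself is not re-implemented.
#'
#' @return Data frame with columns `mineral`, `length_bin`, `width_bin`,
#'   `bin` (id into [emp_bins()]), `gm_width_um`, `avg_aspect_ratio`,
#'   `pulmonary_deposition_rate` (fraction in 0-1, `NA` where undefined).
#' @export
emp_mppd <- function() {
  d <- utils::read.csv(fixture_path("mppd_deposition.csv"),
                       stringsAsFactors = FALSE)
  d$length_bin <- normalize_bin_label(d$length_bin)
  d$width_bin <- normalize_bin_label(d$width_bin)
  b <- emp_bins()
  d$bin <- match(paste(d$length_bin, d$width_bin),
                 paste(b$length_bin, b$width_bin))
  bad <- d$pulmonary_deposition_rate
  stopifnot(all(is.na(bad) | (bad >= 0 & bad <= 1)))
  d
}

#' Packaged published per-bin DSR columns
#'
#' The DSR values as printed in the source frequency table (2 d.p.), kept
#' alongside the frequency columns so recomputed ratios can be audited
#' against them. `NA` marks bins where the exposure frequency is zero.
#'
#' @param mineral `"crocidolite"` or `"amosite"`.
#' @param exposure_source `"airborne_pooley"` or `"dimensional_db"`.
#' @return Numeric vector of 32 DSR values (with `NA`) in [emp_bins()] order.
#' @export
emp_printed_dsr <- function(mineral = c("crocidolite", "amosite"),
                            exposure_source = c("airborne_pooley",
                                                "dimensional_db")) {
  mineral <- match.arg(mineral)
  exposure_source <- match.arg(exposure_source)
  d <- utils::read.csv(fixture_path("dsr_printed.csv"),
                       stringsAsFactors = FALSE)
  d <- d[d$mineral == mineral & d$exposure_source == exposure_source, ]
  b <- emp_bins()
  d$dsr[match(paste(b$length_bin, b$width_bin),
              paste(normalize_bin_label(d$length_bin),
                    normalize_bin_label(d$width_bin)))]
}
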