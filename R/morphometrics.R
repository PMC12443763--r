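default_densities <- c(crocidolite = 3.3, amosite = 3.43)

#' Aerodynamic diameter of an elongate particle (Timbrell model)
#'
#' `AD = 66 * W * (AR / (2 + 4 AR))^shape_exponent * sqrt(rho / rho0)` with
#' `rho0 = 1 g/cm^3`. AD is strictly increasing in width, aspect ratio and
#' density, and approaches `66 * (1/4)^2.2 * W * sqrt(rho) ~= 3.126 W
#' sqrt(rho)` as the aspect ratio grows.
#'
#' @param width Particle width, um.
#' @param aspect_ratio Length/width, >= 1.
#' @param density Particle density, g/cm^3 (crocidolite ~3.3, amosite
#'   ~3.43).
#' @param shape_exponent Exponent on the aspect-ratio term (default 2.2).
#' @return Aerodynamic diameter, um.
#' @examples
#' aerodynamic_diameter(0.2, 10, 3.0)  # ~0.973
#' @export
aerodynamic_diameter <- function(width, aspect_ratio, density = 3.3,
                                 shape_exponent = 2.2) {
  if (any(width <= 0) || any(aspect_ratio < 1) || any(density <= 0)) {
    stop("require width > 0, aspect_ratio >= 1, density > 0")
  }
  66 * width * (aspect_ratio / (2 + 4 * aspect_ratio))^shape_exponent *
    sqrt(density)
}

#' Is a particle respirable?
#'
#' Particles with aerodynamic diameter above the 4 um cutpoint are
#' considered non-respirable.
#'
#' @param ad Aerodynamic diameter, um.
#' @param cutpoint Respirability cutpoint, um.
#' @return Logical vector.
#' @export
is_respirable <- function(ad, cutpoint = 4) {
  ad <= cutpoint
}

#' Dimensional discriminant for criteria particles
#'
#' A particle is a "criteria" particle -- a dimensional proxy for
#' asbestiform morphology -- when
#' `2.99 log10(L) - 5.82 log10(W) - 3.80 >= 0` (boundary inclusive).
#'
#' @param length,width Particle dimensions, um; must be positive.
#' @return Data frame with columns `score` and `is_criteria`.
#' @examples
#' criteria_discriminant(10, 0.1)  # score 5.01, criteria
#' criteria_discriminant(5, 1)    # score -1.71, non-criteria
#' @export
criteria_discriminant <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("particle dimensions must be positive")
  }
  score <- 2.99 * log10(length) - 5.82 * log10(width) - 3.80
  data.frame(score = score, is_criteria = score >= 0)
}

#' Pearson index of a particle population
#'
#' The Pearson index is the correlation between log width and log length
#' over particles longer than `min_length` um (with the global width and
#' aspect-ratio filter applied); the companion least-squares fit
#' `log10 W = F log10 L + C` gives the slope `F` and intercept `C`. A high
#' index indicates mechanical shaping (cleavage fragments); asbestiform
#' growth yields weaker length-width coupling.
#'
#' @param fibers A [fiber_set()].
#' @param min_length Strict lower length bound, um (default 2).
#' @return A list of class `pearson_fit`: `r`, `slope`, `intercept`,
#'   `n_used`.
#' @export
pearson_index <- function(fibers, min_length = 2) {
  f <- filter_fibers(fibers, min_length = min_length)
  if (nrow(f) < 3) {
    stop("need at least 3 particles after filtering for the Pearson index; have ",
         nrow(f))
  }
  x <- log10(f$length_um)
  y <- log10(f$width_um)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in log length or log width: Pearson index undefined")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(r = stats::cor(x, y), slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]), n_used = nrow(f)),
            class = "pearson_fit")
}

#' Fraction of criteria particles in a population
#'
#' @inheritParams pearson_index
#' @return Fraction in 0-1 of particles (after filtering) passing the
#'   criteria discriminant.
#' @export
criteria_fraction <- function(fibers, min_length = 2) {
  f <- filter_fibers(fibers, min_length = min_length)
  check_nonempty(f, "criteria fraction")
  mean(criteria_discriminant(f$length_um, f$width_um)$is_criteria)
}

#' Habit decision rule for a particle population
#'
#' Classifies a population as asbestiform, undetermined, or
#' non-asbestiform from its criteria fraction (CF) and Pearson index (PI),
#' evaluated in order:
#' \enumerate{
#'   \item asbestiform if `CF >= 0.58 * PI + 0.12`;
#'   \item undetermined if `PI` in `[0.3, 0.5]` and `CF` in `[0.2, 0.3]`,
#'     or `PI` in `[0.4, 0.5]` and `CF` in `[0.1, 0.2]` (closed windows);
#'   \item non-asbestiform otherwise.
#' }
#'
#' @param criteria_fraction Fraction in 0-1.
#' @param pearson_index Correlation in -1..1.
#' @return Character vector: `"asbestiform"`, `"undetermined"` or
#'   `"non-asbestiform"`.
#' @export
classify_habit <- function(criteria_fraction, pearson_index) {
  stopifnot(length(criteria_fraction) == length(pearson_index))
  cf <- criteria_fraction
  pi_ <- pearson_index
  if (any(cf < 0 | cf > 1, na.rm = TRUE)) stop("criteria_fraction outside [0, 1]")
  if (any(pi_ < -1 | pi_ > 1, na.rm = TRUE)) stop("pearson_index outside [-1, 1]")
  out <- rep("non-asbestiform", length(cf))
  undet <- (pi_ >= 0.3 & pi_ <= 0.5 & cf >= 0.2 & cf <= 0.3) |
    (pi_ >= 0.4 & pi_ <= 0.5 & cf >= 0.1 & cf <= 0.2)
  out[undet] <- "undetermined"
  out[cf >= 0.58 * pi_ + 0.12] <- "asbestiform"
  out
}

#' Assess the morphological habit of a particle population
#'
#' Computes the criteria fraction and Pearson index on the filtered
#' population and applies [classify_habit()].
#'
#' @inheritParams pearson_index
#' @return A list of class `habit_assessment`: `criteria_fraction`,
#'   `pearson_index`, `habit`, `n_used`.
#' @export
assess_habit <- function(fibers, min_length = 2) {
  pf <- pearson_index(fibers, min_length = min_length)
  cf <- criteria_fraction(fibers, min_length = min_length)
  structure(list(criteria_fraction = cf, pearson_index = pf$r,
                 habit = classify_habit(cf, pf$r), n_used = pf$n_used),
            class = "habit_assessment")
}

#' @export
print.habit_assessment <- function(x, ...) {
  cat(sprintf(
    "habit assessment: %s (criteria fraction %.2f, Pearson index %.2f, n = %d)\n",
    x$habit, x$criteria_fraction, x$pearson_index, x$n_used))
  invisible(x)
}
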