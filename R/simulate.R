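#' Monte Carlo reconstruction settings
#'
#' @param n_particles Number of particles to generate (default 2000, the
#'   size of the reconstructed Pooley-Clark datasets).
#' @param seed Integer RNG seed.
#' @param within_bin_gsd Geometric standard deviation of the within-bin
#'   log-normal dimension distributions (must be > 1; default 1.5).
#' @param mode Bin-count allocation: `"multinomial"` draws counts from a
#'   multinomial with the matrix fractions as probabilities (honest sampling
#'   error); `"quota"` uses largest-remainder rounding for exact quotas.
#' @param max_resample Attempts at jointly redrawing (length, width) pairs
#'   that violate the aspect-ratio >= 3 constraint before falling back to
#'   drawing width conditional on length.
#' @param length_cap,width_cap Sampling caps for the open top bins, um (see
#'   [emp_bins()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_particles = 2000, seed = 1, within_bin_gsd = 1.5,
                       mode = c("multinomial", "quota"), max_resample = 100,
                       length_cap = 40, width_cap = 3) {
  mode <- match.arg(mode)
  stopifnot(n_particles >= 1, within_bin_gsd > 1, max_resample >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 seed = as.integer(seed),
                 within_bin_gsd = within_bin_gsd, mode = mode,
                 max_resample = as.integer(max_resample),
                 length_cap = length_cap, width_cap = width_cap),
            class = "sim_config")
}

# inverse-CDF draw from a log-normal with median `gm` and geometric sd `gsd`,
# truncated to [lo, hi)
rtrunc_lnorm <- function(n, gm, gsd, lo, hi) {
  mu <- log(gm)
  sdlog <- log(gsd)
  plo <- stats::plnorm(lo, mu, sdlog)
  phi <- stats::plnorm(hi, mu, sdlog)
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(u, mu, sdlog)
}

bin_feasible <- function(binrow) {
  # a (L, W) with L/W >= 3 exists in the (capped) bin rectangle iff the
  # largest length exceeds three times the smallest width
  binrow$length_hi_cap > 3 * binrow$width_lo
}

#' Sample particle dimensions within one size bin
#'
#' Length and width are drawn independently from log-normal distributions
#' whose median sits at the geometric midpoint of the (capped) bin interval,
#' with geometric standard deviation `within_bin_gsd`, truncated to the bin
#' by inverse-CDF sampling. Pairs violating the aspect-ratio >= 3 filter are
#' jointly redrawn up to `max_resample` times; any still-invalid pairs then
#' have length redrawn from the feasible sub-interval and width redrawn
#' conditional on that length, which guarantees a valid particle whenever
#' the bin admits one.
#'
#' Uses the current RNG state; call `set.seed()` (or use
#' [reconstruct_fibers()]) for reproducibility.
#'
#' @param bin Bin id (1-32) or a single row of [emp_bins()].
#' @param n Number of particles.
#' @param config A [sim_config()].
#' @return Data frame with columns `length_um`, `width_um`.
#' @export
sample_within_bin <- function(bin, n, config = sim_config()) {
  bins <- emp_bins(config$length_cap, config$width_cap)
  if (is.numeric(bin) && length(bin) == 1) bin <- bins[bin, ]
  stopifnot(is.data.frame(bin), nrow(bin) == 1)
  if (!bin_feasible(bin)) {
    stop("bin (", bin$length_bin, ", ", bin$width_bin,
         ") has no feasible region with aspect ratio >= 3")
  }
  gsd <- config$within_bin_gsd
  gmL <- sqrt(bin$length_lo * bin$length_hi_cap)
  gmW <- sqrt(bin$width_lo * bin$width_hi_cap)
  L <- rtrunc_lnorm(n, gmL, gsd, bin$length_lo, bin$length_hi_cap)
  W <- rtrunc_lnorm(n, gmW, gsd, bin$width_lo, bin$width_hi_cap)
  for (i in seq_len(config$max_resample)) {
    bad <- which(L / W < 3)
    if (!length(bad)) break
    L[bad] <- rtrunc_lnorm(length(bad), gmL, gsd, bin$length_lo,
                           bin$length_hi_cap)
    W[bad] <- rtrunc_lnorm(length(bad), gmW, gsd, bin$width_lo,
                           bin$width_hi_cap)
  }
  bad <- which(L / W < 3)
  if (length(bad)) {
    # conditional fallback: length restricted so that some width is feasible,
    # then width truncated to [width_lo, L/3)
    llo <- max(bin$length_lo, 3 * bin$width_lo)
    L[bad] <- rtrunc_lnorm(length(bad), gmL, gsd, llo, bin$length_hi_cap)
    W[bad] <- rtrunc_lnorm(length(bad), gmW, gsd, bin$width_lo,
                           pmin(bin$width_hi_cap, L[bad] / 3))
  }
  data.frame(length_um = L, width_um = W)
}

largest_remainder <- function(p, n) {
  q <- n * p
  k <- floor(q)
  rem <- as.integer(n - sum(k))
  if (rem > 0) {
    # break remainder ties by bin order
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Reconstruct a fiber-level dataset from a binned size matrix
#'
#' Monte Carlo reconstruction of individual (length, width) records whose
#' bin frequencies correspond to a percent-frequency matrix: bin counts are
#' allocated multinomially (or by largest-remainder quota), then dimensions
#' are drawn within each bin by [sample_within_bin()]. Every record lies in
#' its source bin and satisfies the global dimensional filter.
#'
#' @param matrix A [size_matrix()].
#' @param config A [sim_config()]; `config$seed` fixes the draw.
#' @return A [fiber_set()] of exactly `config$n_particles` records, with
#'   provenance recording mineral, medium, seed and allocation mode.
#' @examples
#' m <- load_size_matrix("amosite/lung")
#' f <- reconstruct_fibers(m, sim_config(n_particles = 500, seed = 7))
#' median(f$width_um)
#' @export
reconstruct_fibers <- function(matrix, config = sim_config()) {
  stopifnot(inherits(matrix, "size_matrix"), inherits(config, "sim_config"))
  p <- matrix$percent
  if (all(p == 0)) stop("all-zero size matrix")
  p <- p / sum(p)
  infeasible <- which(p > 0 &
                        !vapply(seq_len(32L), function(i) {
                          bin_feasible(emp_bins(config$length_cap,
                                                config$width_cap)[i, ])
                        }, logical(1)))
  if (length(infeasible)) {
    b <- emp_bins()
    stop("nonzero frequency in bin(s) with no aspect-ratio-feasible region: ",
         paste(sprintf("(%s, %s)", b$length_bin[infeasible],
                       b$width_bin[infeasible]), collapse = "; "))
  }
  set.seed(config$seed)
  counts <- if (config$mode == "multinomial") {
    as.integer(stats::rmultinom(1, config$n_particles, p))
  } else {
    largest_remainder(p, config$n_particles)
  }
  bins <- emp_bins(config$length_cap, config$width_cap)
  parts <- lapply(which(counts > 0), function(i) {
    sample_within_bin(bins[i, ], counts[i], config)
  })
  d <- do.call(rbind, parts)
  fiber_set(d$length_um, d$width_um, mineral = matrix$mineral,
            provenance = sprintf("simulated %s/%s seed=%d mode=%s n=%d",
                                 matrix$mineral, matrix$medium, config$seed,
                                 config$mode, config$n_particles))
}

derive_seed <- function(master_seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer(((master_seed %% 100000) * 131 + h) %% .Machine$integer.max)
}

#' Reconstruct all six packaged mineral/medium datasets
#'
#' One fiber set per (mineral, medium) fixture combination, with per-dataset
#' seeds derived deterministically from the master seed so partial reruns
#' reproduce identical datasets.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param combos Data frame with columns `mineral`, `medium` (defaults to
#'   the six packaged fixtures).
#' @return Named list of [fiber_set()] objects, names `"mineral/medium"`.
#' @export
simulate_all <- function(config = sim_config(), combos = fixture_combos()) {
  out <- lapply(seq_len(nrow(combos)), function(i) {
    id <- paste(combos$mineral[i], combos$medium[i], sep = "/")
    cfg <- config
    cfg$seed <- derive_seed(config$seed, id)
    reconstruct_fibers(load_size_matrix(id), cfg)
  })
  names(out) <- paste(combos$mineral, combos$medium, sep = "/")
  out
}
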