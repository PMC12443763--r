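#' Build bin-level regression points from DSR tables
#'
#' Each defined (non-`NA`) bin of each table contributes one point with a
#' representative length and width. Under the default `"geomid"` scheme the
#' representatives are the geometric midpoints of the (capped) bin
#' intervals; under `"mppd_gm"` the representative width is the packaged
#' MPPD geometric-mean width for that mineral and bin (length stays at the
#' geometric midpoint).
#'
#' @param tables A `dsr_table` or list of them (see [compute_dsr()]).
#' @param rep_scheme `"geomid"` or `"mppd_gm"`.
#' @param mppd MPPD records (default [emp_mppd()]), used by `"mppd_gm"`.
#' @return Data frame with columns `rep_length`, `rep_width`, `dsr`,
#'   `log_dsr`, `mineral`, `source`, `bin`.
#' @export
make_bin_points <- function(tables, rep_scheme = c("geomid", "mppd_gm"),
                            mppd = NULL) {
  rep_scheme <- match.arg(rep_scheme)
  if (inherits(tables, "dsr_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "dsr_table")))
  if (rep_scheme == "mppd_gm" && is.null(mppd)) mppd <- emp_mppd()
  b <- emp_bins()
  pts <- lapply(tables, function(tb) {
    ok <- which(!is.na(tb$dsr))
    w <- b$rep_width[ok]
    if (rep_scheme == "mppd_gm") {
      sel <- mppd$mineral == tb$mineral
      gmv <- rep(NA_real_, 32)
      gmv[mppd$bin[sel]] <- mppd$gm_width_um[sel]
      w <- ifelse(is.na(gmv[ok]), w, gmv[ok])
    }
    data.frame(rep_length = b$rep_length[ok], rep_width = w,
               dsr = unname(tb$dsr[ok]), log_dsr = log_dsr(unname(tb$dsr[ok])),
               mineral = tb$mineral, source = tb$exposure_source, bin = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  if (!nrow(out)) stop("no defined DSR bins: cannot build regression points")
  out
}

new_dsr_regression <- function(A, B, C, R, R2, p, n) {
  structure(list(A = A, B = B, C = C, R = R, R2 = R2, p = p, n = n),
            class = "dsr_regression")
}

#' @export
print.dsr_regression <- function(x, ...) {
  cat(sprintf(
    "log10(DSR + 0.001) = %.2f %+.2f log10(L) %+.2f log10(W)\n", x$A, x$B,
    x$C))
  cat(sprintf("  R = %.2f, R^2 = %.2f, p = %s, n = %d\n", x$R, x$R2,
              format.pval(x$p, digits = 2), x$n))
  invisible(x)
}

#' Fit the log-log DSR regression
#'
#' Ordinary least squares of `log10(DSR + 0.001)` on `log10(length)` and
#' `log10(width)` over bin-level points: the intercept `A`, length
#' coefficient `B` (positive: longer particles are preferentially retained)
#' and width coefficient `C` (negative: wider particles are deselected).
#'
#' @param points Data frame from [make_bin_points()] (needs `rep_length`,
#'   `rep_width`, `log_dsr`).
#' @return A list of class `dsr_regression`: coefficients `A`, `B`, `C`,
#'   multiple correlation `R`, determination `R2`, overall-F `p`, and `n`.
#' @export
fit_dsr_regression <- function(points) {
  stopifnot(all(c("rep_length", "rep_width", "log_dsr") %in% names(points)))
  if (nrow(points) < 4) stop("need at least 4 points, have ", nrow(points))
  d <- data.frame(y = points$log_dsr, lL = log10(points$rep_length),
                  lW = log10(points$rep_width))
  fit <- stats::lm(y ~ lL + lW, data = d)
  if (any(is.na(stats::coef(fit)))) stop("collinear design: fit is degenerate")
  s <- summary(fit)
  p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                 lower.tail = FALSE)
  cf <- stats::coef(fit)
  new_dsr_regression(unname(cf[1]), unname(cf[2]), unname(cf[3]),
                     sqrt(s$r.squared), s$r.squared, unname(p), nrow(d))
}

#' Published log-log DSR model coefficients
#'
#' The reference coefficient sets for the combined amosite + crocidolite
#' fit and the per-mineral fits, as reported with the packaged frequency
#' tables. Useful for scoring arbitrary particle lists without refitting.
#'
#' @param which `"combined"`, `"crocidolite"` or `"amosite"`.
#' @return A `dsr_regression` object (with `p` and `n` unset).
#' @export
reference_dsr_model <- function(which = c("combined", "crocidolite",
                                          "amosite")) {
  which <- match.arg(which)
  co <- switch(which,
               combined = c(-1.09, 0.53, -1.03, 0.62),
               crocidolite = c(-1.67, 0.76, -1.45, 0.72),
               amosite = c(-0.52, 0.30, -0.63, 0.61))
  new_dsr_regression(co[1], co[2], co[3], co[4], co[4]^2, NA_real_,
                     NA_integer_)
}

#' Predict DSR from particle dimensions
#'
#' Inverts the offset log model: `DSR = 10^(A + B log10 L + C log10 W) -
#' 0.001`, floored at 0.
#'
#' @param length,width Particle dimensions, um.
#' @param model A `dsr_regression` (from [fit_dsr_regression()] or
#'   [reference_dsr_model()]).
#' @return Predicted DSR value(s).
#' @examples
#' predict_dsr(10, 0.1, reference_dsr_model("combined"))  # ~2.95
#' @export
predict_dsr <- function(length, width, model) {
  stopifnot(inherits(model, "dsr_regression"))
  if (any(length <= 0) || any(width <= 0)) {
    stop("particle dimensions must be positive")
  }
  pmax(10^(model$A + model$B * log10(length) + model$C * log10(width)) -
         0.001, 0)
}

#' Correlation matrix between log-transformed DSR estimates
#'
#' Pairwise Pearson correlations of `log10(DSR + 0.001)` vectors over the
#' 32 bins, pairwise-complete (bins undefined in either member dropped).
#'
#' @param tables List of `dsr_table` objects sharing the bin scheme.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
dsr_correlation_matrix <- function(tables) {
  stopifnot(length(tables) >= 2,
            all(vapply(tables, inherits, logical(1), "dsr_table")))
  M <- vapply(tables, function(tb) log_dsr(unname(tb$dsr)), numeric(32))
  if (!is.null(names(tables))) colnames(M) <- names(tables)
  npair <- crossprod(!is.na(M))
  if (any(npair < 3)) stop("fewer than 3 complete bin pairs for some table pair")
  stats::cor(M, use = "pairwise.complete.obs")
}

#' Fit the mesothelioma-potency model
#'
#' OLS of `log10(R_M)` on `log10(average DSR)` and `log10(biopersistence)`
#' over mineral types. Both coefficients are expected positive: minerals
#' whose size distributions favor lung retention, and which persist longer
#' in lung fluid, carry higher mesothelioma potency.
#'
#' @param profiles Data frame with columns `mineral`, `r_m_percent`,
#'   `avg_dsr`, `biopersistence_years` (default [emp_mineral_profiles()]).
#' @return List of class `potency_fit`: `intercept`, `coef_dsr`,
#'   `coef_bioper`, `R`, `R2`, `p`, `n`, and `predicted`, a data frame of
#'   per-mineral observed and predicted R_M (percent).
#' @export
fit_potency_model <- function(profiles = emp_mineral_profiles()) {
  need <- c("mineral", "r_m_percent", "avg_dsr", "biopersistence_years")
  stopifnot(all(need %in% names(profiles)))
  ok <- profiles$r_m_percent > 0 & profiles$avg_dsr > 0 &
    profiles$biopersistence_years > 0
  d <- profiles[ok, ]
  if (nrow(d) < 4) stop("need at least 4 minerals with positive values")
  fit <- stats::lm(log10(r_m_percent) ~ log10(avg_dsr) +
                     log10(biopersistence_years), data = d)
  if (any(is.na(stats::coef(fit)))) stop("degenerate design")
  s <- summary(fit)
  p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                 lower.tail = FALSE)
  cf <- unname(stats::coef(fit))
  structure(list(intercept = cf[1], coef_dsr = cf[2], coef_bioper = cf[3],
                 R = sqrt(s$r.squared), R2 = s$r.squared, p = unname(p),
                 n = nrow(d),
                 predicted = data.frame(mineral = d$mineral,
                                        observed_r_m = d$r_m_percent,
                                        predicted_r_m = 10^stats::fitted(fit),
                                        stringsAsFactors = FALSE)),
            class = "potency_fit")
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf(
    "log10(R_M) = %.2f %+.2f log10(DSR) %+.2f log10(Bioper)\n",
    x$intercept, x$coef_dsr, x$coef_bioper))
  cat(sprintf("  R = %.2f, R^2 = %.2f, p = %.4f, n = %d minerals\n", x$R,
              x$R2, x$p, x$n))
  invisible(x)
}

#' Compare observed DSR with MPPD pulmonary deposition rates
#'
#' Pairs each bin's MPPD pulmonary deposition rate with the observed DSR of
#' that bin (both exposure sources, both minerals by default); bins
#' undefined on either side are dropped. The default `"log"` transform
#' correlates the rate with `log10(DSR + 0.001)`, matching the
#' log-transformation used for DSR throughout; the untransformed variant is
#' always reported alongside. When `lung` matrices are supplied the
#' MPPD-vs-lung-frequency correlation is computed the same way
#' (`log10(percent + 0.001)` under `"log"`).
#'
#' @param tables List of `dsr_table` objects.
#' @param mppd MPPD records (default [emp_mppd()]).
#' @param transform `"log"` or `"linear"`: which variant is the headline
#'   `r`.
#' @param lung Optional named list of lung [size_matrix()] objects keyed by
#'   mineral, for the frequency correlation.
#' @return List of class `mppd_comparison`: `r`, `p`, `n`, `slope`,
#'   `intercept` for the headline variant; `r_log`, `r_linear`; and when
#'   `lung` is given, `r_lung`, `p_lung`, `n_lung`.
#' @export
mppd_comparison <- function(tables, mppd = emp_mppd(),
                            transform = c("log", "linear"), lung = NULL) {
  transform <- match.arg(transform)
  if (inherits(tables, "dsr_table")) tables <- list(tables)
  rate_of <- function(mineral) {
    r <- rep(NA_real_, 32)
    sel <- mppd$mineral == mineral
    r[mppd$bin[sel]] <- mppd$pulmonary_deposition_rate[sel]
    r
  }
  x <- unlist(lapply(tables, function(tb) rate_of(tb$mineral)))
  y <- unlist(lapply(tables, function(tb) unname(tb$dsr)))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 matched (MPPD, DSR) pairs")
  ct_lin <- stats::cor.test(x[ok], y[ok])
  ct_log <- stats::cor.test(x[ok], log_dsr(y[ok]))
  head_ct <- if (transform == "log") ct_log else ct_lin
  yy <- if (transform == "log") log_dsr(y[ok]) else y[ok]
  line <- stats::coef(stats::lm(yy ~ x[ok]))
  out <- list(transform = transform,
              r = unname(head_ct$estimate), p = head_ct$p.value, n = sum(ok),
              slope = unname(line[2]), intercept = unname(line[1]),
              r_log = unname(ct_log$estimate),
              r_linear = unname(ct_lin$estimate))
  if (!is.null(lung)) {
    xf <- unlist(lapply(names(lung), function(m) rate_of(m)))
    yf <- unlist(lapply(lung, function(sm) unname(sm$percent)))
    okf <- !is.na(xf) & !is.na(yf)
    yyf <- if (transform == "log") log10(yf[okf] + 0.001) else yf[okf]
    ctf <- stats::cor.test(xf[okf], yyf)
    out$r_lung <- unname(ctf$estimate)
    out$p_lung <- ctf$p.value
    out$n_lung <- sum(okf)
  }
  structure(out, class = "mppd_comparison")
}

#' @export
print.mppd_comparison <- function(x, ...) {
  cat(sprintf(
    "MPPD pulmonary deposition rate vs DSR (%s): R = %.2f (p = %s, n = %d)\n",
    x$transform, x$r, format.pval(x$p, digits = 2), x$n))
  cat(sprintf("  variants: linear R = %.2f, log R = %.2f\n", x$r_linear,
              x$r_log))
  if (!is.null(x$r_lung)) {
    cat(sprintf("  MPPD vs lung frequency: R = %.2f (p = %s, n = %d)\n",
                x$r_lung, format.pval(x$p_lung, digits = 2), x$n_lung))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov check of DSR log-normality
#'
#' One-sample KS test of `log10(DSR)` (positive values only) against a
#' normal distribution with moment-fitted mean and standard deviation. A
#' large p-value is consistent with log-normally distributed DSR, the
#' assumption behind the offset log transform used in the regressions.
#'
#' @param values Numeric DSR values; `NA` and non-positive values are
#'   dropped (at least 10 positive values required).
#' @return List with `statistic`, `p.value`, `n`.
#' @export
ks_lognormality <- function(values) {
  v <- values[!is.na(values) & values > 0]
  if (length(v) < 10) stop("need at least 10 positive DSR values, have ",
                           length(v))
  x <- log10(v)
  if (stats::sd(x) == 0) stop("constant sample: log-normality test undefined")
  k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(k$statistic), p.value = k$p.value, n = length(v))
}

#' Mean predicted DSR over a particle population
#'
#' Applies [predict_dsr()] to every particle and returns the mean and its
#' standard error.
#'
#' @param fibers A nonempty filtered [fiber_set()].
#' @param model A `dsr_regression`.
#' @return List with `mean`, `se`, `n`.
#' @export
average_dsr <- function(fibers, model) {
  stopifnot(inherits(fibers, "fiber_set"))
  check_nonempty(fibers, "average DSR")
  v <- predict_dsr(fibers$length_um, fibers$width_um, model)
  se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  list(mean = mean(v), se = se, n = length(v))
}
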