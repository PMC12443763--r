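test_that("bin points cover exactly the defined bins with geometric-midpoint reps", {
  tabs <- packaged_dsr_tables()
  p1 <- make_bin_points(tabs[["crocidolite/airborne_pooley"]])
  expect_equal(nrow(p1), 30L)   # two undefined bins dropped
  b <- emp_bins()
  i <- which(b$length_bin == "1-2" & b$width_bin == "<0.125")
  row <- p1[p1$bin == i, ]
  expect_equal(row$rep_length, sqrt(2))
  expect_equal(row$rep_width, sqrt(0.05 * 0.125))
  # additivity over tables
  pall <- make_bin_points(tabs)
  expect_equal(nrow(pall),
               sum(vapply(tabs, function(t) sum(!is.na(t$dsr)), numeric(1))))
  # the mppd_gm scheme swaps in packaged geometric-mean widths
  p6 <- make_bin_points(tabs[["crocidolite/airborne_pooley"]],
                        rep_scheme = "mppd_gm")
  mp <- emp_mppd()
  gm <- mp$gm_width_um[mp$mineral == "crocidolite" & mp$bin == i]
  expect_equal(p6$rep_width[p6$bin == i], gm)
})

test_that("regression recovers planted coefficients and matches a normal-equations oracle", {
  b <- emp_bins()
  pts <- data.frame(rep_length = b$rep_length, rep_width = b$rep_width)
  pts$log_dsr <- -1 + 0.5 * log10(pts$rep_length) - 1 * log10(pts$rep_width)
  fit <- suppressWarnings(fit_dsr_regression(pts))  # exact fit warns
  expect_equal(c(fit$A, fit$B, fit$C), c(-1, 0.5, -1), tolerance = 1e-9)
  expect_equal(fit$R, 1, tolerance = 1e-6)
  # independent least-squares oracle on random designs
  set.seed(12)
  for (k in 1:5) {
    n <- 20
    d <- data.frame(rep_length = 10^runif(n, 0, 1.5),
                    rep_width = 10^runif(n, -1.3, 0.4))
    d$log_dsr <- rnorm(n)
    f <- fit_dsr_regression(d)
    X <- cbind(1, log10(d$rep_length), log10(d$rep_width))
    beta <- solve(t(X) %*% X, t(X) %*% d$log_dsr)
    expect_equal(c(f$A, f$B, f$C), as.numeric(beta), tolerance = 1e-9)
    res <- d$log_dsr - X %*% beta
    R2 <- 1 - sum(res^2) / sum((d$log_dsr - mean(d$log_dsr))^2)
    expect_equal(f$R2, R2, tolerance = 1e-9)
    expect_equal(f$R^2, f$R2, tolerance = 1e-12)
  }
  expect_error(fit_dsr_regression(pts[1:3, ]), "at least 4")
  degen <- pts; degen$rep_width <- degen$rep_length
  expect_error(fit_dsr_regression(degen), "collinear")
})

test_that("DSR prediction inverts the offset log model", {
  m <- reference_dsr_model("combined")
  expect_equal(predict_dsr(10, 0.1, m), 10^0.47 - 0.001, tolerance = 1e-12)
  expect_equal(predict_dsr(10, 0.1, m), 2.950, tolerance = 1e-3)
  # linear predictor of -3 maps back to DSR exactly 0
  W0 <- 10^((-3 - m$A - m$B * log10(4)) / m$C)
  expect_equal(predict_dsr(4, W0, m), 0, tolerance = 1e-15)
  # increasing in length, decreasing in width when B > 0 > C
  expect_gt(predict_dsr(12, 0.1, m), predict_dsr(10, 0.1, m))
  expect_lt(predict_dsr(10, 0.2, m), predict_dsr(10, 0.1, m))
})

test_that("correlation matrix is pairwise-complete, symmetric, unit-diagonal", {
  tabs <- packaged_dsr_tables()
  M <- dsr_correlation_matrix(tabs)
  expect_equal(diag(M), setNames(rep(1, 4), names(tabs)))
  expect_equal(M, t(M))
  # toy pair with hand-computed correlation over the complete bins
  v1 <- rep(NA_real_, 32); v2 <- rep(NA_real_, 32)
  v1[1:5] <- c(0.2, 0.7, 1.4, 2.8, 0.1)
  v2[c(1:4, 6)] <- c(0.3, 0.5, 2.2, 3.1, 0.9)
  x <- log10(v1[1:4] + 0.001); y <- log10(v2[1:4] + 0.001)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  M2 <- dsr_correlation_matrix(list(toy_dsr_table(v1), toy_dsr_table(v2)))
  expect_equal(M2[1, 2], r_hand, tolerance = 1e-12)
})

test_that("the potency model fits planted planes and the packaged minerals", {
  # three synthetic minerals exactly on a plane -> perfect fit
  d <- data.frame(mineral = c("a", "b", "c", "d"),
                  avg_dsr = c(0.5, 1, 2, 4),
                  biopersistence_years = c(10, 100, 50, 20))
  d$r_m_percent <- 10^(-2 + 2 * log10(d$avg_dsr) +
                         1 * log10(d$biopersistence_years))
  f <- suppressWarnings(fit_potency_model(d))  # exact fit warns
  expect_equal(c(f$intercept, f$coef_dsr, f$coef_bioper), c(-2, 2, 1),
               tolerance = 1e-9)
  expect_equal(f$R, 1, tolerance = 1e-6)
  # packaged seven-mineral fit returns per-mineral predictions
  pf <- fit_potency_model()
  expect_equal(pf$n, 7L)
  expect_equal(nrow(pf$predicted), 7L)
  # the published coefficient set predicts crocidolite potency near 0.55%
  pred_croc <- 10^(-3.07 + 3.01 * log10(1.78) + 1.13 * log10(66))
  expect_equal(pred_croc, 0.5495, tolerance = 1e-3)
  expect_error(fit_potency_model(d[1:3, ]), "at least 4")
})

test_that("MPPD comparison returns both transforms and a perfect self-match", {
  mp <- emp_mppd()
  rate <- rep(NA_real_, 32)
  sel <- mp$mineral == "crocidolite"
  rate[mp$bin[sel]] <- mp$pulmonary_deposition_rate[sel]
  self <- mppd_comparison(toy_dsr_table(rate, mineral = "crocidolite"),
                          transform = "linear")
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_error(mppd_comparison(toy_dsr_table(c(0.1, rep(NA, 31)),
                                             mineral = "crocidolite")),
               "fewer than 3")
})

test_that("the log-normality check behaves as a calibrated KS test", {
  # with moment-fitted parameters the KS test is conservative: exactly
  # log-normal data essentially never produce small p-values
  set.seed(99)
  ps <- replicate(40, ks_lognormality(10^rnorm(500, 0, 0.4))$p.value)
  expect_gt(min(ps), 0.05)
  expect_gt(mean(ps), 0.5)
  expect_error(ks_lognormality(rep(2, 50)), "constant sample")
  expect_error(ks_lognormality(c(1, 2, 3)), "at least 10")
  # zeros and NA are excluded, not transformed
  expect_equal(ks_lognormality(c(rep(c(1.1, 2.3, 0.4, 3.7), 5), 0, NA))$n,
               20L)
})

test_that("population mean predicted DSR and its standard error", {
  m <- reference_dsr_model("combined")
  one <- average_dsr(fiber_set(10, 0.1), m)
  expect_equal(one$mean, 2.950, tolerance = 1e-3)
  expect_equal(one$se, 0)
  same <- average_dsr(fiber_set(rep(6, 8), rep(0.2, 8)), m)
  expect_equal(same$se, 0)
})
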