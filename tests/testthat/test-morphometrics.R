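test_that("aerodynamic diameter matches direct arithmetic and its asymptote", {
  expect_equal(aerodynamic_diameter(0.2, 10, 3.0), 0.97272, tolerance = 1e-4)
  # long-fiber asymptote: 66 * (1/4)^2.2 * W * sqrt(rho) ~= 3.126 W sqrt(rho)
  asym <- function(w, rho) 66 * 0.25^2.2 * w * sqrt(rho)
  expect_equal(aerodynamic_diameter(0.3, 1e9, 2.5), asym(0.3, 2.5),
               tolerance = 1e-6)
  expect_equal(asym(1, 1), 3.1264, tolerance = 1e-3)
  # monotone in each argument and bounded by the asymptote
  set.seed(1)
  for (k in 1:50) {
    w <- runif(1, 0.05, 3); ar <- runif(1, 3, 300); rho <- runif(1, 2, 4)
    ad <- aerodynamic_diameter(w, ar, rho)
    expect_lt(ad, aerodynamic_diameter(w * 1.1, ar, rho))
    expect_lt(ad, aerodynamic_diameter(w, ar * 1.1, rho))
    expect_lt(ad, aerodynamic_diameter(w, ar, rho * 1.1))
    expect_lt(ad, asym(w, rho))
  }
  expect_error(aerodynamic_diameter(-1, 10, 3), "require")
  # respirability cutpoint at 4 um aerodynamic diameter
  expect_false(is_respirable(4.2))
  expect_true(is_respirable(3.9))
})

test_that("criteria discriminant scores and boundary are exact", {
  d <- criteria_discriminant(c(10, 5), c(0.1, 1))
  expect_equal(d$score, c(5.01, -1.7101), tolerance = 1e-4)
  expect_equal(d$is_criteria, c(TRUE, FALSE))
  # boundary inclusive: a particle with score exactly 0 is criteria
  L0 <- 10^(3.80 / 2.99)
  expect_true(criteria_discriminant(L0, 1)$is_criteria)
  # the flag flips exactly where the score changes sign (bisection in width)
  L <- 6
  wstar <- stats::uniroot(function(w) criteria_discriminant(L, w)$score,
                          c(0.05, 3), tol = 1e-12)$root
  expect_true(criteria_discriminant(L, wstar * (1 - 1e-9))$is_criteria)
  expect_false(criteria_discriminant(L, wstar * (1 + 1e-9))$is_criteria)
})

test_that("Pearson index recovers exact power laws and matches a hand oracle", {
  L <- c(4, 5, 6.5, 8, 9)
  f <- fiber_set(L, 0.1 * sqrt(L))
  pf <- pearson_index(f)
  expect_equal(pf$r, 1)
  expect_equal(pf$slope, 0.5, tolerance = 1e-12)
  expect_equal(pf$intercept, -1, tolerance = 1e-12)
  # particles at or below 2 um are excluded before the correlation
  f2 <- fiber_set(c(L, 1.5), c(0.1 * sqrt(L), 0.1))
  expect_equal(pearson_index(f2)$n_used, 5L)
  # brute-force correlation formula on an irregular 5-point set
  set.seed(7)
  L3 <- runif(5, 3, 12); W3 <- runif(5, 0.1, 0.9)
  keep <- L3 / W3 >= 3
  x <- log10(L3[keep]); y <- log10(W3[keep])
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_index(fiber_set(L3, W3))$r, r_hand,
               tolerance = 1e-12)
  expect_error(pearson_index(fiber_set(c(3, 4), c(0.1, 0.1))),
               "at least 3")
  expect_error(pearson_index(fiber_set(rep(5, 4), rep(0.2, 4))),
               "zero variance")
})

test_that("criteria fraction counts discriminant passes", {
  f <- fiber_set(c(10, 5), c(0.1, 1))
  expect_equal(criteria_fraction(f), 0.5)
  allc <- fiber_set(c(10, 12, 20), c(0.1, 0.08, 0.05))
  expect_equal(criteria_fraction(allc), 1)
})

test_that("the habit decision rule is total, ordered and matches examples", {
  expect_equal(classify_habit(0.73, 0.47), "asbestiform")
  expect_equal(classify_habit(0.25, 0.40), "undetermined")
  expect_equal(classify_habit(0.05, 0.10), "non-asbestiform")
  expect_equal(classify_habit(0.15, 0.45), "undetermined")
  # grid totality and single-valuedness over the full domain
  g <- expand.grid(cf = seq(0, 1, by = 0.05), pi = seq(-1, 1, by = 0.05))
  h <- classify_habit(g$cf, g$pi)
  expect_true(all(h %in% c("asbestiform", "undetermined",
                           "non-asbestiform")))
  # the asbestiform rule is evaluated first
  on_line <- classify_habit(0.58 * 0.3 + 0.12, 0.3)
  expect_equal(on_line, "asbestiform")
  expect_error(classify_habit(1.2, 0), "outside")
})
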