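test_that("within-bin draws respect the bin and the aspect-ratio filter", {
  cfg <- sim_config(seed = 11)
  b <- emp_bins()
  i <- which(b$length_bin == "1-2" & b$width_bin == "<0.125")
  set.seed(11)
  d <- sample_within_bin(i, 2000, cfg)
  expect_true(all(d$length_um >= 1 & d$length_um < 2))
  expect_true(all(d$width_um >= 0.05 & d$width_um < 0.125))
  expect_true(all(d$length_um / d$width_um >= 3))
  # determinism under a fixed RNG state
  set.seed(11)
  expect_identical(sample_within_bin(i, 2000, cfg), d)
  # infeasible bin: (<1, >0.375) admits no particle with aspect ratio >= 3
  j <- which(b$length_bin == "<1" & b$width_bin == ">0.375")
  expect_error(sample_within_bin(j, 10, cfg), "no feasible region")
})

test_that("within-bin median sits at the geometric bin midpoint", {
  b <- emp_bins()
  i <- which(b$length_bin == "2-3" & b$width_bin == "0.125-0.250")
  set.seed(202)
  d <- sample_within_bin(i, 1e4, sim_config())
  gm <- sqrt(2 * 3)
  expect_gt(median(d$length_um), gm * 0.9)
  expect_lt(median(d$length_um), gm * 1.1)
})

test_that("reconstruction matches the matrix fractions", {
  m <- load_size_matrix("crocidolite/lung")
  f <- reconstruct_fibers(m, sim_config(n_particles = 2000, seed = 5))
  expect_equal(nrow(f), 2000L)
  # chi-square goodness of fit of bin counts against the matrix fractions
  p <- matrix_fractions(m)
  counts <- tabulate(bin_for(f$length_um, f$width_um), 32)
  gof <- suppressWarnings(stats::chisq.test(counts[p > 0], p = p[p > 0],
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
  # quota mode: counts are exactly the largest-remainder quotas
  fq <- reconstruct_fibers(m, sim_config(n_particles = 2000, seed = 5,
                                         mode = "quota"))
  cq <- tabulate(bin_for(fq$length_um, fq$width_um), 32)
  expect_equal(sum(cq), 2000L)
  expect_true(all(abs(cq - 2000 * p) < 1))
  # degenerate matrix: all particles land in the single nonzero bin
  f1 <- reconstruct_fibers(toy_matrix(3), sim_config(n_particles = 100,
                                                     seed = 1))
  expect_equal(unique(bin_for(f1$length_um, f1$width_um)), 3L)
  # mass in an aspect-ratio-infeasible bin is rejected
  expect_error(reconstruct_fibers(toy_matrix(25), sim_config(seed = 1)),
               "no aspect-ratio-feasible")
})

test_that("reconstructed fractions converge to the matrix fractions", {
  m <- load_size_matrix("amosite/dimensional_db")
  f <- reconstruct_fibers(m, sim_config(n_particles = 50000, seed = 9))
  dev <- abs(fractions(f) - matrix_fractions(m))
  expect_lt(max(dev), 0.01)
})

test_that("every simulated dataset is reproducible and filter-closed", {
  cfg <- sim_config(n_particles = 400, seed = 42)
  sets <- simulate_all(cfg)
  expect_named(sets, paste(fixture_combos()$mineral,
                           fixture_combos()$medium, sep = "/"))
  sets2 <- simulate_all(cfg)
  for (id in names(sets)) {
    expect_identical(sets[[id]]$length_um, sets2[[id]]$length_um)
    # filter closure: the global filter removes nothing
    expect_equal(nrow(filter_fibers(sets[[id]])), nrow(sets[[id]]))
  }
  # byte-for-byte identical CSV export under the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_fiber_csv(sets[["amosite/lung"]], p1)
  write_fiber_csv(sets2[["amosite/lung"]], p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reconstructed crocidolite lung lengths have their median in the 2-3 um bin", {
  # cumulative printed length-bin frequencies place the 50th percentile there
  f <- reconstruct_fibers(load_size_matrix("crocidolite/lung"),
                          sim_config(n_particles = 2000, seed = 31))
  expect_gt(median(f$length_um), 2)
  expect_lt(median(f$length_um), 3)
})
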