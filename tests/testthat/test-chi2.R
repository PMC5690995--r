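noise_free <- function(rho, msf, ...) {
  generate_slab_measurements(beam_model(rho, msf),
                             noise = noise_spec(0, seed = 1), ...)
}

test_that("chi-squared is zero at identity and matches hand computation", {
  x <- c(-0.3, -0.9, -1.5)
  expect_identical(chi2_stat(x, x), 0)
  expect_equal(chi2_stat(c(-0.4, -0.9, -1.5), x), 0.01 / 0.3)
  expect_error(chi2_stat(c(-1, -2), c(-1)), "equal length")
  expect_error(chi2_stat(c(-1, 0.5), c(-1, 0)), "0")
})

test_that("chi-squared agrees with a loop-based oracle on random vectors", {
  set.seed(42)
  for (i in 1:100) {
    x <- -runif(3, 0.05, 2)
    p <- x + rnorm(3, 0, 0.1)
    expect_equal(chi2_stat(p, x), chi2_loop(p, x), tolerance = 1e-12)
  }
})

test_that("an MSF sweep recovers on-grid truth with zero objective", {
  meas <- noise_free(8.3, 0.2)
  s <- sweep_chi2(meas, "msf", seq(0, 0.5, 0.05),
                  beam_model(rho = 8.3, msf = 0))
  expect_identical(s$argmin, 0.2)
  expect_equal(s$min_objective, 0)
  expect_true(all(s$objective >= 0))
})

test_that("sweep argmin equals exhaustive evaluation at an off-truth fixed density", {
  meas <- noise_free(8.3, 0.2)
  grid <- seq(0, 0.5, 0.05)
  s <- sweep_chi2(meas, "msf", grid, beam_model(rho = 8.498, msf = 0))
  recs <- meas[meas$thickness_cm > 0, ]
  manual <- vapply(grid, function(v) {
    chi2_loop(log((1 + v * recs$thickness_cm) *
                    exp(-0.037 * 8.498 * recs$thickness_cm)),
              recs$log_ratio)
  }, numeric(1))
  expect_equal(s$objective, manual, tolerance = 1e-12)
  expect_identical(s$argmin, grid[which.min(manual)])
})

test_that("a 3-point grid straddling the optimum picks the interior point", {
  meas <- noise_free(8.3, 0.2)
  s <- sweep_chi2(meas, "msf", c(0.1, 0.2, 0.3),
                  beam_model(rho = 8.3, msf = 0))
  expect_identical(s$argmin, 0.2)
})

test_that("min-of-minima curve recovers on-grid truth exactly and tracks the 2D surface", {
  meas <- noise_free(7.8, 0.1)
  sub <- meas[meas$depth_cm == 10 & meas$field_size_cm == 10, ]
  curve <- min_chi2_curve(sub, default_rho_grid(), default_msf_grid())
  i <- which.min(curve$chi2_min)
  expect_identical(curve$rho[i], 7.8)
  expect_identical(curve$msf_at_min[i], 0.1)
  expect_equal(curve$chi2_min[i], 0)
  # the curve is the row-wise min of the exhaustive 2D surface
  surf <- chi2_surface(sub, default_rho_grid(), default_msf_grid())
  expect_equal(curve$chi2_min, unname(apply(surf, 1, min)), tolerance = 1e-10)
})

test_that("truth off-grid in one parameter is recovered to within one grid step", {
  # The two parameters compensate along a chi2 ridge, so quantization error
  # in one coordinate leaks (amplified) into the other; the one-step bound
  # holds per coordinate when the companion parameter is on-grid.
  meas_r <- noise_free(7.85, 0.1) # rho half a step off, msf on-grid
  sub_r <- meas_r[meas_r$depth_cm == 10 & meas_r$field_size_cm == 10, ]
  curve_r <- min_chi2_curve(sub_r)
  i <- which.min(curve_r$chi2_min)
  expect_lte(abs(curve_r$rho[i] - 7.85), 0.1)

  meas_m <- noise_free(7.8, 0.125) # msf half a step off, rho on-grid
  sub_m <- meas_m[meas_m$depth_cm == 10 & meas_m$field_size_cm == 10, ]
  curve_m <- min_chi2_curve(sub_m)
  j <- which.min(curve_m$chi2_min)
  expect_lte(abs(curve_m$msf_at_min[j] - 0.125), 0.05)
})

test_that("grid refinement never worsens noise-free parameter recovery", {
  meas <- noise_free(7.85, 0.125)
  err <- function(rho_by, msf_by) {
    fit <- commission_slabs(meas,
                            rho_grid = round(seq(7, 9, rho_by), 9),
                            msf_grid = round(seq(0, 0.5, msf_by), 9))
    c(abs(fit$rho_overall - 7.85), abs(fit$msf_final - 0.125))
  }
  coarse <- err(0.1, 0.05)
  fine <- err(0.05, 0.025)
  expect_lte(fine[1], coarse[1])
  expect_lte(fine[2], coarse[2])
})

test_that("aggregation averages per-condition optima and is permutation invariant", {
  # single curve: aggregate equals that curve's argmin
  meas <- noise_free(7.8, 0.1)
  sub <- meas[meas$depth_cm == 10 & meas$field_size_cm == 10, ]
  cv <- min_chi2_curve(sub)
  attr(cv, "depth_cm") <- 10
  attr(cv, "field_size_cm") <- 10
  agg1 <- aggregate_optimum(list(cv))
  expect_identical(agg1$rho_overall, 7.8)
  # hand arithmetic on synthetic curves
  mk <- function(rho_opt, depth) {
    cv <- data.frame(rho = c(rho_opt - 0.1, rho_opt, rho_opt + 0.1),
                     chi2_min = c(1, 0, 1), msf_at_min = 0.1)
    attr(cv, "depth_cm") <- depth
    attr(cv, "field_size_cm") <- 10
    cv
  }
  curves <- list(mk(7.9, 2.5), mk(7.9, 10), mk(7.9, 20),
                 mk(7.3, 10), mk(8.1, 20))
  agg <- aggregate_optimum(curves)
  expect_equal(agg$rho_overall, mean(c(7.9, 7.9, 7.9, 7.3, 8.1)))
  expect_equal(
    agg$rho_by_depth$rho_opt[agg$rho_by_depth$depth_cm == 10],
    mean(c(7.9, 7.3))
  )
  # full fit is invariant to record order
  fit_a <- commission_slabs(meas)
  shuffled <- meas[sample(nrow(meas)), ]
  fit_b <- commission_slabs(slab_measurements(shuffled))
  expect_identical(fit_a$rho_overall, fit_b$rho_overall)
  expect_identical(fit_a$msf_final, fit_b$msf_final)
  expect_equal(sort(fit_a$condition_optima$rho_opt),
               sort(fit_b$condition_optima$rho_opt))
})

test_that("nine-condition aggregate recovers on-grid truth from a single model", {
  fit <- commission_slabs(noise_free(7.8, 0.1))
  expect_equal(nrow(fit$condition_optima), 9L)
  expect_identical(fit$rho_overall, 7.8)
  expect_identical(fit$msf_final, 0.1)
  expect_equal(fit$chi2_min, 0)
})

test_that("argmin ties break toward the smaller parameter value", {
  # exactly representable setup: kappa = 0.25, t = 2, msf = 0 gives
  # predictions -0.5 * rho; with rho grid {2, 3} the predictions are
  # exactly -1.0 and -1.5, and measured -1.25 ties the two objectives
  # bitwise, so the tie-break rule is observable
  meas <- slab_measurements(data.frame(
    thickness_cm = 2, depth_cm = 10, field_size_cm = 10, log_ratio = -1.25
  ))
  s <- sweep_chi2(meas, "rho", c(2, 3),
                  beam_model(rho = 1, msf = 0, kappa = 0.25))
  expect_identical(s$objective[1], s$objective[2])
  expect_identical(s$argmin, 2)
})

test_that("measurement-set validation catches bad records", {
  df <- data.frame(thickness_cm = c(1, 1), depth_cm = 10,
                   field_size_cm = 10, log_ratio = c(-0.3, -0.31))
  expect_error(slab_measurements(df), "duplicate")
  df2 <- data.frame(thickness_cm = 1, depth_cm = 10,
                    field_size_cm = 10, log_ratio = 0.2)
  expect_error(slab_measurements(df2), "negative")
})
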