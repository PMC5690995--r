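truth <- beam_model(7.8, 0.1)

test_that("identical planes give gamma 0 everywhere at any criteria", {
  f <- make_field(truth, seed = 11)
  for (cr in default_criteria_levels()) {
    g <- gamma_index(f$measured, f$measured, cr)
    expect_equal(max(g$gamma, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_identical(g$n_failing, 0L)
    expect_equal(g$pass_rate, 100)
    expect_true(g$n_evaluated <= length(f$measured$values))
  }
})

test_that("local and global gamma are invariant under joint rescaling of both planes", {
  f <- make_field(truth, model = beam_model(8.2, 0.1), seed = 12)
  scale_plane <- function(p, k) dose_plane(p$values * k, p$spacing_mm, p$origin_mm)
  for (norm in c("local", "global")) {
    cr <- gamma_criteria(2, 2, normalization = norm)
    g1 <- gamma_index(f$measured, f$calculated, cr)
    g2 <- gamma_index(scale_plane(f$measured, 3.7),
                      scale_plane(f$calculated, 3.7), cr)
    expect_equal(g1$gamma, g2$gamma, tolerance = 1e-9)
    expect_identical(g1$n_failing, g2$n_failing)
  }
})

test_that("interpolation routes agree: scalar oracle, vectorized oracle, package", {
  set.seed(55)
  p <- dose_plane(matrix(runif(100, 0, 2), 10, 10), c(6, 5), c(-10, 3))
  x <- runif(200, -12, 45)
  y <- runif(200, 1, 50)
  ref <- vapply(seq_along(x), function(k) {
    bilinear_scalar(p$values, p$spacing_mm, p$origin_mm, x[k], y[k])
  }, numeric(1))
  vec <- bilinear_many(p$values, p$spacing_mm, p$origin_mm, x, y)
  pkg <- interp_bilinear(p, x, y)
  expect_identical(is.na(ref), is.na(vec))
  expect_equal(vec, ref, tolerance = 1e-14)
  expect_equal(pkg, ref, tolerance = 1e-14)
})

test_that("the compiled search matches the brute-force oracle on random plane pairs", {
  # 15 x 15 planes, both gamma routes share only the candidate-set definition
  set.seed(99)
  for (case in 1:5) {
    model <- beam_model(runif(1, 7.4, 8.6), runif(1, 0, 0.3))
    f <- make_field(truth, model = model, seed = 100 + case,
                    field_size_cm = 9.8, comp_spacing_mm = 7,
                    relative_sd = 0.01)
    g <- gamma_index(f$measured, f$calculated, gamma_criteria(2, 2))
    ref <- gamma_brute(f$measured, f$calculated, dose_diff = 2, dta = 2)
    expect_identical(is.na(g$gamma), is.na(ref))
    expect_lt(max(abs(g$gamma - ref), na.rm = TRUE), 1e-6)
  }
})

test_that("search-radius truncation leaves gamma below the cap untouched", {
  f <- make_field(truth, model = beam_model(8.6, 0.1), seed = 13)
  cr <- gamma_criteria(2, 2)
  g_trunc <- gamma_index(f$measured, f$calculated, cr,
                         search_radius_factor = 2)
  g_wide <- gamma_index(f$measured, f$calculated, cr,
                        search_radius_factor = 6)
  below <- !is.na(g_wide$gamma) & g_wide$gamma < 2
  expect_true(any(below))
  expect_equal(g_trunc$gamma[below], g_wide$gamma[below], tolerance = 1e-12)
})

test_that("refining the search step can only decrease gamma", {
  f <- make_field(truth, model = beam_model(8.3, 0.15), seed = 14)
  cr <- gamma_criteria(2, 2)
  g_coarse <- gamma_index(f$measured, f$calculated, cr, step_fraction = 0.1)
  g_fine <- gamma_index(f$measured, f$calculated, cr, step_fraction = 0.05)
  ok <- !is.na(g_coarse$gamma)
  expect_true(all(g_fine$gamma[ok] <= g_coarse$gamma[ok] + 1e-12))
})

test_that("loosening criteria never increases any gamma value or failing count", {
  f <- make_field(truth, model = beam_model(8.4, 0.1), seed = 15,
                  relative_sd = 0.01)
  levels <- default_criteria_levels() # 3/3, 2/2, 1.5/1.5, 1/1
  res <- lapply(levels, function(cr) gamma_index(f$measured, f$calculated, cr))
  fails <- vapply(res, `[[`, numeric(1), "n_failing")
  expect_true(all(diff(fails) >= 0)) # stricter criteria, more failures
  expect_true(all(vapply(res, function(r) all(r$gamma >= 0, na.rm = TRUE),
                         logical(1))))
})

test_that("the low-dose threshold excludes out-of-field points and can empty the plane", {
  vals <- matrix(c(0.02, 0.02, 0.02, 1, 1, 0.02, 1, 1, 0.02), 3, 3)
  m <- dose_plane(vals, 10)
  g <- gamma_index(m, m, gamma_criteria(2, 2, low_dose_threshold = 10))
  expect_identical(g$n_evaluated, sum(vals >= 0.1))
  expect_true(all(is.na(g$gamma[vals < 0.1])))
  # measured plane displaced outside the calculated extent -> usage error
  far <- dose_plane(vals, 10, origin_mm = c(1000, 1000))
  expect_error(gamma_index(far, m, gamma_criteria(2, 2)), "overlap")
})

test_that("count_failing totals per-field failures", {
  f <- make_field(truth, seed = 16)
  all_pass <- gamma_index(f$measured, f$measured, gamma_criteria(2, 2))
  expect_identical(count_failing(rep(list(all_pass), 7)), 0)
  fake <- function(n) structure(list(n_failing = n), class = "gamma_result")
  expect_identical(count_failing(list(fake(3), fake(0), fake(2))), 5)
  expect_error(count_failing(list()), "at least one")
})

test_that("failing-vs-parameter recovers on-grid truth and matches a naive recomputation", {
  fields <- lapply(1:3, function(k) {
    f <- make_field(truth, seed = 20 + k)
    list(comp = f$comp, measured = f$measured)
  })
  grid <- round(seq(7.6, 8.0, 0.1), 6)
  levels <- list(gamma_criteria(2, 2), gamma_criteria(1, 1))
  tab <- failing_vs_parameter(fields, "rho", grid, fixed = 0.1,
                              criteria_levels = levels)
  # zero failures at truth for every level; looser criteria have broad flat
  # minima (ties resolve to the smallest value), the strictest level
  # discriminates and lands on the truth
  expect_true(all(tab$n_failing[tab$value == 7.8] == 0))
  am <- attr(tab, "argmin")
  expect_true(all(am$n_failing == 0))
  expect_identical(am$value[am$criteria == "1%/1mm"], 7.8)
  # naive recomputation: loop fields x grid x criteria
  for (lv in seq_along(levels)) {
    for (g in grid) {
      model <- beam_model(g, 0.1)
      total <- 0
      for (f in fields) {
        calc <- simulate_dose_plane(f$comp, model)
        total <- total + gamma_index(f$measured, calc, levels[[lv]])$n_failing
      }
      got <- tab$n_failing[tab$criteria == criteria_label(levels[[lv]]) &
                             tab$value == g]
      expect_identical(got, total)
    }
  }
})

test_that("two-pass gamma commissioning returns the truth on noise-free fields", {
  fields <- lapply(1:3, function(k) {
    f <- make_field(truth, seed = 30 + k)
    list(comp = f$comp, measured = f$measured)
  })
  res <- commission_gamma(fields,
                          rho_grid = round(seq(7.6, 8.0, 0.1), 6),
                          msf_grid = round(seq(0, 0.2, 0.05), 6),
                          msf_init = 0.1,
                          criteria_levels = list(gamma_criteria(2, 2),
                                                 gamma_criteria(1, 1)))
  expect_identical(res$rho_opt, 7.8)
  expect_identical(res$msf_opt, 0.1)
})
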