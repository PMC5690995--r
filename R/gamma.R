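#' Gamma-index acceptance criteria
#'
#' Stringency settings for the gamma comparison of a measured and a
#' calculated dose plane: percent dose difference, distance to agreement
#' (DTA), a low-dose threshold excluding detectors outside the field, and
#' the dose-difference normalization.
#'
#' @param dose_diff Dose-difference tolerance, percent (> 0).
#' @param dta Distance-to-agreement tolerance, mm (> 0).
#' @param low_dose_threshold Percent of the measured-plane maximum below
#'   which points are excluded from evaluation (default 10, the value used
#'   to drop diodes outside an IMRT field); in `[0, 100)`.
#' @param normalization `"local"` (percent difference relative to the
#'   measured dose at the reference point; the default) or `"global"`
#'   (the "Van Dyk" convention, relative to the measured-plane maximum).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff, dta, low_dose_threshold = 10,
                           normalization = c("local", "global")) {
  check_number(dose_diff, "dose_diff", lower = 0, strict_lower = TRUE)
  check_number(dta, "dta", lower = 0, strict_lower = TRUE)
  check_number(low_dose_threshold, "low_dose_threshold",
               lower = 0, upper = 100, strict_upper = TRUE)
  normalization <- match.arg(normalization)
  structure(
    list(dose_diff = dose_diff, dta = dta,
         low_dose_threshold = low_dose_threshold,
         normalization = normalization),
    class = "gamma_criteria"
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %s (threshold %g%%, %s normalization)\n",
              criteria_label(x), x$low_dose_threshold, x$normalization))
  invisible(x)
}

#' @rdname gamma_criteria
#' @param criteria A `gamma_criteria` object.
#' @export
criteria_label <- function(criteria) {
  sprintf("%g%%/%gmm", criteria$dose_diff, criteria$dta)
}

#' Default ladder of gamma criteria
#'
#' The four stringency levels used when optimizing against diode-array
#' measurements: 3%/3mm (the common institutional setting, typically flat
#' in the commissioning parameters), then 2%/2mm, 1.5%/1.5mm and 1%/1mm,
#' which discriminate more sharply.
#'
#' @inheritParams gamma_criteria
#' @return List of [gamma_criteria()] objects, loosest first.
#' @export
default_criteria_levels <- function(low_dose_threshold = 10,
                                    normalization = "local") {
  lapply(c(3, 2, 1.5, 1), function(v) {
    gamma_criteria(v, v, low_dose_threshold, normalization)
  })
}

# Candidate offsets: a disc of radius `radius_factor * dta` sampled at
# step `step_fraction * dta`, always containing the (0, 0) offset.
gamma_offsets <- function(dta, step_fraction, radius_factor) {
  step <- step_fraction * dta
  radius <- radius_factor * dta
  n <- floor(radius / step + 1e-9)
  off <- step * (-n:n)
  grid <- expand.grid(ox = off, oy = off)
  d2 <- grid$ox^2 + grid$oy^2
  keep <- d2 <= radius^2 * (1 + 1e-12)
  list(ox = grid$ox[keep], oy = grid$oy[keep], d2 = d2[keep])
}

#' 2D gamma-index comparison of a measured and a calculated dose plane
#'
#' For every evaluated point of the measured (reference) plane, computes
#' the Low-style gamma index
#' \deqn{\gamma(r_m) = \min_{r_c} \sqrt{\frac{|r_c - r_m|^2}{\mathrm{DTA}^2}
#'   + \frac{\Delta(r_m, r_c)^2}{\Delta D^2}},}
#' minimizing over candidate positions of the calculated plane within a
#' disc of radius `search_radius_factor * dta` around the reference point,
#' sampled every `step_fraction * dta` mm with bilinear interpolation.
#' \eqn{\Delta} is the percent dose difference, normalized locally (to the
#' measured dose at the reference point) or globally (to the measured-plane
#' maximum). Points below the low-dose threshold are excluded. A point
#' fails if its gamma exceeds 1.
#'
#' The truncated disc search is exact for any gamma value below
#' `search_radius_factor`: a candidate outside the disc contributes a
#' distance penalty alone exceeding that bound.
#'
#' @param measured Reference [dose_plane()] (e.g. diode-array measurement).
#' @param calculated [dose_plane()] to search (e.g. TPS calculation); may
#'   have different spacing. Every evaluated reference position must lie
#'   within its extent.
#' @param criteria A [gamma_criteria()].
#' @param step_fraction Search-grid step as a fraction of DTA (default 0.1).
#' @param search_radius_factor Search radius in units of DTA (default 3).
#' @param gamma_cap Optional cap applied to reported gamma values
#'   (default `Inf`, i.e. no cap).
#' @return A `gamma_result`: `gamma` (matrix, `NA` at excluded points),
#'   `n_evaluated`, `n_failing`, `pass_rate` (percent), `criteria`.
#' @export
gamma_index <- function(measured, calculated, criteria,
                        step_fraction = 0.1, search_radius_factor = 3,
                        gamma_cap = Inf) {
  if (!is_dose_plane(measured) || !is_dose_plane(calculated)) {
    stop_usage("`measured` and `calculated` must be dose_plane objects")
  }
  if (!inherits(criteria, "gamma_criteria")) {
    stop_usage("`criteria` must be a gamma_criteria object")
  }
  check_number(step_fraction, "step_fraction", lower = 0, strict_lower = TRUE)
  check_number(search_radius_factor, "search_radius_factor",
               lower = 0, strict_lower = TRUE)
  m <- measured$values
  mmax <- max(m)
  if (!(mmax > 0)) stop_usage("measured plane maximum must be > 0")
  thr <- criteria$low_dose_threshold / 100 * mmax
  eval_mask <- m >= thr
  if (criteria$normalization == "local") eval_mask <- eval_mask & m > 0
  if (!any(eval_mask)) {
    stop_usage("no points to evaluate: all measured doses below threshold")
  }
  ax <- plane_axes(measured)
  px_all <- ax$x[col(m)]
  py_all <- ax$y[row(m)]
  px <- px_all[eval_mask]
  py <- py_all[eval_mask]
  ext <- plane_extent(calculated)
  tol <- 1e-9
  if (any(px < ext[1] - tol | px > ext[2] + tol |
          py < ext[3] - tol | py > ext[4] + tol)) {
    stop_usage(
      "planes do not overlap: evaluated measured point(s) lie outside ",
      "the calculated plane"
    )
  }
  mdose <- m[eval_mask]
  denom <- if (criteria$normalization == "local") mdose else mmax
  offs <- gamma_offsets(criteria$dta, step_fraction, search_radius_factor)
  g2min <- gamma_min_sq(
    calculated$values, calculated$origin_mm[1], calculated$origin_mm[2],
    calculated$spacing_mm[1], calculated$spacing_mm[2],
    px, py, mdose, denom,
    criteria$dta, criteria$dose_diff,
    offs$ox, offs$oy, offs$d2
  )
  gamma_vals <- pmin(sqrt(g2min), gamma_cap)
  gmap <- matrix(NA_real_, nrow(m), ncol(m))
  gmap[eval_mask] <- gamma_vals
  n_evaluated <- length(gamma_vals)
  n_failing <- sum(gamma_vals > 1)
  structure(
    list(
      gamma = gmap,
      n_evaluated = n_evaluated,
      n_failing = n_failing,
      pass_rate = 100 * (1 - n_failing / n_evaluated),
      criteria = criteria
    ),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %s: %d evaluated, %d failing (pass rate %.1f%%)\n",
    criteria_label(x$criteria), x$n_evaluated, x$n_failing, x$pass_rate
  ))
  invisible(x)
}

#' Total failing points across gamma results
#'
#' Sums the failing-point counts of several per-field gamma results, the
#' figure of merit used when optimizing model parameters against a
#' multi-field diode-array measurement set.
#'
#' @param results List of `gamma_result` objects (one per field).
#' @return Integer total of failing points.
#' @export
count_failing <- function(results) {
  if (length(results) < 1L) stop_usage("need at least one gamma_result")
  ok <- vapply(results, inherits, logical(1), what = "gamma_result")
  if (!all(ok)) stop_usage("all elements must be gamma_result objects")
  sum(vapply(results, function(r) as.numeric(r$n_failing), numeric(1)))
}

#' Failing points as a function of a commissioning parameter
#'
#' For each value of a grid over one commissioning parameter (holding the
#' other fixed), recomputes every field's calculated dose plane with the
#' compensator model, runs the gamma comparison against the measured plane
#' at each criteria level, and totals the failing points across fields.
#' The per-criteria argmin (smallest value on ties) is the commissioned
#' parameter value at that stringency.
#'
#' @param fields List of fields, each a list with elements `comp` (a
#'   [compensator_map()]) and `measured` (the measured [dose_plane()]).
#' @param parameter `"rho"` or `"msf"`: the parameter swept.
#' @param grid Strictly increasing grid of parameter values.
#' @param fixed Value of the other parameter, held constant.
#' @param criteria_levels List of [gamma_criteria()] (default the
#'   3/2/1.5/1 ladder).
#' @param kappa Mass attenuation coefficient, cm^2/g.
#' @param ... Passed to [gamma_index()] (search controls).
#' @return A data frame (class `failing_table`) with columns `criteria`,
#'   `parameter`, `value`, `n_failing`; attribute `argmin` holds a data
#'   frame of per-criteria optimal values.
#' @export
failing_vs_parameter <- function(fields, parameter = c("rho", "msf"), grid,
                                 fixed,
                                 criteria_levels = default_criteria_levels(),
                                 kappa = 0.037, ...) {
  parameter <- match.arg(parameter)
  grid <- check_grid(grid, "grid", min_length = 1L)
  if (length(fields) < 1L) stop_usage("need at least one field")
  check_number(fixed, "fixed")
  labels <- vapply(criteria_levels, criteria_label, character(1))
  rows <- list()
  for (g in grid) {
    model <- if (parameter == "rho") {
      beam_model(rho = g, msf = fixed, kappa = kappa)
    } else {
      beam_model(rho = fixed, msf = g, kappa = kappa)
    }
    calc <- lapply(fields, function(f) simulate_dose_plane(f$comp, model))
    for (ci in seq_along(criteria_levels)) {
      res <- mapply(function(f, cp) {
        gamma_index(f$measured, cp, criteria_levels[[ci]], ...)
      }, fields, calc, SIMPLIFY = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        criteria = labels[ci], parameter = parameter, value = g,
        n_failing = count_failing(res)
      )
    }
  }
  out <- do.call(rbind, rows)
  argmin <- do.call(rbind, lapply(labels, function(lb) {
    sub <- out[out$criteria == lb, ]
    i <- which.min(sub$n_failing) # first = smallest parameter value on ties
    data.frame(criteria = lb, value = sub$value[i],
               n_failing = sub$n_failing[i])
  }))
  attr(out, "argmin") <- argmin
  class(out) <- c("failing_table", "data.frame")
  out
}

#' Two-pass gamma commissioning of (rho, MSF)
#'
#' Mirrors the diode-array workflow: sweep density with MSF held at an
#' initial value, take the argmin at the strictest criteria level as the
#' commissioned density, then sweep MSF at that density. The strictest
#' level is used for selection because looser criteria (3%/3mm) are nearly
#' flat in the parameters.
#'
#' @inheritParams failing_vs_parameter
#' @param rho_grid,msf_grid Sweep grids for the two passes.
#' @param msf_init MSF held fixed during the density pass (default
#'   0.1 cm^-1).
#' @return List with `rho_table`, `msf_table` (both [failing_vs_parameter()]
#'   outputs), `rho_opt`, `msf_opt`.
#' @export
commission_gamma <- function(fields, rho_grid, msf_grid, msf_init = 0.1,
                             criteria_levels = default_criteria_levels(),
                             kappa = 0.037, ...) {
  rho_table <- failing_vs_parameter(fields, "rho", rho_grid, fixed = msf_init,
                                    criteria_levels = criteria_levels,
                                    kappa = kappa, ...)
  strict <- which.min(vapply(criteria_levels, `[[`, numeric(1), "dose_diff"))
  strict_label <- criteria_label(criteria_levels[[strict]])
  am_rho <- attr(rho_table, "argmin")
  rho_opt <- am_rho$value[am_rho$criteria == strict_label]
  msf_table <- failing_vs_parameter(fields, "msf", msf_grid, fixed = rho_opt,
                                    criteria_levels = criteria_levels,
                                    kappa = kappa, ...)
  am_msf <- attr(msf_table, "argmin")
  msf_opt <- am_msf$value[am_msf$criteria == strict_label]
  list(rho_table = rho_table, msf_table = msf_table,
       rho_opt = rho_opt, msf_opt = msf_opt)
}
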