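#' Slab measurement set
#'
#' Validates and classes a table of slab attenuation measurements. Each
#' record is a slab geometry plus the measured log attenuation ratio
#' `log_ratio` = ln(reading with brass / open-field reading). Zero-thickness
#' rows (the open-field normalization itself, log ratio 0) are allowed;
#' they are excluded from every chi-squared sum because the relative
#' objective is undefined at a measured value of 0.
#'
#' @param records Data frame with columns `thickness_cm`, `depth_cm`,
#'   `field_size_cm`, `log_ratio`.
#' @param provenance Character tag recording where the data came from
#'   (file name or synthetic-seed description).
#' @return The records, classed `slab_measurements`, with a `provenance`
#'   attribute.
#' @export
slab_measurements <- function(records, provenance = "unspecified") {
  need <- c("thickness_cm", "depth_cm", "field_size_cm", "log_ratio")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_usage(
      "`records` must be a data frame with columns ",
      paste(need, collapse = ", ")
    )
  }
  if (nrow(records) == 0L) stop_usage("`records` must be non-empty")
  for (col in need) {
    if (!is.numeric(records[[col]]) || anyNA(records[[col]]) ||
        any(!is.finite(records[[col]]))) {
      stop_usage(sprintf("column `%s` must be finite numeric", col))
    }
  }
  if (any(records$thickness_cm < 0)) stop_usage("thickness_cm must be >= 0")
  pos <- records$thickness_cm > 0
  if (any(records$log_ratio[pos] >= 0)) {
    stop_usage("log_ratio must be negative for positive thickness")
  }
  key <- paste(records$thickness_cm, records$depth_cm,
               records$field_size_cm)
  if (anyDuplicated(key)) {
    stop_usage(
      "duplicate (thickness, depth, field size) record(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    )
  }
  structure(
    as.data.frame(records)[need],
    provenance = provenance,
    class = c("slab_measurements", "data.frame")
  )
}

is_slab_measurements <- function(x) inherits(x, "slab_measurements")

# Records that enter the chi2 sum: positive thickness only.
chi2_records <- function(measured) {
  measured[measured$thickness_cm > 0, , drop = FALSE]
}

#' Relative chi-squared misfit between predicted and measured log ratios
#'
#' \deqn{\chi^2 = \sum_i (p_i - x_i)^2 / |x_i|}
#' with \eqn{p_i} the model-predicted and \eqn{x_i} the measured log
#' attenuation ratios. The denominator is taken in absolute value: the
#' measured log ratios are negative, and the misfit must be non-negative
#' to serve as an objective. Zero-thickness records (x = 0) must be
#' removed before calling.
#'
#' @param predicted,measured Equal-length numeric vectors; no measured
#'   element may be 0.
#' @return Non-negative scalar; 0 iff `predicted == measured` elementwise.
#' @export
chi2_stat <- function(predicted, measured) {
  if (!is.numeric(predicted) || !is.numeric(measured)) {
    stop_usage("`predicted` and `measured` must be numeric")
  }
  if (length(predicted) != length(measured)) {
    stop_usage("`predicted` and `measured` must have equal length")
  }
  if (length(measured) < 1L) stop_usage("vectors must be non-empty")
  if (any(measured == 0)) {
    stop_usage(
      "`measured` contains 0; exclude zero-thickness (open-field) records"
    )
  }
  sum((predicted - measured)^2 / abs(measured))
}

#' Default commissioning grids
#'
#' Density grid 7.0–9.0 g/cm^3 in steps of 0.1 and MSF grid 0–0.5 cm^-1 in
#' steps of 0.05 with 0.0001 cm^-1 added (the near-zero value used when
#' demonstrating log-linearity). The grids bracket all physically relevant
#' values: nominal brass density 8.5 g/cm^3 and commissioned effective
#' densities in the high 7s. Values are rounded so nominal grid points
#' (e.g. 7.8) are exact.
#'
#' @return Numeric vector, strictly increasing.
#' @export
default_rho_grid <- function() round(seq(7.0, 9.0, by = 0.1), 6)

#' @rdname default_rho_grid
#' @export
default_msf_grid <- function() {
  sort(unique(c(0.0001, round(seq(0, 0.5, by = 0.05), 6))))
}

model_with <- function(model, param, value) {
  args <- list(rho = model$rho, msf = model$msf, kappa = model$kappa)
  args[[param]] <- value
  do.call(beam_model, args)
}

#' One-parameter chi-squared sweep
#'
#' Holds one commissioning parameter fixed (taken from `model`) and
#' evaluates the chi-squared misfit against the measured slab set at each
#' value of a grid over the other, mirroring the manual sweeps used when
#' commissioning a planning system that offers no built-in optimizer.
#'
#' @param measured A [slab_measurements()] set.
#' @param param `"rho"` or `"msf"`: the parameter swept along `grid`.
#' @param grid Strictly increasing numeric grid of length >= 1 (>= 3 for a
#'   meaningful sweep).
#' @param model A [beam_model()] supplying the fixed parameter and kappa.
#' @return A `sweep_result`: list with `parameter`, `grid`, `objective`,
#'   `argmin` (grid value at the smallest objective; ties broken toward
#'   the smallest parameter value) and `min_objective`.
#' @export
sweep_chi2 <- function(measured, param = c("msf", "rho"), grid, model) {
  param <- match.arg(param)
  if (!is_slab_measurements(measured)) {
    measured <- slab_measurements(measured)
  }
  grid <- check_grid(grid, "grid", min_length = 1L)
  recs <- chi2_records(measured)
  if (nrow(recs) == 0L) {
    stop_usage("no positive-thickness records to fit")
  }
  objective <- vapply(grid, function(v) {
    chi2_stat(
      predicted_log_ratios(recs, model_with(model, param, v)),
      recs$log_ratio
    )
  }, numeric(1))
  i <- which.min(objective) # first minimum = smallest grid value on ties
  structure(
    list(
      parameter = param,
      grid = grid,
      objective = objective,
      argmin = grid[i],
      min_objective = objective[i]
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %s over [%g, %g] (%d points): argmin %s = %g, min chi2 = %g\n",
    x$parameter, min(x$grid), max(x$grid), length(x$grid),
    x$parameter, x$argmin, x$min_objective
  ))
  invisible(x)
}

#' Exhaustive 2D chi-squared surface
#'
#' Cross-check mode: evaluates the chi-squared objective on the full
#' (rho x msf) grid. The sequential sweep machinery must agree with
#' reductions of this surface.
#'
#' @inheritParams sweep_chi2
#' @param rho_grid,msf_grid Strictly increasing grids.
#' @param kappa Mass attenuation coefficient, cm^2/g.
#' @return Matrix of chi-squared values, rows indexed by `rho_grid`,
#'   columns by `msf_grid`, with dimnames.
#' @export
chi2_surface <- function(measured, rho_grid = default_rho_grid(),
                         msf_grid = default_msf_grid(), kappa = 0.037) {
  rho_grid <- check_grid(rho_grid, "rho_grid")
  msf_grid <- check_grid(msf_grid, "msf_grid")
  recs <- chi2_records(measured)
  if (nrow(recs) == 0L) stop_usage("no positive-thickness records to fit")
  t_cm <- recs$thickness_cm
  x <- recs$log_ratio
  out <- matrix(NA_real_, length(rho_grid), length(msf_grid),
                dimnames = list(format(rho_grid), format(msf_grid)))
  for (i in seq_along(rho_grid)) {
    for (j in seq_along(msf_grid)) {
      p <- log(1 + msf_grid[j] * t_cm) - kappa * rho_grid[i] * t_cm
      out[i, j] <- sum((p - x)^2 / abs(x))
    }
  }
  out
}

#' Minimum-of-minima chi-squared curve over density
#'
#' For each density on `rho_grid`, sweeps MSF over `msf_grid` and records
#' the minimum chi-squared. The argmin of the resulting curve is the
#' commissioned density for that measurement condition; the MSF at which
#' each row attains its minimum is carried along.
#'
#' @inheritParams chi2_surface
#' @return A data frame (class `min_chi2_curve`) with columns `rho`,
#'   `chi2_min`, `msf_at_min`.
#' @export
min_chi2_curve <- function(measured, rho_grid = default_rho_grid(),
                           msf_grid = default_msf_grid(), kappa = 0.037) {
  rho_grid <- check_grid(rho_grid, "rho_grid")
  msf_grid <- check_grid(msf_grid, "msf_grid")
  if (!is_slab_measurements(measured)) {
    measured <- slab_measurements(measured)
  }
  rows <- lapply(rho_grid, function(r) {
    s <- sweep_chi2(measured, "msf", msf_grid,
                    beam_model(rho = r, msf = 0, kappa = kappa))
    data.frame(rho = r, chi2_min = s$min_objective, msf_at_min = s$argmin)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("min_chi2_curve", "data.frame")
  out
}

curve_argmin <- function(curve) {
  i <- which.min(curve$chi2_min)
  list(rho = curve$rho[i], chi2_min = curve$chi2_min[i],
       msf_at_min = curve$msf_at_min[i])
}

#' Aggregate per-condition density optima into a commissioning result
#'
#' Takes one minimum-of-minima curve per measurement condition (depth,
#' field size), extracts each condition's optimal density, and aggregates
#' by unweighted arithmetic mean — overall and stratified by depth. If the
#' pooled measurement set is supplied, a final MSF sweep is run at the
#' aggregate density to commission the scatter factor.
#'
#' @param curves Named list of [min_chi2_curve()] data frames; each must
#'   carry `depth_cm` and `field_size_cm` attributes (as produced by
#'   [commission_slabs()]), or be accompanied by parseable names
#'   `"d<depth>_fs<fs>"`.
#' @param measured Optional pooled [slab_measurements()] for the final MSF
#'   sweep.
#' @param msf_grid Grid for the final MSF sweep.
#' @param kappa Mass attenuation coefficient, cm^2/g.
#' @return A `commissioning_result` list: `condition_optima` (data frame),
#'   `rho_by_depth`, `rho_overall`, `msf_sweep`, `msf_final`, `chi2_min`.
#' @export
aggregate_optimum <- function(curves, measured = NULL,
                              msf_grid = default_msf_grid(), kappa = 0.037) {
  if (length(curves) < 1L) stop_usage("need at least one curve")
  optima <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    am <- curve_argmin(cv)
    data.frame(
      depth_cm = attr(cv, "depth_cm") %||% NA_real_,
      field_size_cm = attr(cv, "field_size_cm") %||% NA_real_,
      rho_opt = am$rho,
      chi2_min = am$chi2_min,
      msf_at_min = am$msf_at_min
    )
  }))
  rho_overall <- mean(optima$rho_opt)
  rho_by_depth <- if (!anyNA(optima$depth_cm)) {
    stats::aggregate(rho_opt ~ depth_cm, data = optima, FUN = mean)
  } else {
    NULL
  }
  msf_sweep <- NULL
  msf_final <- NA_real_
  chi2_min <- min(optima$chi2_min)
  if (!is.null(measured)) {
    msf_sweep <- sweep_chi2(
      measured, "msf", msf_grid,
      beam_model(rho = rho_overall, msf = 0, kappa = kappa)
    )
    msf_final <- msf_sweep$argmin
    chi2_min <- msf_sweep$min_objective
  }
  structure(
    list(
      curves = curves,
      condition_optima = optima,
      rho_by_depth = rho_by_depth,
      rho_overall = rho_overall,
      msf_sweep = msf_sweep,
      msf_final = msf_final,
      chi2_min = chi2_min,
      kappa = kappa
    ),
    class = "commissioning_result"
  )
}

#' Commission the compensator model against slab measurements
#'
#' The full slab workflow: stratify the measurement set by condition
#' (depth, field size), compute each condition's minimum-of-minima
#' chi-squared curve over density, take the unweighted mean of the
#' per-condition optimal densities as the commissioned density, and run a
#' final MSF sweep (pooling all conditions) at that density to commission
#' the scatter factor.
#'
#' @inheritParams chi2_surface
#' @return A `commissioning_result`; see [aggregate_optimum()].
#' @examples
#' truth <- beam_model(rho = 7.8, msf = 0.1)
#' meas <- generate_slab_measurements(truth, noise = noise_spec(0, seed = 1))
#' fit <- commission_slabs(meas)
#' c(rho = fit$rho_overall, msf = fit$msf_final, chi2 = fit$chi2_min)
#' @export
commission_slabs <- function(measured, rho_grid = default_rho_grid(),
                             msf_grid = default_msf_grid(), kappa = 0.037) {
  if (!is_slab_measurements(measured)) {
    measured <- slab_measurements(measured)
  }
  cond <- interaction(measured$depth_cm, measured$field_size_cm, drop = TRUE)
  groups <- split(seq_len(nrow(measured)), cond)
  curves <- lapply(groups, function(idx) {
    sub <- measured[idx, , drop = FALSE]
    class(sub) <- c("slab_measurements", "data.frame")
    cv <- min_chi2_curve(sub, rho_grid, msf_grid, kappa)
    attr(cv, "depth_cm") <- sub$depth_cm[1]
    attr(cv, "field_size_cm") <- sub$field_size_cm[1]
    cv
  })
  names(curves) <- vapply(curves, function(cv) {
    sprintf("d%g_fs%g", attr(cv, "depth_cm"), attr(cv, "field_size_cm"))
  }, character(1))
  res <- aggregate_optimum(curves, measured = measured,
                           msf_grid = msf_grid, kappa = kappa)
  res$rho_grid <- rho_grid
  res$msf_grid <- msf_grid
  res$provenance <- attr(measured, "provenance")
  res
}

#' @export
print.commissioning_result <- function(x, ...) {
  cat("<commissioning_result>\n")
  cat(sprintf("  conditions: %d\n", nrow(x$condition_optima)))
  cat(sprintf("  per-condition rho optima: %s g/cm^3\n",
              paste(format(x$condition_optima$rho_opt), collapse = ", ")))
  cat(sprintf("  commissioned rho (mean): %g g/cm^3\n", x$rho_overall))
  if (!is.na(x$msf_final)) {
    cat(sprintf("  commissioned MSF: %g cm^-1 (chi2 = %g)\n",
                x$msf_final, x$chi2_min))
  }
  invisible(x)
}
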