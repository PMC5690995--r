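# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: scalar arithmetic and hand-rolled
# interpolation only.

# Loop-based chi-squared, one term at a time.
chi2_loop <- function(p, x) {
  total <- 0
  for (i in seq_along(p)) {
    total <- total + (p[i] - x[i])^2 / abs(x[i])
  }
  total
}

# Scalar bilinear interpolation written from the textbook definition
# (values matrix, rows = y, cols = x). Returns NA outside the grid.
bilinear_scalar <- function(values, spacing, origin, x, y) {
  nr <- nrow(values)
  nc <- ncol(values)
  gx <- (x - origin[1]) / spacing[1]
  gy <- (y - origin[2]) / spacing[2]
  tol <- 1e-9
  if (gx < -tol || gx > nc - 1 + tol || gy < -tol || gy > nr - 1 + tol) {
    return(NA_real_)
  }
  gx <- min(max(gx, 0), nc - 1)
  gy <- min(max(gy, 0), nr - 1)
  i0 <- min(floor(gx), nc - 2)
  j0 <- min(floor(gy), nr - 2)
  fx <- gx - i0
  fy <- gy - j0
  values[j0 + 1, i0 + 1] * (1 - fx) * (1 - fy) +
    values[j0 + 1, i0 + 2] * fx * (1 - fy) +
    values[j0 + 2, i0 + 1] * (1 - fx) * fy +
    values[j0 + 2, i0 + 2] * fx * fy
}

# Vectorized wrapper over the same textbook formula (same clamping and
# tolerance rules as bilinear_scalar, checked against it in the suite).
bilinear_many <- function(values, spacing, origin, x, y) {
  nr <- nrow(values)
  nc <- ncol(values)
  gx <- (x - origin[1]) / spacing[1]
  gy <- (y - origin[2]) / spacing[2]
  tol <- 1e-9
  bad <- gx < -tol | gx > nc - 1 + tol | gy < -tol | gy > nr - 1 + tol
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  i0 <- pmin(floor(gx), nc - 2)
  j0 <- pmin(floor(gy), nr - 2)
  fx <- gx - i0
  fy <- gy - j0
  out <- values[cbind(j0 + 1, i0 + 1)] * (1 - fx) * (1 - fy) +
    values[cbind(j0 + 1, i0 + 2)] * fx * (1 - fy) +
    values[cbind(j0 + 2, i0 + 1)] * (1 - fx) * fy +
    values[cbind(j0 + 2, i0 + 2)] * fx * fy
  out[bad] <- NA_real_
  out
}

# Brute-force gamma map: for each evaluated reference point, exhaustively
# scan the candidate disc (step = step_fraction * dta, radius =
# radius_factor * dta) interpolating the calculated plane. Per-point work
# is vectorized over candidates but shares no code with the package's
# compiled kernel.
gamma_brute <- function(measured, calculated, dose_diff, dta,
                        threshold_pct = 10, normalization = "local",
                        step_fraction = 0.1, radius_factor = 3) {
  m <- measured$values
  mmax <- max(m)
  thr <- threshold_pct / 100 * mmax
  xs <- measured$origin_mm[1] + (seq_len(ncol(m)) - 1) * measured$spacing_mm[1]
  ys <- measured$origin_mm[2] + (seq_len(nrow(m)) - 1) * measured$spacing_mm[2]
  step <- step_fraction * dta
  nmax <- floor(radius_factor * dta / step + 1e-9)
  offs <- expand.grid(ix = -nmax:nmax, iy = -nmax:nmax)
  ox <- step * offs$ix
  oy <- step * offs$iy
  d2 <- ox^2 + oy^2
  keep <- d2 <= (radius_factor * dta)^2 * (1 + 1e-12)
  ox <- ox[keep]; oy <- oy[keep]; d2 <- d2[keep]
  gmap <- matrix(NA_real_, nrow(m), ncol(m))
  for (j in seq_len(nrow(m))) {
    for (i in seq_len(ncol(m))) {
      dm <- m[j, i]
      if (dm < thr || (normalization == "local" && dm <= 0)) next
      cx <- xs[i] + ox
      cy <- ys[j] + oy
      cd <- bilinear_many(calculated$values, calculated$spacing_mm,
                          calculated$origin_mm, cx, cy)
      den <- if (normalization == "local") dm else mmax
      dd <- 100 * (cd - dm) / den
      g2 <- d2 / dta^2 + (dd / dose_diff)^2
      gmap[j, i] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  gmap
}

# A small synthetic field: compensator + calculated plane at `model` +
# measured diode plane at `truth` (noise optional). Plane is 15 x 15 at
# 7 mm pitch when comp_spacing_mm = 7 and field_size_cm = 9.8.
make_field <- function(truth, model = truth, seed = 1,
                       field_size_cm = 10, comp_spacing_mm = 5,
                       diode_spacing_mm = 7, roughness = 1,
                       relative_sd = 0) {
  plan <- plan_spec(field_size_cm = field_size_cm,
                    comp_spacing_mm = comp_spacing_mm,
                    diode_spacing_mm = diode_spacing_mm,
                    roughness = roughness)
  comp <- generate_compensator_map(plan, seed = seed)
  delivered <- simulate_dose_plane(comp, truth)
  measured <- sample_diode_array(delivered, diode_spacing_mm,
                                 noise_spec(relative_sd, seed = seed + 7000))
  list(comp = comp, measured = measured,
       calculated = simulate_dose_plane(comp, model))
}
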