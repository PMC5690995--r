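#' Measurement noise specification
#'
#' Controls the noise injected by the synthetic-data generators:
#' multiplicative Gaussian noise on readings (ion-chamber and diode
#' repeatability is proportional to signal at therapy dose levels), an
#' optional beam-hardening-like quadratic perturbation of the log
#' attenuation, and the seed that makes every generator reproducible.
#'
#' @param relative_sd Relative standard deviation of multiplicative
#'   Gaussian noise (fraction, >= 0; 0.005 is a realistic chamber
#'   repeatability).
#' @param hardening_coeff Coefficient (cm^-2) of a `-c * t^2` term added to
#'   the log attenuation, emulating beam hardening; default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0, hardening_coeff = 0, seed = 1L) {
  check_number(relative_sd, "relative_sd", lower = 0)
  check_number(hardening_coeff, "hardening_coeff")
  check_number(seed, "seed")
  structure(
    list(relative_sd = relative_sd, hardening_coeff = hardening_coeff,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Synthetic slab-attenuation measurement set
#'
#' Emulates an ion-chamber slab study: transmission through each brass
#' thickness under every (depth, field size) condition, with
#' multiplicative reading noise and optional hardening. The measured log
#' ratio for a slab of thickness t is
#' `log(transmission(t, truth) * (1 + eps)) - hardening_coeff * t^2`,
#' with `eps ~ N(0, relative_sd^2)` drawn per record. Zero-thickness rows
#' are the open-field normalization and carry log ratio exactly 0.
#'
#' Depth and field size act only as condition labels by default; with
#' `kappa_jitter > 0`, each condition's effective kappa is perturbed by a
#' uniform factor in `(1 - kappa_jitter, 1 + kappa_jitter)`, emulating the
#' spread of per-condition density optima seen in practice (harder beams
#' for small fields, softer for large).
#'
#' @param truth Ground-truth [beam_model()].
#' @param thicknesses_cm Slab thicknesses, cm; default `c(0, 1, 3, 5)`
#'   (the three manufactured slabs plus the open-field row).
#' @param depths_cm Measurement depths, cm; default `c(2.5, 10, 20)`.
#' @param field_sizes_cm Square field sides, cm; default `c(5, 10, 20)`.
#' @param noise A [noise_spec()].
#' @param kappa_jitter Relative half-width of the per-condition kappa
#'   perturbation (default 0 = identical physics across conditions;
#'   0.02 emulates a realistic spread).
#' @return A [slab_measurements()] set covering the full crossing of
#'   thickness, depth and field size.
#' @export
generate_slab_measurements <- function(truth,
                                       thicknesses_cm = c(0, 1, 3, 5),
                                       depths_cm = c(2.5, 10, 20),
                                       field_sizes_cm = c(5, 10, 20),
                                       noise = noise_spec(),
                                       kappa_jitter = 0) {
  if (!is_beam_model(truth)) stop_usage("`truth` must be a beam_model")
  if (!inherits(noise, "noise_spec")) stop_usage("`noise` must be a noise_spec")
  check_number(kappa_jitter, "kappa_jitter", lower = 0, upper = 0.5)
  if (!any(thicknesses_cm > 0)) {
    stop_usage("`thicknesses_cm` must include positive values")
  }
  grid <- expand.grid(
    thickness_cm = sort(thicknesses_cm),
    depth_cm = sort(depths_cm),
    field_size_cm = sort(field_sizes_cm),
    KEEP.OUT.ATTRS = FALSE
  )
  conds <- unique(grid[c("depth_cm", "field_size_cm")])
  with_seed(noise$seed, {
    kfac <- if (kappa_jitter > 0) {
      stats::runif(nrow(conds), 1 - kappa_jitter, 1 + kappa_jitter)
    } else {
      rep(1, nrow(conds))
    }
    eps <- stats::rnorm(nrow(grid), 0, noise$relative_sd)
    cond_idx <- match(
      paste(grid$depth_cm, grid$field_size_cm),
      paste(conds$depth_cm, conds$field_size_cm)
    )
    t_cm <- grid$thickness_cm
    model_k <- truth$kappa * kfac[cond_idx]
    trans <- (1 + truth$msf * t_cm) * exp(-model_k * truth$rho * t_cm)
    x <- log(trans * (1 + eps)) - noise$hardening_coeff * t_cm^2
    x[t_cm == 0] <- 0 # open-field row is its own normalization
    slab_measurements(
      data.frame(
        thickness_cm = t_cm,
        depth_cm = grid$depth_cm,
        field_size_cm = grid$field_size_cm,
        log_ratio = x
      ),
      provenance = sprintf(
        "synthetic(rho=%g, msf=%g, kappa=%g, sd=%g, hardening=%g, jitter=%g, seed=%d)",
        truth$rho, truth$msf, truth$kappa, noise$relative_sd,
        noise$hardening_coeff, kappa_jitter, noise$seed
      )
    )
  })
}

#' IMRT plan specification for the synthetic study
#'
#' Geometry and modulation settings for the synthetic seven-field
#' compensator study: number of fields, field size, diode-array pitch,
#' compensator-grid spacing, and a roughness knob controlling how sharp
#' the compensator's hills and valleys are.
#'
#' @param n_fields Number of fields (default 7).
#' @param field_size_cm Square field side, cm (default 25, covering a
#'   typical diode-array active area).
#' @param diode_spacing_mm Diode pitch, mm (default 7, a generic
#'   diode-array geometry).
#' @param comp_spacing_mm Compensator/calculation grid spacing, mm
#'   (default 5).
#' @param roughness Non-negative modulation roughness; 0 gives a flat
#'   compensator, larger values give higher spatial frequencies (default 1).
#' @param base_thickness_cm Minimum milled thickness, cm (default 0.6, the
#'   fabrication minimum for commercial brass compensators).
#' @param max_thickness_cm Maximum thickness, cm (default 5, the top of the
#'   slab range studied).
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(n_fields = 7, field_size_cm = 25,
                      diode_spacing_mm = 7, comp_spacing_mm = 5,
                      roughness = 1, base_thickness_cm = 0.6,
                      max_thickness_cm = 5) {
  check_number(n_fields, "n_fields", lower = 1)
  check_number(field_size_cm, "field_size_cm", lower = 0, strict_lower = TRUE)
  check_number(diode_spacing_mm, "diode_spacing_mm", lower = 0,
               strict_lower = TRUE)
  check_number(comp_spacing_mm, "comp_spacing_mm", lower = 0,
               strict_lower = TRUE)
  check_number(roughness, "roughness", lower = 0)
  check_number(base_thickness_cm, "base_thickness_cm", lower = 0)
  check_number(max_thickness_cm, "max_thickness_cm",
               lower = base_thickness_cm)
  structure(
    list(n_fields = as.integer(n_fields), field_size_cm = field_size_cm,
         diode_spacing_mm = diode_spacing_mm,
         comp_spacing_mm = comp_spacing_mm, roughness = roughness,
         base_thickness_cm = base_thickness_cm,
         max_thickness_cm = max_thickness_cm),
    class = "plan_spec"
  )
}

#' Compensator thickness map
#'
#' A 2D brass thickness map on a regular grid, the synthetic analogue of a
#' milled IMRT compensator.
#'
#' @param thickness_cm Numeric matrix of thicknesses, cm.
#' @param spacing_mm Grid spacing, mm (scalar or `c(x, y)`).
#' @param base_thickness_cm Minimum milled thickness, cm; every value must
#'   be at least this.
#' @param origin_mm Physical coordinates of `thickness_cm[1, 1]`, mm.
#' @return An object of class `compensator_map`.
#' @export
compensator_map <- function(thickness_cm, spacing_mm,
                            base_thickness_cm = 0.6, origin_mm = c(0, 0)) {
  if (!is.matrix(thickness_cm) || !is.numeric(thickness_cm)) {
    stop_usage("`thickness_cm` must be a numeric matrix")
  }
  if (anyNA(thickness_cm) || any(!is.finite(thickness_cm))) {
    stop_usage("`thickness_cm` must be finite")
  }
  check_number(base_thickness_cm, "base_thickness_cm", lower = 0)
  if (any(thickness_cm < base_thickness_cm - 1e-12)) {
    stop_usage("thickness must be >= base_thickness_cm everywhere")
  }
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  origin_mm <- rep_len(as.numeric(origin_mm), 2L)
  if (any(spacing_mm <= 0)) stop_usage("`spacing_mm` must be positive")
  structure(
    list(values = thickness_cm, spacing_mm = spacing_mm,
         origin_mm = origin_mm, base_thickness_cm = base_thickness_cm),
    class = "compensator_map"
  )
}

#' @export
print.compensator_map <- function(x, ...) {
  cat(sprintf(
    "<compensator_map> %d x %d, spacing (%g, %g) mm, thickness [%g, %g] cm\n",
    nrow(x$values), ncol(x$values), x$spacing_mm[1], x$spacing_mm[2],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Generate a random IMRT-like compensator map
#'
#' Builds a smooth random thickness field — a sum of random low-frequency
#' cosine modes plus a few localized Gaussian bumps — rescaled to span
#' `[base, max]` thickness and clipped below at the base thickness. The
#' `roughness` setting of the plan spec scales the spatial frequencies and
#' shrinks the bumps, so rougher compensators have steeper thickness (and
#' hence fluence) gradients; `roughness = 0` degenerates to a flat slab at
#' the base thickness.
#'
#' @param spec A [plan_spec()].
#' @param seed Integer seed; maps are bit-reproducible per
#'   `(spec, seed)`.
#' @return A [compensator_map()] covering `field_size_cm` at
#'   `comp_spacing_mm`.
#' @export
generate_compensator_map <- function(spec = plan_spec(), seed = 1L) {
  if (!inherits(spec, "plan_spec")) stop_usage("`spec` must be a plan_spec")
  n <- floor(spec$field_size_cm * 10 / spec$comp_spacing_mm) + 1L
  xs <- (seq_len(n) - 1) * spec$comp_spacing_mm / 10 # cm
  if (spec$roughness == 0) {
    thick <- matrix(spec$base_thickness_cm, n, n)
    return(compensator_map(thick, spec$comp_spacing_mm,
                           spec$base_thickness_cm))
  }
  with_seed(seed, {
    X <- matrix(xs, n, n, byrow = TRUE)
    Y <- matrix(xs, n, n)
    raw <- matrix(0, n, n)
    n_modes <- 8L
    freq_scale <- 0.08 * spec$roughness # cycles per cm at roughness 1
    for (k in seq_len(n_modes)) {
      fx <- stats::runif(1, -1, 1) * freq_scale
      fy <- stats::runif(1, -1, 1) * freq_scale
      amp <- stats::runif(1, 0.5, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      raw <- raw + amp * cos(2 * pi * (fx * X + fy * Y) + phase)
    }
    n_bumps <- 3L
    bump_w <- 3 / (1 + spec$roughness) # cm
    for (k in seq_len(n_bumps)) {
      cx <- stats::runif(1, min(xs), max(xs))
      cy <- stats::runif(1, min(xs), max(xs))
      sgn <- sample(c(-1, 1), 1)
      raw <- raw + 2 * sgn * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * bump_w^2))
    }
    rng <- range(raw)
    unit <- (raw - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    thick <- spec$base_thickness_cm +
      (spec$max_thickness_cm - spec$base_thickness_cm) * unit
    thick <- pmax(thick, spec$base_thickness_cm)
    compensator_map(thick, spec$comp_spacing_mm, spec$base_thickness_cm)
  })
}

#' Calculated dose plane behind a compensator
#'
#' The surrogate TPS calculation: applies the compensator model's
#' transmission pointwise to an open-field plane, giving the relative dose
#' behind the compensator. The open field is flat (1.0) by default; a
#' smooth profile can be supplied as a function of (x, y) in mm.
#'
#' @param comp A [compensator_map()].
#' @param model A [beam_model()].
#' @param spacing_mm Output grid spacing, mm; default the compensator's
#'   own grid. A finer/coarser grid resamples the thickness map
#'   bilinearly over the same extent.
#' @param open_field `NULL` for a flat unit open field, or
#'   `function(x_mm, y_mm)` returning the open-field dose.
#' @return A [dose_plane()] of relative dose.
#' @export
simulate_dose_plane <- function(comp, model, spacing_mm = NULL,
                                open_field = NULL) {
  if (!inherits(comp, "compensator_map")) {
    stop_usage("`comp` must be a compensator_map")
  }
  if (!is_beam_model(model)) stop_usage("`model` must be a beam_model")
  if (is.null(spacing_mm) ||
      all(rep_len(spacing_mm, 2L) == comp$spacing_mm)) {
    thick <- comp$values
    spacing_mm <- comp$spacing_mm
    ax <- plane_axes(comp)
  } else {
    spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
    ext <- plane_extent(comp)
    xs <- seq(ext[1], ext[2], by = spacing_mm[1])
    ys <- seq(ext[3], ext[4], by = spacing_mm[2])
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    thick <- interp_bilinear(comp, X, Y)
    ax <- list(x = xs, y = ys)
  }
  of <- if (is.null(open_field)) {
    1
  } else {
    X <- matrix(ax$x, length(ax$y), length(ax$x), byrow = TRUE)
    Y <- matrix(ax$y, length(ax$y), length(ax$x))
    open_field(X, Y)
  }
  dose <- of * transmission(thick, model)
  dim(dose) <- dim(thick)
  dose_plane(dose, spacing_mm, comp$origin_mm)
}

#' Sample a dose plane on a diode array
#'
#' Emulates a diode-array measurement of a delivered dose plane: bilinear
#' sampling at diode positions on a regular pitch covering the plane,
#' with multiplicative Gaussian reading noise.
#'
#' @param plane A [dose_plane()] (the delivered/calculated dose).
#' @param diode_spacing_mm Diode pitch, mm; must be >= the plane's grid
#'   spacing (a diode array is always coarser than the calculation grid).
#' @param noise A [noise_spec()]; only `relative_sd` and `seed` are used.
#' @return A [dose_plane()] on the diode grid.
#' @export
sample_diode_array <- function(plane, diode_spacing_mm = 7,
                               noise = noise_spec()) {
  if (!is_dose_plane(plane)) stop_usage("`plane` must be a dose_plane")
  if (!inherits(noise, "noise_spec")) stop_usage("`noise` must be a noise_spec")
  check_number(diode_spacing_mm, "diode_spacing_mm", lower = 0,
               strict_lower = TRUE)
  if (any(diode_spacing_mm < plane$spacing_mm - 1e-12)) {
    stop_usage("diode spacing must be >= the plane grid spacing")
  }
  ext <- plane_extent(plane)
  xs <- seq(ext[1], ext[2], by = diode_spacing_mm)
  ys <- seq(ext[3], ext[4], by = diode_spacing_mm)
  if (length(xs) < 2L || length(ys) < 2L) {
    stop_usage("diode grid does not fit inside the plane")
  }
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  vals <- interp_bilinear(plane, X, Y)
  if (anyNA(vals)) stop_usage("diode grid extends beyond the plane")
  with_seed(noise$seed, {
    eps <- stats::rnorm(length(vals), 0, noise$relative_sd)
    noisy <- vals * (1 + eps)
    dim(noisy) <- dim(vals)
    noisy <- pmax(noisy, 0)
    dose_plane(noisy, diode_spacing_mm, c(ext[1], ext[3]))
  })
}

#' Generate a complete synthetic commissioning study
#'
#' Writes everything the two commissioning workflows need into a
#' directory: a slab-attenuation CSV covering all 9 (depth, field size)
#' conditions, and per-field compensator maps plus measured diode-array
#' planes for the seven-field plan, all generated from a single
#' ground-truth model. A JSON manifest records the full configuration and
#' seed, sufficient to regenerate the study bit-identically.
#'
#' @param dir Output directory (created if needed).
#' @param truth Ground-truth [beam_model()].
#' @param plan A [plan_spec()].
#' @param noise A [noise_spec()]; its seed derives all per-piece seeds.
#' @param kappa_jitter Per-condition kappa perturbation for the slab set.
#' @return Invisibly, a list with the generated `slabs` and `fields`
#'   objects and the file `paths`.
#' @export
simulate_study <- function(dir, truth = beam_model(7.8, 0.1),
                           plan = plan_spec(), noise = noise_spec(),
                           kappa_jitter = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slabs <- generate_slab_measurements(truth, noise = noise,
                                      kappa_jitter = kappa_jitter)
  slab_path <- file.path(dir, "slabs.csv")
  write_slab_csv(slabs, slab_path)
  seed_base <- (as.numeric(noise$seed) %% 1e6) * 1000 # keep derived seeds in range
  fields <- lapply(seq_len(plan$n_fields), function(k) {
    comp <- generate_compensator_map(plan, seed = seed_base + k)
    delivered <- simulate_dose_plane(comp, truth)
    measured <- sample_diode_array(
      delivered, plan$diode_spacing_mm,
      noise_spec(noise$relative_sd, seed = seed_base + 500 + k)
    )
    list(comp = comp, measured = measured)
  })
  paths <- list(slabs = slab_path)
  for (k in seq_along(fields)) {
    cp <- file.path(dir, sprintf("field%02d_compensator.txt", k))
    mp <- file.path(dir, sprintf("field%02d_measured.txt", k))
    write_grid_file(fields[[k]]$comp$values, fields[[k]]$comp$spacing_mm,
                    fields[[k]]$comp$origin_mm, cp)
    write_dose_plane(fields[[k]]$measured, mp)
    paths[[sprintf("field%02d", k)]] <- c(comp = cp, measured = mp)
  }
  manifest <- list(
    truth = list(rho = truth$rho, msf = truth$msf, kappa = truth$kappa),
    plan = unclass(plan),
    noise = unclass(noise),
    kappa_jitter = kappa_jitter
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(slabs = slabs, fields = fields, paths = paths))
}
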