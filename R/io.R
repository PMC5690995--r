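#' Read slab-attenuation measurements from CSV
#'
#' Expects a header row with named columns `thickness_cm`, `depth_cm`,
#' `field_size_cm`, `ratio` (ion-chamber reading relative to the open
#' field, so 1.0 at zero thickness). Ratios are converted to natural-log
#' ratios on read. Malformed rows are rejected with row-numbered messages.
#'
#' @param path Path to the CSV file.
#' @return A [slab_measurements()] set; `provenance` is the file name.
#' @export
read_slab_csv <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("thickness_cm", "depth_cm", "field_size_cm", "ratio")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_usage("missing column(s) in ", path, ": ",
               paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0L) {
      stop_usage(sprintf(
        "non-numeric or missing `%s` in %s at data row(s) %s",
        col, path, paste(bad, collapse = ", ")
      ))
    }
    df[[col]] <- vals
  }
  bad_ratio <- which(df$ratio <= 0)
  if (length(bad_ratio) > 0L) {
    stop_usage(sprintf("non-positive ratio in %s at data row(s) %s",
                       path, paste(bad_ratio, collapse = ", ")))
  }
  key <- paste(df$thickness_cm, df$depth_cm, df$field_size_cm)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_usage(sprintf(
      "duplicate (thickness, depth, field size) in %s at data row(s) %s",
      path, paste(dup, collapse = ", ")
    ))
  }
  slab_measurements(
    data.frame(
      thickness_cm = df$thickness_cm,
      depth_cm = df$depth_cm,
      field_size_cm = df$field_size_cm,
      log_ratio = log(df$ratio)
    ),
    provenance = basename(path)
  )
}

#' Write slab-attenuation measurements to CSV
#'
#' Inverse of [read_slab_csv()]: log ratios are exponentiated back to
#' plain ratios and written with 15 significant digits, so a write/read
#' round trip preserves the log ratios to better than 1e-12.
#'
#' @param measured A [slab_measurements()] set.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_slab_csv <- function(measured, path) {
  if (!is_slab_measurements(measured)) {
    measured <- slab_measurements(measured)
  }
  out <- data.frame(
    thickness_cm = measured$thickness_cm,
    depth_cm = measured$depth_cm,
    field_size_cm = measured$field_size_cm,
    ratio = sprintf("%.15g", exp(measured$log_ratio))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared ASCII grid writer: 4 header lines then whitespace-separated rows.
write_grid_file <- function(values, spacing_mm, origin_mm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("rows %d", nrow(values)),
    sprintf("cols %d", ncol(values)),
    sprintf("spacing_mm %.12g %.12g", spacing_mm[1], spacing_mm[2]),
    sprintf("origin_mm %.12g %.12g", origin_mm[1], origin_mm[2])
  ), con)
  utils::write.table(
    matrix(sprintf("%.12g", values), nrow(values), ncol(values)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_grid_file <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 5L) stop_usage("truncated grid file: ", path)
  header <- list()
  for (i in 1:4) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[parts[1]]] <- suppressWarnings(as.numeric(parts[-1]))
  }
  need <- c("rows", "cols", "spacing_mm", "origin_mm")
  if (!all(need %in% names(header)) ||
      anyNA(unlist(header[need]))) {
    stop_usage("malformed header in ", path,
               " (need rows, cols, spacing_mm, origin_mm)")
  }
  nr <- as.integer(header$rows)
  nc <- as.integer(header$cols)
  body <- lines[-(1:4)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    stop_usage(sprintf("%s: header says %d rows, body has %d",
                       path, nr, length(body)))
  }
  vals <- lapply(seq_along(body), function(i) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row)) {
      stop_usage(sprintf(
        "%s: data row %d does not contain %d numeric values", path, i, nc
      ))
    }
    row
  })
  list(
    values = do.call(rbind, vals),
    spacing_mm = rep_len(header$spacing_mm, 2L),
    origin_mm = rep_len(header$origin_mm, 2L)
  )
}

#' Read / write dose planes as ASCII grid files
#'
#' A simplified analogue of a diode-array text export: four header lines
#' (`rows`, `cols`, `spacing_mm`, `origin_mm`) followed by
#' whitespace-separated rows of dose values, printed with 12 significant
#' digits so round trips are lossless to better than 1e-9.
#'
#' @param path File path.
#' @return `read_dose_plane` returns a [dose_plane()];
#'   `write_dose_plane` invisibly returns `path`.
#' @export
read_dose_plane <- function(path) {
  g <- read_grid_file(path)
  dose_plane(g$values, g$spacing_mm, g$origin_mm)
}

#' @rdname read_dose_plane
#' @param plane A [dose_plane()].
#' @export
write_dose_plane <- function(plane, path) {
  if (!is_dose_plane(plane)) stop_usage("`plane` must be a dose_plane")
  write_grid_file(plane$values, plane$spacing_mm, plane$origin_mm, path)
}

#' Read a compensator thickness map from an ASCII grid file
#'
#' Same file format as [read_dose_plane()], with values interpreted as
#' brass thickness in cm.
#'
#' @param path File path.
#' @param base_thickness_cm Minimum milled thickness the map must respect
#'   (default: the smallest value present).
#' @return A [compensator_map()].
#' @export
read_compensator_map <- function(path, base_thickness_cm = NULL) {
  g <- read_grid_file(path)
  compensator_map(
    g$values, g$spacing_mm,
    base_thickness_cm = base_thickness_cm %||% min(g$values),
    origin_mm = g$origin_mm
  )
}

config_defaults <- function() {
  list(
    kappa = 0.037,
    rho_grid = default_rho_grid(),
    msf_grid = default_msf_grid(),
    criteria = list(
      list(dose_diff = 3, dta = 3), list(dose_diff = 2, dta = 2),
      list(dose_diff = 1.5, dta = 1.5), list(dose_diff = 1, dta = 1)
    ),
    low_dose_threshold = 10,
    normalization = "local",
    noise = list(relative_sd = 0.005, hardening_coeff = 0, seed = 1L),
    kappa_jitter = 0,
    seed = 1L,
    output_dir = "results"
  )
}

as_grid <- function(x, name) {
  if (is.list(x) && all(c("from", "to", "by") %in% names(x))) {
    x <- round(seq(x$from, x$to, by = x$by), 9)
  }
  check_grid(unlist(x), name, min_length = 2L)
}

#' Run configuration
#'
#' Loads, validates and completes the configuration driving both
#' commissioning workflows: the fixed mass attenuation coefficient, the
#' two sweep grids (either explicit vectors or `{from, to, by}` ranges),
#' the gamma criteria ladder, noise settings and the master seed. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML configuration file.
#' @param overrides Named list merged over the file's values (e.g. from
#'   command-line flags).
#' @return A validated `run_config` list with all defaults filled in.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_usage("config file not found: ", path)
    yaml::read_yaml(path) %||% list()
  }
  raw <- utils::modifyList(raw, overrides)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop_usage("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  check_number(cfg$kappa, "kappa", lower = 0, strict_lower = TRUE)
  cfg$rho_grid <- as_grid(cfg$rho_grid, "rho_grid")
  cfg$msf_grid <- as_grid(cfg$msf_grid, "msf_grid")
  check_number(cfg$low_dose_threshold, "low_dose_threshold",
               lower = 0, upper = 100, strict_upper = TRUE)
  if (!cfg$normalization %in% c("local", "global")) {
    stop_usage("`normalization` must be \"local\" or \"global\"")
  }
  cfg$criteria_levels <- lapply(cfg$criteria, function(cr) {
    gamma_criteria(cr$dose_diff, cr$dta, cfg$low_dose_threshold,
                   cfg$normalization)
  })
  cfg$noise_spec <- noise_spec(
    cfg$noise$relative_sd %||% 0,
    cfg$noise$hardening_coeff %||% 0,
    cfg$noise$seed %||% cfg$seed
  )
  structure(cfg, class = "run_config")
}

# Make a run_config JSON-serializable: drop classes from nested objects.
sanitize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$criteria_levels)) {
    cfg$criteria_levels <- lapply(cfg$criteria_levels, unclass)
  }
  if (!is.null(cfg$noise_spec)) cfg$noise_spec <- unclass(cfg$noise_spec)
  cfg
}

#' Write a commissioning report as JSON
#'
#' Serializes a slab [commission_slabs()] result together with the full
#' configuration and seed that produced it, so the run can be reproduced
#' exactly from the report alone.
#'
#' @param result A `commissioning_result`.
#' @param path Output JSON path.
#' @param config Optional `run_config` (or any list) echoed into the
#'   report.
#' @return Invisibly, `path`.
#' @export
write_commissioning_report <- function(result, path, config = NULL) {
  if (!inherits(result, "commissioning_result")) {
    stop_usage("`result` must be a commissioning_result")
  }
  payload <- list(
    rho_overall = result$rho_overall,
    msf_final = result$msf_final,
    chi2_min = result$chi2_min,
    condition_optima = result$condition_optima,
    rho_by_depth = result$rho_by_depth,
    kappa = result$kappa,
    rho_grid = result$rho_grid,
    msf_grid = result$msf_grid,
    provenance = result$provenance,
    config = if (is.null(config)) NULL else sanitize_config(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
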