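#' 2D dose plane
#'
#' A regular 2D grid of dose values with physical spacing and origin.
#' Columns run along x and rows along y; `origin_mm` gives the physical
#' (x, y) coordinates in mm of the first grid point `values[1, 1]`.
#' Doses may be relative (open field = 1) or absolute; the gamma analysis
#' only ever uses ratios.
#'
#' @param values Numeric matrix of finite, non-negative dose values.
#' @param spacing_mm Grid spacing in mm: scalar or `c(x, y)`.
#' @param origin_mm Physical coordinates (mm) of `values[1, 1]`; scalar or
#'   `c(x, y)`.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(values, spacing_mm, origin_mm = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_usage("`values` must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop_usage("`values` must be finite and >= 0")
  }
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  origin_mm <- rep_len(as.numeric(origin_mm), 2L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop_usage("`spacing_mm` must be positive")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "dose_plane"
  )
}

is_dose_plane <- function(x) inherits(x, "dose_plane")

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf(
    "<dose_plane> %d x %d, spacing (%g, %g) mm, origin (%g, %g) mm, dose [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$spacing_mm[1], x$spacing_mm[2],
    x$origin_mm[1], x$origin_mm[2], min(x$values), max(x$values)
  ))
  invisible(x)
}

# Physical x (per column) and y (per row) coordinates in mm.
plane_axes <- function(plane) {
  list(
    x = plane$origin_mm[1] +
      (seq_len(ncol(plane$values)) - 1) * plane$spacing_mm[1],
    y = plane$origin_mm[2] +
      (seq_len(nrow(plane$values)) - 1) * plane$spacing_mm[2]
  )
}

# Bounding box c(xmin, xmax, ymin, ymax) in mm.
plane_extent <- function(plane) {
  ax <- plane_axes(plane)
  c(min(ax$x), max(ax$x), min(ax$y), max(ax$y))
}

#' Bilinear interpolation of a dose plane
#'
#' Interpolates plane values at arbitrary physical positions; positions
#' outside the grid return `NA`. Used for the gamma-index search over the
#' calculated plane and for diode-array sampling.
#'
#' @param plane A [dose_plane()] (or compensator map) with >= 2 rows and
#'   columns.
#' @param x,y Physical coordinates in mm (vectors or matrices of equal
#'   shape).
#' @return Interpolated values, same shape as `x`; `NA` outside the grid.
#' @export
interp_bilinear <- function(plane, x, y) {
  v <- plane$values
  nr <- nrow(v)
  nc <- ncol(v)
  if (nr < 2L || nc < 2L) {
    stop_usage("plane must be at least 2 x 2 for bilinear interpolation")
  }
  gx <- (x - plane$origin_mm[1]) / plane$spacing_mm[1]
  gy <- (y - plane$origin_mm[2]) / plane$spacing_mm[2]
  tol <- 1e-9
  outside <- gx < -tol | gx > (nc - 1) + tol | gy < -tol | gy > (nr - 1) + tol
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  i0 <- pmin(floor(gx), nc - 2) # 0-based column of the lower-left node
  j0 <- pmin(floor(gy), nr - 2)
  fx <- gx - i0
  fy <- gy - j0
  # linear indices into v for the 4 surrounding nodes
  base <- j0 + 1 + nr * i0
  v00 <- v[base]
  v10 <- v[base + nr]
  v01 <- v[base + 1]
  v11 <- v[base + nr + 1]
  out <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out[outside] <- NA_real_
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}
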