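`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Sets the random seed, runs `code`, and restores the caller's RNG state,
#' so seeded generators are reproducible without clobbering the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(list = ".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  }
  force(code)
}

stop_usage <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_usage(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_usage(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_grid <- function(grid, name, min_length = 1L) {
  if (!is.numeric(grid) || length(grid) < min_length || anyNA(grid)) {
    stop_usage(sprintf(
      "`%s` must be a numeric vector of length >= %d with no missing values",
      name, min_length
    ))
  }
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop_usage(sprintf("`%s` must be strictly increasing", name))
  }
  invisible(as.numeric(grid))
}
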