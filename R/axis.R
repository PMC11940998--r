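#' Uniform wavenumber axis
#'
#' Constructs the shared Raman-shift grid on which all spectra of a dataset
#' live.  The default reproduces the acquisition grid used throughout the
#' package: 1950 evenly spaced points from 517 to 1913 cm^-1, endpoints
#' inclusive.
#'
#' @param start,end First and last wavenumber (cm^-1); `start < end`.
#' @param n_points Number of grid points (>= 2).
#' @return An object of class `wavenumber_axis`: a numeric vector of
#'   wavenumbers with attributes `start`, `end` and `n_points`.
#' @examples
#' ax <- wavenumber_axis()
#' length(ax)   # 1950
#' range(ax)    # 517 1913
#' @export
wavenumber_axis <- function(start = 517, end = 1913, n_points = 1950) {
  if (!is.numeric(start) || !is.numeric(end) || start >= end)
    stop_("wavenumber_axis: 'start' (%s) must be < 'end' (%s)", start, end)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop_("wavenumber_axis: 'n_points' must be an integer >= 2")
  x <- seq(start, end, length.out = n_points)
  structure(x, start = start, end = end, n_points = n_points,
            class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %d points, %.6g-%.6g cm^-1 (step %.6g)\n",
              length(x), x[1], x[length(x)], x[2] - x[1]))
  invisible(x)
}

as_axis <- function(x) {
  if (inherits(x, "wavenumber_axis")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2L || any(!is.finite(x)) || any(diff(x) <= 0))
    stop_("wavenumbers must be finite and strictly increasing")
  structure(x, start = x[1], end = x[length(x)], n_points = length(x),
            class = "wavenumber_axis")
}

# closed-interval crop; returns integer index vector into the axis
crop_index <- function(axis, start, end) {
  which(axis >= start - 1e-9 & axis <= end + 1e-9)
}
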