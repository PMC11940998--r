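# Spectral preprocessing chain: Savitzky-Golay smoothing, iterative
# modified-polynomial background removal, SNV normalisation, applied per
# spectrum on the cropped wavenumber grid, in that fixed order.

#' Preprocessing configuration
#'
#' Defaults follow the standard serum-SERS chain: SG filter of window 15
#' (grid points), polynomial order 1, derivative order 0; 15th-degree
#' iterative polynomial baseline; SNV; crop to the closed interval
#' 517-1913 cm^-1.
#'
#' @param sg_window Odd SG window width in grid points, > `sg_polyorder`.
#' @param sg_polyorder Order of the local smoothing polynomial.
#' @param sg_deriv Derivative order (<= `sg_polyorder`).
#' @param baseline_degree Degree of the background polynomial.
#' @param baseline_max_iter Iteration cap for the modified-polynomial fit.
#' @param baseline_tol Relative-change stopping tolerance.
#' @param crop Length-2 numeric, closed crop interval in cm^-1.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 15L, sg_polyorder = 1L,
                              sg_deriv = 0L, baseline_degree = 15L,
                              baseline_max_iter = 100L,
                              baseline_tol = 1e-6,
                              crop = c(517, 1913)) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stop_("preprocess_config: 'sg_window' must be odd and > 'sg_polyorder'")
  if (sg_deriv > sg_polyorder)
    stop_("preprocess_config: 'sg_deriv' must be <= 'sg_polyorder'")
  if (baseline_degree < 0)
    stop_("preprocess_config: 'baseline_degree' must be >= 0")
  if (length(crop) != 2 || crop[1] >= crop[2])
    stop_("preprocess_config: 'crop' must be (start, end) with start < end")
  structure(list(sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 baseline_degree = as.integer(baseline_degree),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol, crop = as.numeric(crop)),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Each interior point is replaced by the value (or `sg_deriv`-th
#' derivative) of the local least-squares polynomial of order
#' `sg_polyorder` over the centred window; edges are evaluated from the
#' polynomial fitted at the boundary windows rather than truncated.
#'
#' @param intensities Numeric vector, length >= `cfg$sg_window`.
#' @param cfg A [preprocess_config()].
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(intensities, cfg = preprocess_config()) {
  n <- length(intensities)
  if (n < cfg$sg_window)
    stop_("savgol_smooth: need at least %d points (got %d)",
          cfg$sg_window, n)
  if (any(!is.finite(intensities)))
    stop_("savgol_smooth: non-finite input")
  as.numeric(signal::sgolayfilt(intensities, p = cfg$sg_polyorder,
                                n = cfg$sg_window, m = cfg$sg_deriv))
}

# Chebyshev design matrix of degree d on x mapped to [-1, 1]
cheb_design <- function(x, degree) {
  u <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  B <- matrix(1, length(u), degree + 1L)
  if (degree >= 1L) B[, 2] <- u
  if (degree >= 2L)
    for (k in 3:(degree + 1L)) B[, k] <- 2 * u * B[, k - 1] - B[, k - 2]
  B
}

#' Iterative polynomial background estimation
#'
#' Modified-polynomial (ModPoly-style) baseline: fit a degree-`d`
#' polynomial, clip the working spectrum to `min(spectrum, fit)`, refit,
#' and iterate until the fit changes by less than `baseline_tol`
#' (relative RMS) or `baseline_max_iter` is reached.  Clipping lets the
#' polynomial settle under the peaks instead of absorbing them; a plain
#' least-squares fit of this degree would follow the peaks.  The fit uses
#' a Chebyshev basis on the wavenumber rescaled to `[-1, 1]` for
#' conditioning.
#'
#' @param intensities Finite numeric vector.
#' @param axis Wavenumbers of the same length.
#' @param cfg A [preprocess_config()].
#' @return List with `baseline` and `corrected` (= input - baseline).
#' @export
polynomial_baseline <- function(intensities, axis = seq_along(intensities),
                                cfg = preprocess_config()) {
  n <- length(intensities)
  if (any(!is.finite(intensities)))
    stop_("polynomial_baseline: non-finite input")
  if (cfg$baseline_degree >= n)
    stop_("polynomial_baseline: degree %d >= number of points %d",
          cfg$baseline_degree, n)
  B <- cheb_design(as.numeric(axis), cfg$baseline_degree)
  qrB <- qr(B)  # basis is fixed; factor once, reuse across iterations
  work <- intensities
  fit <- drop(B %*% qr.coef(qrB, work))
  scale <- max(diff(range(intensities)), .Machine$double.eps)
  for (it in seq_len(cfg$baseline_max_iter)) {
    work <- pmin(work, fit)
    new_fit <- drop(B %*% qr.coef(qrB, work))
    delta <- sqrt(mean((new_fit - fit)^2)) / scale
    fit <- new_fit
    if (delta < cfg$baseline_tol) break
  }
  list(baseline = fit, corrected = intensities - fit)
}

#' Standard normal variate normalisation
#'
#' Centres and scales one spectrum to mean 0, sample standard deviation 1
#' (n - 1 denominator).
#'
#' @param intensities Numeric vector with >= 2 points and nonzero spread.
#' @return Normalised vector.
#' @examples
#' snv_normalize(c(1, 2, 3))   # -1 0 1
#' @export
snv_normalize <- function(intensities) {
  if (length(intensities) < 2)
    stop_("snv_normalize: need at least 2 points")
  s <- sd(intensities)
  if (!is.finite(s) || s == 0)
    stop_("zero variance under SNV")
  (intensities - mean(intensities)) / s
}

#' Preprocess every spectrum of a dataset
#'
#' Crops to `cfg$crop` (closed interval), then applies, per spectrum and
#' in this fixed order: Savitzky-Golay smoothing, iterative polynomial
#' background removal, SNV normalisation.  Metadata is unchanged; the
#' output axis contains exactly the grid points inside the crop range.
#'
#' @param ds A [sers_dataset()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed [sers_dataset()].
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "sers_dataset"))
  keep <- crop_index(ds$axis, cfg$crop[1], cfg$crop[2])
  if (length(keep) < 2)
    stop_("preprocess_dataset: crop [%g, %g] leaves fewer than 2 grid points",
          cfg$crop[1], cfg$crop[2])
  axis <- as_axis(as.numeric(ds$axis)[keep])
  X <- ds$intensities[, keep, drop = FALSE]
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    y <- tryCatch({
      y <- savgol_smooth(X[i, ], cfg)
      y <- polynomial_baseline(y, axis, cfg)$corrected
      snv_normalize(y)
    }, error = function(e)
      stop_("preprocess_dataset: spectrum '%s': %s",
            ds$meta$spectrum_id[i], conditionMessage(e)))
    out[i, ] <- y
  }
  sers_dataset(out, axis, ds$meta)
}
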