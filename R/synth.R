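# Synthetic SERS serum cohorts: Lorentzian peak sums on a shared grid,
# patient-level multiplicative random effects, smooth fluorescence-like
# polynomial baseline, per-spectrum gain and additive detector noise.

#' Configuration for the synthetic cohort generator
#'
#' @param classes Data frame (or list coercible to one) with columns
#'   `label`, `n_patients`, `spectra_per_patient`; one row per class.
#' @param axis A [wavenumber_axis()]; default 1950 points on 517-1913.
#' @param peaks List of [peak_spec()]; default [default_peak_library()]
#'   keyed to the first two class labels (first = positive/respiratory
#'   side of the default group effects).
#' @param patient_sd Standard deviation of the patient-level log-normal
#'   amplitude random effect (on the log scale), >= 0.
#' @param noise_sd Additive Gaussian detector-noise sd (intensity units).
#' @param baseline_coeffs Polynomial coefficients `c0..ck` of the smooth
#'   background, evaluated in the scaled coordinate `u = (w - start) /
#'   (end - start)` in `[0, 1]`; constant term positive.
#' @param gain_sd Per-spectrum log-normal gain sd (log scale), >= 0.
#' @param spectra_jitter Non-negative integer; each patient's replicate
#'   count is drawn uniformly from `spectra_per_patient +/- jitter`
#'   (floored at 1) to emulate uneven per-patient totals.  Default 0
#'   keeps counts exact.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(classes = data.frame(
                               label = c("respiratory", "referent"),
                               n_patients = c(41L, 103L),
                               spectra_per_patient = c(3L, 3L)),
                             axis = wavenumber_axis(),
                             peaks = NULL,
                             patient_sd = 0.15,
                             noise_sd = 0.02,
                             baseline_coeffs = c(2.5, -2.0, 0.8, -0.2, 0.1, 0.05),
                             gain_sd = 0.10,
                             spectra_jitter = 0L,
                             seed = 1L) {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  need <- c("label", "n_patients", "spectra_per_patient")
  if (!all(need %in% names(classes)))
    stop_("synthetic_config: 'classes' needs columns %s",
          paste(need, collapse = ", "))
  if (any(classes$n_patients < 1) || any(classes$spectra_per_patient < 1))
    stop_("synthetic_config: 'classes' counts must all be >= 1")
  if (anyDuplicated(classes$label))
    stop_("synthetic_config: 'classes' labels must be unique")
  for (nm in c("patient_sd", "noise_sd", "gain_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop_("synthetic_config: '%s' must be a single number >= 0", nm)
  }
  if (spectra_jitter < 0)
    stop_("synthetic_config: 'spectra_jitter' must be >= 0")
  if (is.null(peaks))
    peaks <- default_peak_library(classes$label[1],
                                  classes$label[min(2, nrow(classes))])
  structure(list(classes = classes, axis = as_axis(axis), peaks = peaks,
                 patient_sd = patient_sd, noise_sd = noise_sd,
                 baseline_coeffs = baseline_coeffs, gain_sd = gain_sd,
                 spectra_jitter = as.integer(spectra_jitter),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# unit-height Lorentzian line shape, width = HWHM
lorentzian <- function(x, center, width) 1 / (1 + ((x - center) / width)^2)

# evaluate baseline polynomial on the axis (scaled coordinate in [0,1])
eval_baseline <- function(axis, coeffs) {
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

# deterministic per-entity child seed: polynomial string hash folded into
# the master seed, so each patient's stream survives class reordering
child_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147480009
  as.integer((h + as.double(seed) * 7919) %% 2147480009) + 1L
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic SERS serum cohort
#'
#' Per patient one multiplicative log-normal amplitude effect is drawn;
#' each replicate spectrum is `gain * patient_effect * sum(peaks) +
#' baseline + noise`, where each peak contributes `base_amplitude *
#' group_effect[class] * Lorentzian(center, width)`.  All randomness flows
#' from `config$seed` through per-patient child streams, so the output is
#' reproducible and stable under class reordering.
#'
#' @param config A [synthetic_config()].
#' @return A [sers_dataset()] with
#'   `sum(n_patients * spectra_per_patient)` spectra (exactly, when
#'   `spectra_jitter = 0`).
#' @examples
#' ds <- generate_cohort(synthetic_config(classes = data.frame(
#'   label = c("a", "b"), n_patients = c(3, 4), spectra_per_patient = 3),
#'   seed = 7))
#' dim(ds)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  axis <- config$axis
  baseline <- eval_baseline(axis, config$baseline_coeffs)
  # per-class clean peak sums (shared across patients of a class)
  signal_of <- lapply(seq_len(nrow(config$classes)), function(k) {
    lab <- config$classes$label[k]
    s <- numeric(length(axis))
    for (p in config$peaks)
      s <- s + p$base_amplitude * peak_factor(p, lab) *
        lorentzian(as.numeric(axis), p$center, p$width)
    s
  })
  rows <- list(); meta <- list(); idx <- 0L
  for (k in seq_len(nrow(config$classes))) {
    lab <- config$classes$label[k]
    spp <- config$classes$spectra_per_patient[k]
    for (i in seq_len(config$classes$n_patients[k])) {
      idx <- idx + 1L
      pid <- sprintf("%s_p%03d", lab, i)
      res <- with_seed(child_seed(config$seed, pid), {
        n_s <- if (config$spectra_jitter > 0)
          max(1L, spp + sample.int(2L * config$spectra_jitter + 1L, 1L) -
                config$spectra_jitter - 1L) else spp
        pe <- exp(rnorm(1, 0, config$patient_sd))
        gains <- exp(rnorm(n_s, 0, config$gain_sd))
        noise <- matrix(rnorm(n_s * length(axis), 0, config$noise_sd), n_s)
        list(n_s = n_s, pe = pe, gains = gains, noise = noise)
      })
      m <- res$gains %o% (res$pe * signal_of[[k]]) +
        matrix(baseline, res$n_s, length(axis), byrow = TRUE) + res$noise
      rows[[idx]] <- m
      meta[[idx]] <- data.frame(
        spectrum_id = sprintf("%s_s%d", pid, seq_len(res$n_s)),
        patient_id = pid, class_label = lab, stringsAsFactors = FALSE)
    }
  }
  sers_dataset(do.call(rbind, rows), axis, do.call(rbind, meta))
}

#' Generate a signal-free (null) cohort
#'
#' As [generate_cohort()] but with every band's group effect forced to 1:
#' both classes are drawn from the identical generating distribution, so
#' class labels carry no information.  Used to calibrate the protocol's
#' type-I behaviour (chance-level accuracy and AUC expected downstream).
#'
#' @param config A [synthetic_config()].
#' @return A [sers_dataset()].
#' @export
null_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  config$peaks <- neutral_peaks(config$peaks)
  generate_cohort(config)
}
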