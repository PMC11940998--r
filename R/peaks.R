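#' Define a Raman band for the synthetic generator
#'
#' A band is a Lorentzian line with a centre, a half-width at half-maximum
#' and a base amplitude, plus a per-class multiplicative `group_effect`
#' encoding how strongly each class expresses the band.
#'
#' @param center Band centre (cm^-1).
#' @param width Half-width at half-maximum (cm^-1), > 0.
#' @param base_amplitude Peak amplitude in arbitrary intensity units, >= 0.
#' @param assignment Free-text biochemical assignment.
#' @param group_effect Named numeric vector of strictly positive
#'   multiplicative factors, one per class label; classes not named get
#'   factor 1.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, width = 8, base_amplitude = 1,
                      assignment = "", group_effect = numeric(0)) {
  if (!is.numeric(width) || width <= 0)
    stop_("peak_spec(center=%s): 'width' must be > 0", center)
  if (!is.numeric(base_amplitude) || base_amplitude < 0)
    stop_("peak_spec(center=%s): 'base_amplitude' must be >= 0", center)
  if (length(group_effect) && (is.null(names(group_effect)) ||
      any(!nzchar(names(group_effect)))))
    stop_("peak_spec(center=%s): 'group_effect' must be a named vector", center)
  if (any(group_effect <= 0))
    stop_("peak_spec(center=%s): 'group_effect' factors must be > 0", center)
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude,
                 assignment = assignment,
                 group_effect = group_effect),
            class = "peak_spec")
}

# factor a band applies for a class label (1 when the class is unnamed)
peak_factor <- function(peak, class_label) {
  g <- peak$group_effect[class_label]
  if (length(g) == 1 && !is.na(g)) unname(g) else 1
}

#' Serum SERS band library
#'
#' The fifteen prominent serum bands used as the generator's default peak
#' set, with their usual biochemical assignments.  Default group effects
#' encode the band-intensity differences reported between a respiratory
#' disease group and a pathological referent (CHF) group: the respiratory
#' class is higher at 724, 947, 1051 and 1390 cm^-1 and lower at 638 and
#' 1657 cm^-1; all other bands are neutral.  The two headline bands carry
#' a 20% shift (0.80 at 638, 1.20 at 1051), the secondary bands 10%.
#'
#' @param positive_class,referent_class Class labels the default group
#'   effects are keyed to.
#' @return List of 15 [peak_spec()] objects.
#' @examples
#' lib <- default_peak_library()
#' vapply(lib, `[[`, numeric(1), "center")
#' @export
default_peak_library <- function(positive_class = "respiratory",
                                 referent_class = "referent") {
  eff <- function(pos) setNames(c(pos, 1), c(positive_class, referent_class))
  amp <- function(a) a
  bands <- list(
    list(587,  "Phosphatidylinositol in lipids",                    0.45, 1.00),
    list(638,  "uric acid",                                          0.70, 0.80),
    list(724,  "delta(C-H) of adenine, coenzyme A, DNA/RNA",         0.65, 1.10),
    list(805,  "nu(C-C-O) of L-Serine, glutathione",                 0.40, 1.00),
    list(890,  "delta(C-O-H)/ring bending of tryptophan, glutathione, D-(C)-galactosamine",
               0.40, 1.00),
    list(947,  "C-C stretching of proteins",                         0.50, 1.10),
    list(1008, "Phenylalanine",                                      1.00, 1.00),
    list(1051, "Glycogen in Carbohydrates",                          0.60, 1.20),
    list(1132, "nu(C-N) in D-Mannose",                               0.55, 1.00),
    list(1207, "ring vibrations in L-Tryptophan, phenylalanine",     0.50, 1.00),
    list(1329, "Torsion mode CH2 in lipids",                         0.60, 1.00),
    list(1390, "C-N, C-H group, omega(CH3), CH2 wagging in lipids",  0.65, 1.10),
    list(1442, "CH2/CH3 deformations in proteins and lipids",        0.55, 1.00),
    list(1568, "DNA/RNA bases",                                      0.45, 1.00),
    list(1657, "nu(C-O), Amide I",                                   0.75, 0.90))
  lapply(bands, function(b)
    peak_spec(center = b[[1]], width = 8, base_amplitude = amp(b[[3]]),
              assignment = b[[2]], group_effect = eff(b[[4]])))
}

#' Null version of a peak library
#'
#' Forces every band's group effect to 1 so class labels carry no signal.
#'
#' @param peaks List of [peak_spec()] objects.
#' @return The same list with all group-effect factors set to 1.
#' @export
neutral_peaks <- function(peaks) {
  lapply(peaks, function(p) {
    p$group_effect[] <- 1
    p
  })
}
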