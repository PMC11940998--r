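#' Spectra dataset container
#'
#' Bundles a spectra matrix (one row per spectrum, one column per grid
#' point) with its wavenumber axis and per-spectrum metadata.  Replicate
#' spectra of one patient share a `patient_id`, and all spectra of a
#' patient carry the same `class_label` -- the invariant the patient-wise
#' resampling protocol relies on.
#'
#' @param intensities Numeric matrix, spectra in rows; finite values.
#' @param axis A [wavenumber_axis()] (or numeric vector of strictly
#'   increasing wavenumbers) with `ncol(intensities)` points.
#' @param meta Data frame with columns `spectrum_id`, `patient_id`,
#'   `class_label`, one row per spectrum, in row order of `intensities`.
#' @return An object of class `sers_dataset` with elements `axis`,
#'   `intensities` (rownames = spectrum ids) and `meta`.
#' @export
sers_dataset <- function(intensities, axis, meta) {
  axis <- as_axis(axis)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(axis))
    stop_("sers_dataset: %d intensity columns but %d axis points",
          ncol(intensities), length(axis))
  if (nrow(intensities) > 0 && any(!is.finite(intensities)))
    stop_("sers_dataset: non-finite intensity values")
  need <- c("spectrum_id", "patient_id", "class_label")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop_("sers_dataset: 'meta' must have columns %s",
          paste(need, collapse = ", "))
  meta <- data.frame(lapply(meta[need], as.character),
                     stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(intensities))
    stop_("sers_dataset: %d meta rows but %d spectra",
          nrow(meta), nrow(intensities))
  if (anyDuplicated(meta$spectrum_id))
    stop_("sers_dataset: duplicate spectrum_id: %s",
          meta$spectrum_id[duplicated(meta$spectrum_id)][1])
  cpp <- unique(meta[c("patient_id", "class_label")])
  if (anyDuplicated(cpp$patient_id))
    stop_("sers_dataset: patient %s appears under more than one class",
          cpp$patient_id[duplicated(cpp$patient_id)][1])
  rownames(intensities) <- meta$spectrum_id
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "sers_dataset")
}

#' @export
print.sers_dataset <- function(x, ...) {
  tab <- table(class_of_patients(x))
  cat(sprintf("<sers_dataset> %d spectra, %d patients, %d grid points (%.5g-%.5g cm^-1)\n",
              nrow(x$intensities), length(unique(x$meta$patient_id)),
              length(x$axis), x$axis[1], x$axis[length(x$axis)]))
  if (length(tab))
    cat("  patients per class:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sers_dataset <- function(x) dim(x$intensities)

#' Map patient id to class label
#' @param ds A [sers_dataset()].
#' @return Named character vector, one element per patient.
#' @export
class_of_patients <- function(ds) {
  u <- unique(ds$meta[c("patient_id", "class_label")])
  setNames(u$class_label, u$patient_id)
}

#' Subset a dataset by spectrum rows
#'
#' @param ds A [sers_dataset()].
#' @param i Row index (logical, integer, or spectrum ids).
#' @return A [sers_dataset()] with the selected spectra.
#' @export
subset_spectra <- function(ds, i) {
  if (is.character(i)) i <- match(i, ds$meta$spectrum_id)
  sers_dataset(ds$intensities[i, , drop = FALSE], ds$axis,
               ds$meta[i, , drop = FALSE])
}

#' Subset a dataset by patients
#' @param ds A [sers_dataset()].
#' @param patients Character vector of patient ids to keep.
#' @return A [sers_dataset()] with every spectrum of the given patients.
#' @export
subset_patients <- function(ds, patients) {
  subset_spectra(ds, ds$meta$patient_id %in% patients)
}

# 0/1 response vector for a binary dataset, given the positive class
class_response <- function(ds, positive_class) {
  cls <- unique(ds$meta$class_label)
  if (!positive_class %in% cls)
    stop_("positive class '%s' not present (classes: %s)",
          positive_class, paste(cls, collapse = ", "))
  as.numeric(ds$meta$class_label == positive_class)
}
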