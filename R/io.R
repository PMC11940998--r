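# Readers/writers for the package's interchange formats: wide spectra
# CSV (column 1 = wavenumber_cm1, one column per spectrum id), metadata
# CSV (spectrum_id, patient_id, class_label), JSON/CSV result exports.
# Readers validate and reject malformed input rather than coercing.

#' Read a spectra dataset from wide CSV + metadata CSV
#'
#' @param path_wide_csv Wide CSV: first column `wavenumber_cm1`
#'   (strictly increasing), then one intensity column per spectrum id.
#' @param path_meta_csv Metadata CSV with columns `spectrum_id`,
#'   `patient_id`, `class_label`.
#' @return A [sers_dataset()].
#' @export
read_spectra <- function(path_wide_csv, path_meta_csv) {
  for (p in c(path_wide_csv, path_meta_csv))
    if (!file.exists(p)) stop_("read_spectra: no such file: %s", p)
  wide <- read.csv(path_wide_csv, check.names = FALSE)
  if (names(wide)[1] != "wavenumber_cm1")
    stop_("read_spectra: first column must be 'wavenumber_cm1' (got '%s')",
          names(wide)[1])
  ax <- as.numeric(wide[[1]])
  if (any(!is.finite(ax)) || any(diff(ax) <= 0))
    stop_("read_spectra: wavenumbers not strictly increasing")
  ids <- names(wide)[-1]
  if (anyDuplicated(ids))
    stop_("read_spectra: duplicate spectrum column '%s'",
          ids[duplicated(ids)][1])
  meta <- read.csv(path_meta_csv, colClasses = "character")
  need <- c("spectrum_id", "patient_id", "class_label")
  if (!all(need %in% names(meta)))
    stop_("read_spectra: metadata needs columns %s",
          paste(need, collapse = ", "))
  missing <- setdiff(ids, meta$spectrum_id)
  if (length(missing))
    stop_("read_spectra: spectrum '%s' has no metadata row", missing[1])
  extra <- setdiff(meta$spectrum_id, ids)
  if (length(extra))
    stop_("read_spectra: metadata row '%s' has no spectrum column", extra[1])
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  X <- t(as.matrix(wide[-1]))
  if (any(!is.finite(X)))
    stop_("read_spectra: non-finite intensity values")
  sers_dataset(X, ax, meta)
}

#' Write a spectra dataset as wide CSV + metadata CSV
#'
#' Inverse of [read_spectra()]; round-trips losslessly up to CSV numeric
#' printing (15 significant digits).
#'
#' @param ds A [sers_dataset()].
#' @param path_wide_csv,path_meta_csv Output paths.
#' @return The wide-CSV path, invisibly.
#' @export
write_spectra <- function(ds, path_wide_csv, path_meta_csv) {
  wide <- data.frame(wavenumber_cm1 = as.numeric(ds$axis),
                     t(ds$intensities), check.names = FALSE)
  names(wide) <- c("wavenumber_cm1", ds$meta$spectrum_id)
  write.csv(wide, path_wide_csv, row.names = FALSE)
  write.csv(ds$meta, path_meta_csv, row.names = FALSE)
  invisible(path_wide_csv)
}

#' Write a protocol summary as CSV and JSON
#'
#' The CSV mirrors the mean (min-max) results-table layout: one row per
#' set (train/test), three columns (mean, min, max) for each of
#' specificity, sensitivity, accuracy and ROC AUC.  A JSON twin carrying
#' the full summary (including the mean VIP profile) is written next to
#' it when `path_json` is given.
#'
#' @param summary A `protocol_summary` from [aggregate_folds()].
#' @param path CSV output path.
#' @param path_json Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, path_json = NULL) {
  tab <- summary$table
  out <- data.frame(set = unique(tab$set))
  for (m in unique(tab$metric)) for (s in c("mean", "min", "max"))
    out[[paste(m, s, sep = "_")]] <- vapply(out$set, function(se)
      tab[[s]][tab$set == se & tab$metric == m], numeric(1))
  write.csv(out, path, row.names = FALSE)
  if (!is.null(path_json)) {
    payload <- list(table = tab, n_folds = summary$n_folds,
                    n_lv_used = summary$n_lv_used,
                    positive_class = summary$positive_class,
                    mean_vip = summary$mean_vip,
                    wavenumber = as.numeric(summary$axis))
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a protocol summary back from its JSON twin
#' @param path_json Path written by [write_summary()].
#' @return A `protocol_summary`.
#' @export
read_summary <- function(path_json) {
  p <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  structure(list(table = p$table, mean_vip = p$mean_vip,
                 n_folds = p$n_folds, n_lv_used = p$n_lv_used,
                 positive_class = p$positive_class,
                 axis = if (length(p$wavenumber)) as_axis(p$wavenumber)),
            class = "protocol_summary")
}

#' Serialize a fitted PLS-DA model to JSON
#'
#' All matrices are stored column-major with explicit dimensions; the
#' file is plain JSON, fit for `sersclass train`/`predict` round trips.
#'
#' @param model A [plsda()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plsda <- function(model, path) {
  m <- model
  for (f in c("weights", "loadings", "scores_basis", "scores", "coef_path"))
    m[[f]] <- list(dim = dim(model[[f]]), data = as.numeric(model[[f]]))
  m$class_codes <- as.list(model$class_codes)  # keep label names in JSON
  m$cv <- if (!is.null(model$cv)) list(rmse = model$cv$rmse,
                                       max_lv = model$cv$max_lv)
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "loadings", "scores_basis", "scores", "coef_path"))
    m[[f]] <- matrix(m[[f]]$data, m[[f]]$dim[1], m[[f]]$dim[2])
  if (!is.null(m$cv)) class(m$cv) <- "rmse_curve"
  m$class_codes <- unlist(m$class_codes)
  structure(m, class = "plsda")
}
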