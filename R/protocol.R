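# Repeated bootstrap-balanced, patient-wise resampling protocol: at every
# (p, t) fold the larger class is randomly balanced down to the smaller
# class's patient count, replicate spectra are drawn per patient, the
# cohort is split 80/20 by whole patients, and a PLS-DA model with a
# CV-selected LV count is trained and evaluated on both sides.

#' Protocol configuration
#'
#' @param P Repeats of the train/test division.
#' @param T_rep Repeats of model training per division.  Each of the
#'   `P * T_rep` folds draws a fresh balanced subset and split ("treated
#'   as a new observation"), so every fold is an independent realisation
#'   of the design.
#' @param train_fraction Target fraction of spectra in the training set.
#' @param K Cross-validation folds for LV selection.
#' @param max_lv Upper bound of the LV search.
#' @param spectra_per_patient_draw Spectra drawn per retained patient at
#'   the balancing step.
#' @param balance_patient_sampling `"without"` (default) samples patients
#'   of the larger class without replacement; `"with"` uses replacement.
#' @param threshold Classification threshold on the PLS score.
#' @param positive_class Label coded 1 (the sensitivity class); `NULL`
#'   picks the class with fewer patients (the clinical case group in
#'   both study designs) and records the choice in the results.
#' @param seed Integer seed determining the full fold sequence.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(P = 5L, T_rep = 5L, train_fraction = 0.8,
                            K = 10L, max_lv = 15L,
                            spectra_per_patient_draw = 3L,
                            balance_patient_sampling = c("without", "with"),
                            threshold = 0.5, positive_class = NULL,
                            seed = 1L) {
  if (P < 1 || T_rep < 1) stop_("protocol_config: P and T_rep must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_("protocol_config: train_fraction must be in (0, 1)")
  if (spectra_per_patient_draw < 1)
    stop_("protocol_config: spectra_per_patient_draw must be >= 1")
  structure(list(P = as.integer(P), T_rep = as.integer(T_rep),
                 train_fraction = train_fraction, K = as.integer(K),
                 max_lv = as.integer(max_lv),
                 spectra_per_patient_draw = as.integer(spectra_per_patient_draw),
                 balance_patient_sampling = match.arg(balance_patient_sampling),
                 threshold = threshold, positive_class = positive_class,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Bootstrap class balancing
#'
#' Randomly samples patients of the larger class down to the smaller
#' class's patient count (without replacement by default), then draws
#' `spectra_per_patient_draw` replicate spectra within every retained
#' patient of both classes -- without replacement when the patient has
#' enough replicates, with replacement otherwise.  Uses the caller's RNG
#' stream.
#'
#' @param ds A two-class [sers_dataset()].
#' @param cfg A [protocol_config()].
#' @return A balanced [sers_dataset()] with equal patient counts per
#'   class.  Re-drawn spectra of one patient get unique suffixed ids
#'   when drawn with replacement.
#' @export
balance_classes <- function(ds, cfg = protocol_config()) {
  cls_map <- class_of_patients(ds)
  classes <- sort(unique(cls_map))
  if (length(classes) != 2)
    stop_("balance_classes: need exactly 2 classes (got %d)", length(classes))
  n_by <- table(factor(cls_map, classes))
  if (any(n_by == 0)) stop_("balance_classes: a class has zero patients")
  n_keep <- min(n_by)
  keep <- unlist(lapply(classes, function(cl) {
    pats <- names(cls_map)[cls_map == cl]
    if (cfg$balance_patient_sampling == "with")
      sample(pats, n_keep, replace = TRUE)
    else if (length(pats) > n_keep) sample(pats, n_keep)
    else pats
  }))
  draw <- cfg$spectra_per_patient_draw
  rows <- integer(0); dup_tag <- character(0)
  for (pid in keep) {
    idx <- which(ds$meta$patient_id == pid)
    take <- if (length(idx) >= draw) sample(idx, draw)
            else sample(idx, draw, replace = TRUE)
    rows <- c(rows, take)
    dup_tag <- c(dup_tag, rep(pid, draw))
  }
  meta <- ds$meta[rows, , drop = FALSE]
  # unique ids for rows drawn more than once (replacement path)
  meta$spectrum_id <- make.unique(meta$spectrum_id, sep = "_r")
  sers_dataset(ds$intensities[rows, , drop = FALSE], ds$axis, meta)
}

#' Patient-wise train/test split
#'
#' Assigns whole patients to the training side until its spectra count
#' is the feasible count closest to `train_fraction * total` (ties going
#' to the larger training set), under the constraint that both classes
#' are represented on both sides.  Uses the caller's RNG stream.
#'
#' @param ds A two-class [sers_dataset()].
#' @param train_fraction Target training fraction of spectra.
#' @return List with `train` and `test` datasets (disjoint patients).
#' @export
patient_split <- function(ds, train_fraction = 0.8) {
  cls_map <- class_of_patients(ds)
  classes <- sort(unique(cls_map))
  if (length(classes) != 2)
    stop_("patient_split: need exactly 2 classes")
  pats <- lapply(classes, function(cl) sample(names(cls_map)[cls_map == cl]))
  if (any(lengths(pats) < 2))
    stop_("patient_split: need >= 2 patients per class to keep both classes on both sides")
  cum1 <- cumsum(vapply(pats[[1]], function(p) sum(ds$meta$patient_id == p),
                        integer(1)))
  cum2 <- cumsum(vapply(pats[[2]], function(p) sum(ds$meta$patient_id == p),
                        integer(1)))
  target <- train_fraction * nrow(ds$intensities)
  n1 <- length(pats[[1]]); n2 <- length(pats[[2]])
  best <- NULL
  for (m1 in seq_len(n1 - 1L))
    for (m2 in seq_len(n2 - 1L)) {
      cnt <- cum1[m1] + cum2[m2]
      d <- abs(cnt - target)
      # primary: spectra count nearest the target; ties toward the larger
      # training set; equal-count ties toward class-proportional patient
      # allocation (keeps train/test composition unbiased)
      bal <- abs(m1 / n1 - m2 / n2)
      if (is.null(best) || d < best$d - 1e-9 ||
          (abs(d - best$d) <= 1e-9 &&
           (cnt > best$cnt ||
            (cnt == best$cnt && bal < best$bal - 1e-12))))
        best <- list(m1 = m1, m2 = m2, d = d, cnt = cnt, bal = bal)
    }
  train_pats <- c(pats[[1]][seq_len(best$m1)], pats[[2]][seq_len(best$m2)])
  list(train = subset_patients(ds, train_pats),
       test = subset_patients(ds, setdiff(names(cls_map), train_pats)))
}

#' Run the full resampling protocol
#'
#' For each of the `P * T_rep` folds: fresh bootstrap balancing, fresh
#' patient-wise split, LV selection by patient-grouped K-fold CV on the
#' training set, PLS-DA fit, and evaluation of sensitivity, specificity,
#' accuracy and ROC/AUC on both the training and the test spectra, plus
#' the fold's VIP profile.  Fully reproducible from `cfg$seed`.
#'
#' @param ds A preprocessed two-class [sers_dataset()].
#' @param cfg A [protocol_config()].
#' @return An object of class `sers_protocol`: list with `folds` (one
#'   `fold_result` per (p, t)), `axis`, `config`, `positive_class`.
#' @export
run_protocol <- function(ds, cfg = protocol_config()) {
  stopifnot(inherits(ds, "sers_dataset"))
  cls_map <- class_of_patients(ds)
  classes <- sort(unique(cls_map))
  if (length(classes) != 2)
    stop_("run_protocol: need exactly 2 classes (got %d)", length(classes))
  positive <- cfg$positive_class %||%
    names(which.min(table(factor(cls_map, classes))))
  folds <- vector("list", cfg$P * cfg$T_rep)
  i <- 0L
  for (p in seq_len(cfg$P)) for (t in seq_len(cfg$T_rep)) {
    i <- i + 1L
    fold_seed <- child_seed(cfg$seed, sprintf("fold_p%d_t%d", p, t))
    folds[[i]] <- with_seed(fold_seed, tryCatch(
      run_one_fold(ds, cfg, positive, p, t),
      error = function(e)
        stop_("run_protocol: fold (p=%d, t=%d): %s", p, t,
              conditionMessage(e))))
  }
  structure(list(folds = folds, axis = ds$axis, config = cfg,
                 positive_class = positive),
            class = "sers_protocol")
}

run_one_fold <- function(ds, cfg, positive, p, t) {
  bal <- balance_classes(ds, cfg)
  sp <- patient_split(bal, cfg$train_fraction)
  tr <- sp$train; te <- sp$test
  y_tr <- class_response(tr, positive)
  curve <- cv_rmse(tr$intensities, y_tr, tr$meta$patient_id,
                   max_lv = cfg$max_lv, K = min(cfg$K,
                     length(unique(tr$meta$patient_id))))
  n_lv <- select_n_lv(curve)
  model <- plsda(tr$intensities, y_tr, ncomp = n_lv,
                 threshold = cfg$threshold)
  eval_side <- function(side) {
    y <- class_response(side, positive)
    sc <- predict_scores(model, side$intensities)
    m <- confusion(y, classify(sc, cfg$threshold))
    list(metrics = m, roc = roc_curve(sc, y))
  }
  ev_tr <- eval_side(tr); ev_te <- eval_side(te)
  structure(list(fold_id = c(p = p, t = t), n_lv_used = n_lv,
                 train_metrics = ev_tr$metrics, test_metrics = ev_te$metrics,
                 train_roc = ev_tr$roc, test_roc = ev_te$roc,
                 vip = vip(model), rmse_curve = curve,
                 train_patient_ids = unique(tr$meta$patient_id),
                 test_patient_ids = unique(te$meta$patient_id)),
            class = "fold_result")
}

#' @export
print.sers_protocol <- function(x, ...) {
  cat(sprintf("<sers_protocol> %d folds (P=%d, T=%d), positive class '%s'\n",
              length(x$folds), x$config$P, x$config$T_rep, x$positive_class))
  print(summary(x))
  invisible(x)
}

#' Aggregate fold results into a mean (min-max) summary
#'
#' @param results A `sers_protocol` object or bare list of `fold_result`s.
#' @param ... Unused.
#' @return An object of class `protocol_summary`: `table` (data frame
#'   with one row per set x metric and columns mean/min/max), `mean_vip`
#'   (element-wise mean of the fold VIP vectors), `n_folds`, `n_lv_used`,
#'   `positive_class`, `axis`.
#' @export
aggregate_folds <- function(results, ...) {
  axis <- NULL; positive <- NA_character_
  if (inherits(results, "sers_protocol")) {
    axis <- results$axis
    positive <- results$positive_class
    results <- results$folds
  }
  if (length(results) == 0) stop_("aggregate_folds: no folds")
  get_metric <- function(set, metric) vapply(results, function(f) {
    fm <- f[[paste0(set, "_metrics")]]
    if (metric == "roc_auc") f[[paste0(set, "_roc")]]$auc else fm[[metric]]
  }, numeric(1))
  metrics <- c("specificity", "sensitivity", "accuracy", "roc_auc")
  rows <- list()
  for (set in c("train", "test")) for (m in metrics) {
    v <- get_metric(set, m)
    rows[[paste(set, m)]] <- data.frame(
      set = set, metric = m, mean = mean(v), min = min(v), max = max(v))
  }
  vips <- vapply(results, `[[`, numeric(length(results[[1]]$vip)), "vip")
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 mean_vip = rowMeans(vips),
                 n_folds = length(results),
                 n_lv_used = vapply(results, `[[`, numeric(1), "n_lv_used"),
                 positive_class = positive, axis = axis),
            class = "protocol_summary")
}

#' @export
summary.sers_protocol <- function(object, ...) aggregate_folds(object)

#' @export
print.protocol_summary <- function(x, ...) {
  cat(sprintf("Protocol summary over %d folds (positive class: %s)\n",
              x$n_folds, x$positive_class))
  cat(sprintf("LVs used per fold: %s\n",
              paste(range(x$n_lv_used), collapse = "-")))
  tab <- x$table
  tab$cell <- sprintf("%.2f (%.2f-%.2f)", tab$mean, tab$min, tab$max)
  wide <- reshape_cells(tab)
  print(wide, row.names = FALSE)
  invisible(x)
}

# tiny pivot (base R, no reshape dependency)
reshape_cells <- function(tab) {
  sets <- unique(tab$set)
  out <- data.frame(set = sets)
  for (m in unique(tab$metric))
    out[[m]] <- vapply(sets, function(s)
      tab$cell[tab$set == s & tab$metric == m], character(1))
  out
}

#' @export
plot.sers_protocol <- function(x, ...) {
  s <- aggregate_folds(x)
  plot(as.numeric(s$axis), s$mean_vip, type = "l",
       xlab = "wavenumber (cm^-1)", ylab = "mean VIP",
       main = sprintf("Mean VIP over %d folds", s$n_folds), ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Band-level report of the mean VIP profile
#'
#' For every band of a peak library, reports the maximum of the
#' mean-VIP profile within `center +/- window_cm1` and its rank among
#' the library bands (rank 1 = most important).
#'
#' @param summary A `protocol_summary` (from [aggregate_folds()]).
#' @param peak_library List of [peak_spec()]s; default
#'   [default_peak_library()].
#' @param window_cm1 Half-window around each band centre, in cm^-1;
#'   0 looks up the single nearest grid point.
#' @return Data frame with columns `band`, `assignment`, `mean_vip`,
#'   `rank`, ordered by band centre.
#' @export
vip_band_report <- function(summary, peak_library = default_peak_library(),
                            window_cm1 = 10) {
  if (is.null(summary$mean_vip)) stop_("vip_band_report: no mean VIP present")
  ax <- as.numeric(summary$axis)
  v <- vapply(peak_library, function(p) {
    if (window_cm1 <= 0) idx <- which.min(abs(ax - p$center))
    else {
      idx <- which(ax >= p$center - window_cm1 & ax <= p$center + window_cm1)
      if (!length(idx)) idx <- which.min(abs(ax - p$center))
    }
    max(summary$mean_vip[idx])
  }, numeric(1))
  data.frame(band = vapply(peak_library, `[[`, numeric(1), "center"),
             assignment = vapply(peak_library, `[[`, character(1),
                                 "assignment"),
             mean_vip = v,
             rank = rank(-v, ties.method = "min"))
}
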