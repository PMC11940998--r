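# Patient-grouped cross-validation for LV selection.  Folds partition
# patients, never spectra: replicates of one subject stay together, so
# the CV error reflects performance on unseen patients.

#' Cross-validated RMSE per latent-variable count
#'
#' Splits patients into `K` folds (shuffled with the current RNG stream),
#' refits the PLS model on each training part and pools the held-out
#' squared prediction errors of the continuous score for every candidate
#' LV count `1..max_lv`.
#'
#' @param x Predictor matrix, spectra in rows.
#' @param y 0/1 (or continuous) response vector.
#' @param patient_ids Grouping vector, one entry per row of `x`.
#' @param max_lv Largest LV count to evaluate; silently capped at the
#'   rank bound of the smallest training fold.
#' @param K Number of folds (>= 2, <= number of patients).
#' @return An object of class `rmse_curve`: list with `rmse` (vector
#'   indexed by LV count) and `max_lv`.
#' @export
cv_rmse <- function(x, y, patient_ids, max_lv = 15L, K = 10L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(patient_ids) != nrow(x))
    stop_("cv_rmse: %d patient ids for %d rows", length(patient_ids), nrow(x))
  patients <- unique(as.character(patient_ids))
  if (K < 2) stop_("cv_rmse: K must be >= 2")
  if (length(patients) < K)
    stop_("cv_rmse: only %d patients for K = %d folds", length(patients), K)
  fold_of <- setNames(rep_len(seq_len(K), length(patients)),
                      sample(patients))
  idx_fold <- fold_of[as.character(patient_ids)]
  # rank bound over the worst training fold
  min_train <- min(vapply(seq_len(K), function(k) sum(idx_fold != k),
                          integer(1)))
  max_lv <- min(as.integer(max_lv), min_train - 1L, ncol(x))
  if (max_lv < 1L) stop_("cv_rmse: no feasible LV count")
  sse <- numeric(max_lv); n_tot <- 0L
  for (k in seq_len(K)) {
    tr <- idx_fold != k
    if (all(tr) || !any(tr)) next
    xm <- colMeans(x[tr, , drop = FALSE])
    ym <- mean(y[tr])
    core <- pls1_core(sweep(x[tr, , drop = FALSE], 2, xm), y[tr] - ym,
                      max_lv, strict = FALSE)
    pred <- sweep(x[!tr, , drop = FALSE], 2, xm) %*% core$B + ym
    sse <- sse + colSums((pred - y[!tr])^2)
    n_tot <- n_tot + sum(!tr)
  }
  structure(list(rmse = sqrt(sse / n_tot), max_lv = max_lv),
            class = "rmse_curve")
}

#' First-local-minimum rule for choosing the LV count
#'
#' Returns the smallest LV count `i` that is a local minimum of the RMSE
#' curve: `rmse[i] < rmse[i-1]` (vacuous at `i = 1`) and
#' `rmse[i] <= rmse[i+1]` (vacuous at the last index).  A curve that
#' decreases monotonically throughout therefore yields its global
#' minimum (the last index).  The result is unchanged by whatever the
#' curve does after the selected minimum.
#'
#' @param curve An `rmse_curve` from [cv_rmse()], or a bare numeric
#'   vector of RMSE values indexed by LV count.
#' @return Integer LV count.
#' @examples
#' select_n_lv(c(1.0, 0.8, 0.9, 0.7))  # 2
#' select_n_lv(c(0.5, 0.6, 0.4))       # 1
#' @export
select_n_lv <- function(curve) {
  r <- if (inherits(curve, "rmse_curve")) curve$rmse else as.numeric(curve)
  n <- length(r)
  if (n == 0) stop_("select_n_lv: empty RMSE curve")
  for (i in seq_len(n)) {
    down <- i == 1L || r[i] < r[i - 1L]
    flat_ok <- i == n || r[i] <= r[i + 1L]
    if (down && flat_ok) return(i)
  }
  which.min(r)  # unreachable for finite curves; defensive
}
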