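# PLS1 via NIPALS deflation, written for a univariate 0/1 response: the
# weight vector of each component is closed-form (X'y normalised), so no
# inner iteration is needed.  Predictors are mean-centred on the training
# set only; spectra arrive SNV-normalised, so no column autoscaling.

# Core extraction on pre-centred X, y.  Returns weights W, loadings P,
# response loadings q, scores Tsc, scores basis R and per-component
# response sum of squares explained (ssy), plus cumulative coefficient
# columns B[, a] for models truncated at a components.
pls1_core <- function(Xc, yc, n_lv, strict = TRUE) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, n_lv)
  B <- matrix(0, p, n_lv)
  Tsc <- matrix(0, n, n_lv)
  q <- ssy <- numeric(n_lv)
  Xa <- Xc; ya <- yc
  n_used <- n_lv
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (strict)
        stop_("PLS: no residual covariance left at component %d", a)
      # covariance exhausted: later components change nothing; freeze the
      # coefficient path so every candidate LV count stays defined
      n_used <- a - 1L
      if (n_used == 0L)
        stop_("PLS: response has no covariance with any predictor")
      break
    }
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    Tsc[, a] <- t_a
    ssy[a] <- q_a^2 * tt
  }
  # R maps raw centred predictors to scores: Tsc = Xc %*% R
  use <- seq_len(n_used)
  W <- W[, use, drop = FALSE]; P <- P[, use, drop = FALSE]
  Tsc <- Tsc[, use, drop = FALSE]; q <- q[use]; ssy <- ssy[use]
  R <- W %*% solve(crossprod(P, W))
  for (a in use)
    B[, a] <- (if (a > 1) B[, a - 1] else 0) + R[, a] * q[a]
  if (n_used >= 1L && n_used < n_lv)
    for (aa in (n_used + 1L):n_lv) B[, aa] <- B[, n_used]
  list(W = W, P_load = P, q = q, R = R, Tsc = Tsc, ssy = ssy, B = B,
       n_used = n_used)
}

#' Fit a PLS-DA model
#'
#' Regresses a two-class response, coded 0/1, on the spectra matrix with
#' partial least squares (NIPALS deflation) and classifies by
#' thresholding the continuous predicted score.  When `ncomp` is `NULL`
#' the number of latent variables (LVs) is chosen by patient-grouped
#' K-fold cross-validation via [cv_rmse()] and [select_n_lv()].
#'
#' @param x Numeric matrix, spectra in rows, predictors in columns.
#' @param y Response: a factor/character with two levels, or a 0/1
#'   numeric vector.
#' @param ncomp Number of LVs; `NULL` to select by cross-validation.
#' @param positive_class Label coded as 1 (scored class).  Defaults to
#'   the second level of `factor(y)` when `y` is not already 0/1.
#' @param max_lv Upper bound of the LV search when `ncomp` is `NULL`.
#' @param K Number of cross-validation folds.
#' @param patient_ids Grouping vector for the CV folds (replicates of one
#'   patient never straddle folds); defaults to one group per row.
#' @param threshold Classification threshold on the continuous score.
#' @return An object of class `plsda` with components `n_lv`, `x_mean`,
#'   `y_mean`, `weights`, `loadings`, `q`, `scores_basis`, `scores`,
#'   `coefficients`, `ssy`, `class_codes`, `threshold`, and (when CV was
#'   run) `cv` containing the RMSE curve.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 6), 40)
#' y <- rep(0:1, each = 20)
#' X[, 2] <- X[, 2] + y          # informative column
#' m <- plsda(X, y, ncomp = 2)
#' table(predict(m, X, type = "class"), y)
#' @export
plsda <- function(x, y, ncomp = NULL, positive_class = NULL,
                  max_lv = 15L, K = 10L, patient_ids = NULL,
                  threshold = 0.5) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  cod <- code_response(y, positive_class)
  y01 <- cod$y
  if (length(y01) != nrow(x))
    stop_("plsda: %d responses for %d spectra", length(y01), nrow(x))
  if (min(table(y01)) < 2)
    stop_("plsda: need at least 2 samples in each class")
  cap <- min(nrow(x) - 1L, ncol(x))
  cv <- NULL
  if (is.null(ncomp)) {
    if (is.null(patient_ids)) patient_ids <- paste0("row", seq_len(nrow(x)))
    cv <- cv_rmse(x, y01, patient_ids, max_lv = min(max_lv, cap), K = K)
    ncomp <- select_n_lv(cv)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > cap)
    stop_("plsda: ncomp = %d outside feasible range 1..%d", ncomp, cap)
  x_mean <- colMeans(x)
  y_mean <- mean(y01)
  core <- pls1_core(sweep(x, 2, x_mean), y01 - y_mean, ncomp)
  structure(list(n_lv = ncomp, x_mean = x_mean, y_mean = y_mean,
                 weights = core$W, loadings = core$P_load, q = core$q,
                 scores_basis = core$R, scores = core$Tsc,
                 coefficients = core$B[, ncomp],
                 coef_path = core$B, ssy = core$ssy,
                 class_codes = cod$codes, threshold = threshold,
                 cv = cv, n_obs = nrow(x), y = y01),
            class = "plsda")
}

# map an arbitrary 2-level response to 0/1 plus a label->code map
code_response <- function(y, positive_class = NULL) {
  if (is.numeric(y) && all(y %in% c(0, 1)) && is.null(positive_class))
    return(list(y = as.numeric(y), codes = c("0" = 0, "1" = 1)))
  f <- as.character(y)
  lev <- sort(unique(f))
  if (length(lev) != 2)
    stop_("plsda: response must have exactly 2 classes (got %d)",
          length(lev))
  if (is.null(positive_class)) positive_class <- lev[2]
  if (!positive_class %in% lev)
    stop_("plsda: positive class '%s' not among response levels",
          positive_class)
  codes <- setNames(as.numeric(lev == positive_class), lev)
  list(y = unname(codes[f]), codes = codes)
}

#' Continuous PLS scores for new spectra
#'
#' @param model A fitted [plsda()] object.
#' @param x Matrix with the model's predictor count.
#' @return Numeric vector `(x - x_mean) %*% b + y_mean`, one per row.
#' @export
predict_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$x_mean))
    stop_("predict_scores: %d predictors, model expects %d",
          ncol(x), length(model$x_mean))
  drop(sweep(x, 2, model$x_mean) %*% model$coefficients) + model$y_mean
}

#' Threshold continuous scores into class labels
#'
#' @param scores Numeric scores.
#' @param threshold Decision threshold; ties go to class 1.
#' @return Integer 0/1 vector: 1 iff `score >= threshold`.
#' @export
classify <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}

#' @export
#' @rdname plsda
#' @param object,model A fitted `plsda` object.
#' @param newdata Spectra matrix to predict for (training scores-basis
#'   predictors when omitted is not stored; supply the matrix).
#' @param type `"score"` for the continuous response, `"class"` for the
#'   thresholded 0/1 code, `"label"` for original class labels.
#' @param ... Unused.
predict.plsda <- function(object, newdata, type = c("score", "class", "label"),
                          ...) {
  type <- match.arg(type)
  sc <- predict_scores(object, newdata)
  if (type == "score") return(sc)
  cl <- classify(sc, object$threshold)
  if (type == "class") return(cl)
  labs <- names(object$class_codes)
  labs[match(cl, object$class_codes)]
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variable(s), %d predictors, %d training spectra\n",
              x$n_lv, length(x$x_mean), x$n_obs))
  cat(sprintf("  classes: %s (coded %s); threshold %.3g\n",
              paste(names(x$class_codes), collapse = " vs "),
              paste(x$class_codes, collapse = "/"), x$threshold))
  if (!is.null(x$cv))
    cat(sprintf("  LV count chosen at first local minimum of CV RMSE (curve length %d)\n",
                length(x$cv$rmse)))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  expl <- object$ssy / sum(object$ssy)
  out <- list(n_lv = object$n_lv,
              ssy = object$ssy, prop_ssy = expl,
              vip = vip(object), cv = object$cv,
              class_codes = object$class_codes)
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA with %d latent variables\n", x$n_lv))
  cat("Response sum-of-squares explained per LV (proportion):\n")
  print(round(x$prop_ssy, 4))
  cat(sprintf("VIP scores: %d predictors, %d with VIP > 1\n",
              length(x$vip), sum(x$vip > 1)))
  invisible(x)
}

#' @export
fitted.plsda <- function(object, ...) {
  drop(object$scores %*% object$q) + object$y_mean
}

#' @export
residuals.plsda <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
#' @rdname plsda
#' @param which `"rmse"` plots the cross-validation RMSE curve with the
#'   selected LV count; `"coefficients"` the regression vector;
#'   `"vip"` the VIP profile.
#' @param axis Optional wavenumber axis for the x coordinate of
#'   coefficient/VIP plots.
plot.plsda <- function(x, which = c("rmse", "coefficients", "vip"),
                       axis = NULL, ...) {
  which <- match.arg(which)
  if (which == "rmse") {
    if (is.null(x$cv)) stop_("plot.plsda: no CV curve stored (ncomp was fixed)")
    plot(seq_along(x$cv$rmse), x$cv$rmse, type = "b", xlab = "latent variables",
         ylab = "CV RMSE", main = "LV selection", ...)
    abline(v = x$n_lv, lty = 2)
  } else {
    v <- if (which == "vip") vip(x) else x$coefficients
    xx <- if (is.null(axis)) seq_along(v) else as.numeric(axis)
    plot(xx, v, type = "l",
         xlab = if (is.null(axis)) "predictor" else "wavenumber (cm^-1)",
         ylab = which, main = paste("PLS-DA", which), ...)
    if (which == "vip") abline(h = 1, lty = 3)
  }
  invisible(x)
}
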