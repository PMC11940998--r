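# Shared fixtures: small synthetic cohorts and reference implementations
# used as independent oracles.

tiny_classes <- function(n1 = 4, n2 = 5, spp = 3,
                         labels = c("case", "ref")) {
  data.frame(label = labels, n_patients = c(n1, n2),
             spectra_per_patient = c(spp, spp))
}

# short-axis config so per-test generation stays fast
tiny_config <- function(n1 = 4, n2 = 5, spp = 3, seed = 1, n_points = 200,
                        ...) {
  synthetic_config(classes = tiny_classes(n1, n2, spp),
                   axis = wavenumber_axis(517, 1913, n_points),
                   peaks = default_peak_library("case", "ref"),
                   seed = seed, ...)
}

tiny_preprocess <- function(n_points = 200) {
  preprocess_config(baseline_degree = 7)
}

# brute-force Savitzky-Golay oracle: direct least-squares polynomial fit
# over each centred window, evaluated at the centre point
sg_oracle <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    idx <- (i - h):(i + h)
    fit <- lm.fit(outer(idx - i, 0:polyorder, `^`), y[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

# O(n^2) pairwise-concordance AUC oracle (ties counted one half)
auc_oracle <- function(scores, labels, positive = 1) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# minimal reference NIPALS written independently of the package internals
# (explicit per-component loop, no coefficient-path bookkeeping)
ref_pls1_coef <- function(X, y, a_max) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- NULL; q <- c()
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    q_ <- sum(f * t_) / sum(t_^2)
    E <- E - outer(t_, p_)
    f <- f - q_ * t_
    W <- cbind(W, w); P <- cbind(P, p_); q <- c(q, q_)
  }
  b <- W %*% solve(t(P) %*% W) %*% q
  list(b = drop(b), x_mean = xm, y_mean = ym)
}

ref_pls1_predict <- function(ref, X) {
  drop(sweep(X, 2, ref$x_mean) %*% ref$b) + ref$y_mean
}
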