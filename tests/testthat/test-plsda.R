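test_that("single informative predictor is fitted exactly with one LV", {
  y <- rep(c(0, 1), each = 5)
  X <- cbind(y - mean(y))
  m <- plsda(X, y, ncomp = 1)
  expect_equal(predict_scores(m, X), y, tolerance = 1e-12)
  expect_equal(fitted(m), y, tolerance = 1e-12)
  expect_equal(residuals(m), rep(0, 10), tolerance = 1e-12)
})

test_that("full-rank PLS coefficients equal the least-squares solution", {
  set.seed(101)
  for (rep in 1:10) {
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- rep(c(0, 1), 3)
    m <- plsda(X, y, ncomp = 4)
    Xc <- sweep(X, 2, colMeans(X))
    b_ls <- qr.solve(Xc, y - mean(y))
    expect_equal(unname(m$coefficients), unname(b_ls), tolerance = 1e-6)
  }
})

test_that("predictors orthogonal to the response get zero LV1 weight", {
  set.seed(5)
  y <- rep(c(0, 1), each = 10)
  x1 <- y - mean(y)
  x2 <- rnorm(20)
  x2 <- residuals(lm.fit(cbind(1, y), x2))  # exactly orthogonal to y
  m <- plsda(cbind(x1, x2), y, ncomp = 1)
  expect_lt(abs(m$weights[2, 1]), 1e-10)
})

test_that("score vectors of distinct LVs are orthogonal and both prediction routes agree", {
  set.seed(77)
  X <- matrix(rnorm(30 * 12), 30)
  y <- rep(c(0, 1), 15)
  m <- plsda(X, y, ncomp = 5)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # coefficient route equals sequential LV reconstruction
  via_b <- predict_scores(m, X)
  via_scores <- drop(sweep(X, 2, m$x_mean) %*% m$scores_basis %*% m$q) +
    m$y_mean
  expect_equal(via_b, via_scores, tolerance = 1e-8)
})

test_that("prediction follows the centering identity and rejects bad input", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rep(c(0, 1), each = 10)
  m <- plsda(X, y, ncomp = 3)
  expect_equal(predict_scores(m, rbind(m$x_mean)), m$y_mean)
  perm <- sample(20)
  expect_equal(predict_scores(m, X[perm, ]), predict_scores(m, X)[perm])
  expect_error(predict_scores(m, X[, 1:3]), "predictors")
  expect_error(plsda(X, y, ncomp = 25), "feasible range")
  expect_error(plsda(X, c(rep(0, 19), 1), ncomp = 2), "2 samples")
  expect_error(plsda(X, rep(c("a", "b", "c"), length.out = 20)),
               "exactly 2 classes")
})

test_that("classify thresholds scores with ties going to class 1", {
  expect_equal(classify(c(0.9, 0.1)), c(1L, 0L))
  expect_equal(classify(0.5), 1L)
  expect_equal(classify(c(0.2, 0.8), threshold = 0.1), c(1L, 1L))
  # label mapping through the model's class codes
  y <- rep(c("chf", "resp"), each = 5)
  X <- cbind(as.numeric(y == "resp") + rnorm(10, 0, 1e-8))
  m <- plsda(X, y, ncomp = 1, positive_class = "resp")
  expect_equal(predict(m, X, type = "label"), y)
})

test_that("cross-validated RMSE matches a brute-force per-fold refit oracle", {
  set.seed(31)
  n_pat <- 12; spp <- 2; K <- 4; max_lv <- 3
  pid <- rep(sprintf("p%02d", 1:n_pat), each = spp)
  X <- matrix(rnorm(n_pat * spp * 8), n_pat * spp)
  y <- rep(rep(c(0, 1), n_pat / 2), each = spp)
  X[, 1] <- X[, 1] + 2 * y

  seed <- 99
  got <- sersclass:::with_seed(seed, cv_rmse(X, y, pid, max_lv, K))
  # replay the fold assignment, then refit with the reference NIPALS
  fold_of <- sersclass:::with_seed(seed, {
    pats <- unique(pid)
    setNames(rep_len(seq_len(K), length(pats)), sample(pats))
  })
  idx_fold <- fold_of[pid]
  sse <- numeric(max_lv); n_tot <- 0
  for (k in seq_len(K)) {
    tr <- idx_fold != k
    for (a in seq_len(max_lv)) {
      ref <- ref_pls1_coef(X[tr, ], y[tr], a)
      sse[a] <- sse[a] + sum((ref_pls1_predict(ref, X[!tr, ]) - y[!tr])^2)
    }
    n_tot <- n_tot + sum(!tr)
  }
  expect_equal(got$rmse, sqrt(sse / n_tot), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cv folds never split a patient and a perfect predictor gives near-zero RMSE at 1 LV", {
  pid <- rep(sprintf("p%d", 1:10), each = 3)
  y <- rep(rep(c(0, 1), 5), each = 3)
  X <- cbind(y, matrix(rnorm(30 * 3, 0, 1e-6), 30))
  curve <- sersclass:::with_seed(2, cv_rmse(X, y, pid, max_lv = 2, K = 5))
  expect_lt(curve$rmse[1], 1e-3)
  expect_error(cv_rmse(X, y, pid, max_lv = 2, K = 11), "patients")
})

test_that("first-local-minimum LV selection follows the stated rule", {
  expect_equal(select_n_lv(c(1.0, 0.8, 0.9, 0.7)), 2)
  expect_equal(select_n_lv(c(0.5, 0.6, 0.4)), 1)
  expect_equal(select_n_lv(c(1.0, 0.9, 0.8)), 3)
  expect_equal(select_n_lv(c(2)), 1)
  expect_error(select_n_lv(numeric(0)), "empty")
  # invariance to whatever is appended after the selected minimum
  base <- c(1.0, 0.8, 0.9)
  sel <- select_n_lv(base)  # 2
  for (tail_vals in list(0.1, c(5, 0.01), c(0.85, 0.2, 0.9)))
    expect_equal(select_n_lv(c(base, tail_vals)), sel)
})

test_that("VIP obeys its mean-square normalization and symmetry identities", {
  set.seed(55)
  X <- matrix(rnorm(24 * 9), 24)
  y <- rep(c(0, 1), 12)
  for (a in c(1, 3, 5)) {
    v <- vip(plsda(X, y, ncomp = a))
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
  # identical predictor copies share VIP = 1
  z <- rnorm(24) + y
  Xc <- cbind(z, z, z, z)
  vc <- vip(plsda(Xc, y, ncomp = 1))
  expect_equal(vc, rep(1, 4), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("VIP singles out the informative predictor among noise", {
  set.seed(123)
  y <- rep(c(0, 1), each = 15)
  X <- matrix(rnorm(30 * 20), 30)
  X[, 7] <- X[, 7] + 2 * y
  m <- plsda(X, y, ncomp = 2)
  v <- vip(m)
  expect_equal(which.max(v), 7L)
  expect_gt(v[7], 1)
})

test_that("automatic LV selection is wired through the fitting front end", {
  set.seed(9)
  pid <- rep(sprintf("p%d", 1:16), each = 2)
  y <- rep(rep(c(0, 1), 8), each = 2)
  X <- matrix(rnorm(32 * 10), 32)
  X[, 3] <- X[, 3] + 1.5 * y
  m <- sersclass:::with_seed(4,
    plsda(X, y, max_lv = 6, K = 4, patient_ids = pid))
  expect_s3_class(m$cv, "rmse_curve")
  expect_equal(m$n_lv, select_n_lv(m$cv))
})
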