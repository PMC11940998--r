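#' Variable importance in projection (VIP)
#'
#' For predictor `j` over components `a = 1..A`:
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a )`,
#' where `p` is the predictor count and `SSY_a` the response sum of
#' squares explained by component `a` (`q_a^2 t_a't_a`).  By
#' construction the mean of the squared VIPs is exactly 1, so predictors
#' with VIP > 1 contribute more than average to the discrimination.
#'
#' @param model A fitted [plsda()] object.
#' @param ... Unused.
#' @return Numeric vector of length `p`.
#' @export
vip <- function(model, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.plsda <- function(model, ...) {
  ssy <- model$ssy
  tot <- sum(ssy)
  if (!is.finite(tot) || tot <= 0)
    stop_("vip: zero total explained response variance")
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), `/`)   # (w_ja / ||w_a||)^2
  p <- nrow(W)
  sqrt(p * drop(wn2 %*% ssy) / tot)
}

#' @rdname vip
#' @param x Ignored (training data is stored in the model).
#' @param y Ignored.
#' @export
vip_scores <- function(model, x = NULL, y = NULL) vip(model)
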