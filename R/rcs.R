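#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis, linear beyond the boundary
#' knots, in the truncated-power parameterisation common in survival
#' regression. With three knots the basis has two columns: the identity and
#' one nonlinear term
#' \deqn{[(x-k_1)_+^3 - (x-k_2)_+^3 (k_3-k_1)/(k_3-k_2)
#'        + (x-k_3)_+^3 (k_2-k_1)/(k_3-k_2)] / (k_3-k_1)^2.}
#' Default knots sit at the 10th, 50th and 90th empirical centiles.
#'
#' @param x numeric vector with at least three distinct values (unless
#'   `knots` is supplied).
#' @param knots optional increasing knot vector; defaults to the
#'   10/50/90 centiles of `x`.
#' @return matrix with `length(knots) - 1` columns and attribute `knots`.
#' @export
rcs_basis <- function(x, knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(x[!is.na(x)])) < 3L)
      stopf("rcs_basis needs at least 3 distinct values to place knots")
    knots <- unname(quantile(x, c(0.1, 0.5, 0.9), na.rm = TRUE))
  }
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3L || anyDuplicated(knots))
    stopf("rcs_basis needs at least 3 distinct knots")
  pos3 <- function(u) pmax(u, 0)^3
  kn <- knots[k]; kn1 <- knots[k - 1L]
  norm <- (kn - knots[1])^2
  B <- matrix(x, ncol = 1L)
  for (j in seq_len(k - 2L)) {
    B <- cbind(B, (pos3(x - knots[j]) -
                     pos3(x - kn1) * (kn - knots[j]) / (kn - kn1) +
                     pos3(x - kn) * (kn1 - knots[j]) / (kn - kn1)) / norm)
  }
  colnames(B) <- c("", paste0("'", seq_len(k - 2L)))
  attr(B, "knots") <- knots
  B
}
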