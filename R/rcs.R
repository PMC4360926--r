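# Restricted cubic spline basis (natural spline, truncated-power form).

#' Restricted cubic spline basis
#'
#' Builds the k-1 column truncated-power basis for a restricted (natural)
#' cubic spline with knots `t_1 < ... < t_k`: the raw values as the first
#' column, followed by k-2 nonlinear terms
#'
#' \deqn{C_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#'
#' for j = 1, ..., k-2. The construction is linear beyond the boundary
#' knots (second derivative zero outside `[t_1, t_k]`) and all nonlinear
#' columns vanish at and below the first knot. The `(t_k - t_1)^2`
#' normalisation keeps the columns on the scale of `x`.
#'
#' @param x numeric vector of values.
#' @param knots strictly ascending numeric vector, length >= 3.
#' @return numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns; column 1 equals `x`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3) stopf("restricted cubic splines need at least 3 knots (got %d)", k)
  if (any(diff(knots) <= 0)) stopf("knots must be strictly ascending")
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]
  tk1 <- knots[k - 1]
  norm <- (tk - knots[1])^2
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("x", seq_len(k - 2), "'"))
  out
}

#' Default knot placement quantiles
#'
#' Sample quantiles at which spline knots are placed, by knot count.
#' Interior knots are spread evenly; the boundary knots for k >= 5 sit far
#' out (0.5th/99.5th percentiles) so that the spline remains fully
#' supported across the sparse extremes of blood-pressure-like variables,
#' where risk cutoffs can lie beyond the bulk of the data and linear-tail
#' extrapolation would otherwise distort them.
#'
#' @param k number of knots (3 to 7).
#' @return numeric vector of probabilities, length `k`.
#' @export
default_knot_quantiles <- function(k) {
  switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.005, 0.275, 0.50, 0.725, 0.995),
    "6" = c(0.005, 0.20, 0.40, 0.60, 0.80, 0.995),
    "7" = c(0.005, 0.17, 0.33, 0.50, 0.67, 0.83, 0.995),
    stopf("unsupported knot count %s (use 3-7)", k)
  )
}
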