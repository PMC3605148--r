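#' Local polynomial regression with an SPH kernel
#'
#' Presentation smoother for sweep curves: at each evaluation point a
#' degree-`degree` polynomial is fitted by weighted least squares. Weights
#' combine the cubic-spline smoothing kernel used in smoothed-particle
#' hydrodynamics, with bandwidth set to the distance of the
#' `ceiling(nnFrac * n)`-th nearest neighbour, and a constant component
#' with weight `constFrac` so that remote points retain some influence.
#' Used for display only, never for inference.
#'
#' @param x,y data points (at least 5).
#' @param xout evaluation grid (default `x`).
#' @param degree polynomial degree (default 2).
#' @param nnFrac nearest-neighbour fraction defining the bandwidth.
#' @param constFrac weight of the constant kernel component.
#' @return data.frame with `x` and fitted `y`.
#' @export
smoothCurve <- function(x, y, xout = x, degree = 2, nnFrac = 0.5,
                        constFrac = 0.1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 points")
  n <- length(x)
  k <- max(degree + 1, ceiling(nnFrac * n))
  fit <- vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[min(k, n)]
    if (h <= 0) h <- max(d[d > 0], 1)
    q <- 2 * d / h # kernel support covers the nn range
    w <- ifelse(q <= 1, 1 - 1.5 * q^2 + 0.75 * q^3,
                ifelse(q <= 2, 0.25 * (2 - q)^3, 0))
    w <- (1 - constFrac) * w / max(sum(w), .Machine$double.eps) +
      constFrac / n
    X <- outer(x - x0, 0:degree, "^")
    beta <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * y)),
      error = function(e) qr.solve(sqrt(w) * X, sqrt(w) * y)
    )
    beta[1]
  }, numeric(1))
  data.frame(x = xout, y = fit)
}
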