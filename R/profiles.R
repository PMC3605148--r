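## Recombination-rate trajectories through time.
##
## All profiles are normalized so the time-average rate over the change
## window [0, windowT) equals meanRate; only the apportioning of
## recombination through time differs between shapes. Beyond the window every
## profile takes the background rate baseRate (by default the window mean),
## confining rate variation to the window.

# unnormalized shape u(t) on [0, windowT) and its window mean
profileShapeMean <- function(shape, direction, windowT, lambda, K, N0, g) {
  T <- windowT
  switch(shape,
    constant = 1,
    linear = T / 2,
    exponential = if (direction == "decreasing")
      (exp(lambda * T) - 1) / (lambda * T)
    else
      (1 - exp(-lambda * T)) / (lambda * T),
    logistic = {
      # (K/(gT)) * log(D(T)/K) with D(T) = K + N0 (e^{gT} - 1), written to
      # survive large gT: log D = gT + log N0 + log1p((K - N0) e^{-gT} / N0)
      lnD <- g * T + log(N0) + log1p((K - N0) * exp(-g * T) / N0)
      (K / (g * T)) * (lnD - log(K))
    }
  )
}

profileShapeEval <- function(shape, direction, t, windowT, lambda, K, N0, g) {
  T <- windowT
  # forward logistic, s measured from the low end of the curve; the
  # exp(-gs) form is stable for large gs
  L <- function(s) K / (1 + (K / N0 - 1) * exp(-g * s))
  switch(shape,
    constant = rep(1, length(t)),
    linear = if (direction == "decreasing") t else T - t,
    exponential = if (direction == "decreasing") exp(lambda * t)
                  else exp(-lambda * t),
    logistic = if (direction == "decreasing") L(t) else L(T - t)
  )
}

#' Construct a recombination-rate trajectory
#'
#' Builds a [RateProfile-class] of the given shape, normalized so that the
#' time-averaged rate over the change window equals `meanRate`. `direction`
#' is read toward the present: an `"increasing"` profile attains its maximum
#' at `t = 0` (the sampling generation) and its minimum at the ancient edge
#' of the window. The linear shape runs from 0 at one end of the window to
#' `2 * meanRate` at the other; exponential and logistic shapes follow
#' `exp(lambda t)` and the standard logistic growth curve
#' `K N0 e^{g s} / (K + N0 (e^{g s} - 1))` on the generation axis (mirrored
#' in time for the increasing direction), multiplicatively rescaled.
#'
#' @param shape `"constant"`, `"linear"`, `"exponential"` or `"logistic"`.
#' @param direction `"increasing"` or `"decreasing"` toward the present;
#'   ignored (`"na"`) for the constant shape.
#' @param meanRate mean rate over the window, events/bp/generation.
#' @param windowT change-window length in generations.
#' @param baseRate background rate beyond the window; defaults to `meanRate`.
#' @param lambda exponential rate constant (1/generation).
#' @param logisticK,logisticN0,logisticG logistic curve parameters.
#' @return a [RateProfile-class] object.
#' @examples
#' p <- makeProfile("linear", "decreasing")
#' evaluateRate(p, c(0, 5000, 1e4)) # 0 at present, 2 * meanRate at the window
#' @export
makeProfile <- function(shape = c("constant", "linear", "exponential", "logistic"),
                        direction = c("na", "increasing", "decreasing"),
                        meanRate = 3.75e-8, windowT = 1e4,
                        baseRate = meanRate,
                        lambda = 5e-4, logisticK = 100, logisticN0 = 1,
                        logisticG = 9e-4) {
  shape <- match.arg(shape)
  direction <- match.arg(direction)
  if (shape == "constant") direction <- "na"
  if (shape != "constant" && direction == "na")
    stop("direction must be 'increasing' or 'decreasing' for shape '",
         shape, "'")
  if (meanRate < 0) stop("meanRate must be nonnegative")
  if (meanRate == 0 && shape != "constant")
    stop("a zero mean rate is only meaningful for the constant shape")
  if (windowT <= 0) stop("windowT must be positive")
  meanU <- profileShapeMean(shape, direction, windowT, lambda, logisticK,
                            logisticN0, logisticG)
  new("RateProfile", shape = shape, direction = direction,
      meanRate = meanRate, windowT = windowT, baseRate = baseRate,
      lambda = lambda, logisticK = logisticK, logisticN0 = logisticN0,
      logisticG = logisticG, normC = meanRate / meanU)
}

#' Evaluate a rate profile
#'
#' Rate of `profile` at time `t` generations before present (vectorized).
#' For `t >= windowT` the background rate is returned.
#'
#' @param profile a [RateProfile-class].
#' @param t nonnegative times, generations before present.
#' @return rates in events/bp/generation.
#' @export
evaluateRate <- function(profile, t) {
  stopifnot(is(profile, "RateProfile"))
  if (any(t < 0)) stop("t must be nonnegative")
  out <- rep(profile@baseRate, length(t))
  inw <- t < profile@windowT
  if (any(inw)) {
    u <- profileShapeEval(profile@shape, profile@direction, t[inw],
                          profile@windowT, profile@lambda, profile@logisticK,
                          profile@logisticN0, profile@logisticG)
    out[inw] <- profile@normC * u
  }
  out
}

#' Discretize a profile into piecewise-constant epochs
#'
#' Tiles time with epochs of `step` generations over the remainder of the
#' change window, each taking the profile's midpoint rate, plus a final
#' unbounded epoch at the background rate. `offset` shifts the profile, as
#' seen by a sample taken `offset` generations before present. With the
#' default 20-generation step the integrated recombination over the window
#' is preserved to well within 1e-3 relative error for all shapes.
#'
#' @param profile a [RateProfile-class].
#' @param step epoch width in generations (default 20).
#' @param offset sampling time in generations before present.
#' @return data.frame with columns `tStart`, `tEnd` (last is `Inf`), `rate`.
#' @export
discretizeProfile <- function(profile, step = 20, offset = 0) {
  stopifnot(is(profile, "RateProfile"))
  if (step <= 0) stop("step must be positive")
  if (offset < 0) stop("offset must be nonnegative")
  remain <- profile@windowT - offset
  if (remain <= 0 || profile@shape == "constant" &&
        profile@meanRate == profile@baseRate) {
    starts <- numeric(0)
  } else {
    nEpochs <- ceiling(remain / step - 1e-9)
    starts <- (seq_len(nEpochs) - 1) * step
  }
  ends <- pmin(starts + step, remain)
  mids <- offset + (starts + ends) / 2
  rates <- if (length(mids)) evaluateRate(profile, mids) else numeric(0)
  data.frame(
    tStart = c(starts, if (length(starts)) remain else 0),
    tEnd = c(ends, Inf),
    rate = c(rates, profile@baseRate)
  )
}

#' Low and high constant rates matched to a linear profile
#'
#' The constant comparison levels used in the four-model classification
#' test: 15% and 85% of the maximum rate attained by the corresponding
#' linear profile over its window (that maximum is `2 * meanRate`).
#'
#' @param profile a linear [RateProfile-class].
#' @return named numeric `c(low = , high = )` in events/bp/generation.
#' @export
constantLowHigh <- function(profile) {
  stopifnot(is(profile, "RateProfile"))
  if (profile@shape != "linear")
    stop("constantLowHigh() is defined for linear profiles")
  maxRate <- 2 * profile@meanRate
  c(low = 0.15 * maxRate, high = 0.85 * maxRate)
}

#' Named profile presets
#'
#' Convenience constructor for the profiles used throughout the package's
#' experiments. `constant-low` / `constant-high` hold 15% / 85% of the
#' matched linear maximum inside the window and revert to the background
#' mean rate beyond it.
#'
#' @param name one of `"constant"`, `"linear-inc"`, `"linear-dec"`,
#'   `"exp-inc"`, `"exp-dec"`, `"logistic-inc"`, `"logistic-dec"`,
#'   `"constant-low"`, `"constant-high"`.
#' @param meanRate,windowT see [makeProfile()].
#' @return a [RateProfile-class].
#' @export
profilePreset <- function(name, meanRate = 3.75e-8, windowT = 1e4) {
  lh <- constantLowHigh(makeProfile("linear", "increasing", meanRate, windowT))
  switch(name,
    "constant" = makeProfile("constant", meanRate = meanRate, windowT = windowT),
    "linear-inc" = makeProfile("linear", "increasing", meanRate, windowT),
    "linear-dec" = makeProfile("linear", "decreasing", meanRate, windowT),
    "exp-inc" = makeProfile("exponential", "increasing", meanRate, windowT),
    "exp-dec" = makeProfile("exponential", "decreasing", meanRate, windowT),
    "logistic-inc" = makeProfile("logistic", "increasing", meanRate, windowT),
    "logistic-dec" = makeProfile("logistic", "decreasing", meanRate, windowT),
    "constant-low" = makeProfile("constant", meanRate = lh[["low"]],
                                 windowT = windowT, baseRate = meanRate),
    "constant-high" = makeProfile("constant", meanRate = lh[["high"]],
                                  windowT = windowT, baseRate = meanRate),
    stop("unknown profile preset '", name, "'")
  )
}
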