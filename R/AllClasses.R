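#' Recombination-rate trajectory through time
#'
#' A `RateProfile` describes how the per-generation recombination rate of a
#' locus varies backward in time. Time `t` is measured in generations before
#' present; `t = 0` is the sampling generation. Within the change window
#' `[0, windowT)` the rate follows the chosen shape, normalized so that its
#' time average over the window equals `meanRate` (the equal-total-
#' recombination constraint). Beyond the window the rate is the background
#' rate `baseRate`, so that rate variation is confined to the window and
#' profiles sharing `meanRate` and `baseRate` imply the same total amount of
#' recombination over any time horizon.
#'
#' @slot shape one of `"constant"`, `"linear"`, `"exponential"`, `"logistic"`.
#' @slot direction `"increasing"` or `"decreasing"` toward the present
#'   (`"na"` for the constant shape). An increasing profile has its maximum
#'   at `t = 0`.
#' @slot meanRate time-averaged rate over the window, events/bp/generation.
#' @slot windowT length of the change window, generations.
#' @slot baseRate rate held for `t >= windowT`, events/bp/generation.
#' @slot lambda exponential rate constant, 1/generation.
#' @slot logisticK,logisticN0,logisticG logistic carrying capacity, initial
#'   value and growth rate (1/generation).
#' @slot normC normalization multiplier mapping the unnormalized shape to
#'   rates (computed by [makeProfile()], not user-set).
#'
#' @seealso [makeProfile()], [evaluateRate()], [discretizeProfile()]
#' @export
setClass("RateProfile",
  representation(
    shape = "character",
    direction = "character",
    meanRate = "numeric",
    windowT = "numeric",
    baseRate = "numeric",
    lambda = "numeric",
    logisticK = "numeric",
    logisticN0 = "numeric",
    logisticG = "numeric",
    normC = "numeric"
  )
)

setValidity("RateProfile", function(object) {
  msg <- character()
  if (!object@shape %in% c("constant", "linear", "exponential", "logistic"))
    msg <- c(msg, "unknown shape")
  if (!object@direction %in% c("na", "increasing", "decreasing"))
    msg <- c(msg, "unknown direction")
  if (object@shape == "constant" && object@direction != "na")
    msg <- c(msg, "constant profiles have direction 'na'")
  if (object@shape != "constant" && object@direction == "na")
    msg <- c(msg, "non-constant profiles need a direction")
  if (object@meanRate < 0) msg <- c(msg, "meanRate must be nonnegative")
  if (object@windowT <= 0) msg <- c(msg, "windowT must be positive")
  if (object@baseRate < 0) msg <- c(msg, "baseRate must be nonnegative")
  if (object@lambda <= 0 || object@logisticK <= 0 || object@logisticN0 <= 0 ||
      object@logisticG <= 0)
    msg <- c(msg, "curve parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Binary haplotype sample with segregating-site positions
#'
#' The unit of simulation and analysis: a sample of `n` haplotypes typed at
#' `S` segregating sites of a locus, stored as an `n x S` 0/1 matrix plus
#' the relative position of each site in `[0, 1)`. Every column segregates
#' (both alleles present) and positions are strictly increasing. This is the
#' in-memory form of one replicate of `ms`-style output ([readMs()],
#' [writeMs()]).
#'
#' @slot haplotypes integer 0/1 matrix, samples in rows, sites in columns.
#' @slot positions numeric vector of relative site positions.
#' @slot provenance list of free-form metadata (profile name, seed, ...).
#'
#' @seealso [simulateDataset()], [summaryStats()], [drawSubsample()]
#' @export
setClass("HaplotypeDataset",
  representation(
    haplotypes = "matrix",
    positions = "numeric",
    provenance = "list"
  )
)

setValidity("HaplotypeDataset", function(object) {
  h <- object@haplotypes
  p <- object@positions
  msg <- character()
  if (ncol(h) != length(p))
    msg <- c(msg, "positions must have one entry per column")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "haplotypes must be binary 0/1")
  if (length(p)) {
    if (any(p < 0 | p >= 1)) msg <- c(msg, "positions must lie in [0, 1)")
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, "positions must be strictly increasing")
  }
  if (ncol(h) > 0 && nrow(h) > 0) {
    cs <- colSums(h)
    if (any(cs == 0 | cs == nrow(h)))
      msg <- c(msg, "every column must segregate")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted Gaussian discriminant classifier
#'
#' Linear (pooled covariance) or quadratic (per-class covariance)
#' discriminant model over recombination-history model labels, with uniform
#' class priors. Stores the training standardization, the feature columns
#' retained (zero-variance columns are dropped), training feature means used
#' to impute missing values, and any ridge added to keep covariances
#' positive definite.
#'
#' @seealso [fitLda()], [fitQda()], [loocvAccuracy()]
#' @export
setClass("DiscriminantModel",
  representation(
    method = "character",
    labels = "character",
    means = "matrix",
    pooledCov = "matrix",
    classCov = "list",
    center = "numeric",
    scale = "numeric",
    keep = "logical",
    imputeMeans = "numeric",
    ridge = "numeric",
    featureNames = "character"
  )
)

#' Classification accuracy report
#'
#' Confusion matrix (true model in rows, assigned model in columns),
#' per-class and overall assignment rates from jackknife (leave-one-out)
#' cross-validation, and the feature subset used.
#'
#' @seealso [loocvAccuracy()]
#' @export
setClass("AccuracyReport",
  representation(
    confusion = "matrix",
    perClass = "numeric",
    overall = "numeric",
    method = "character",
    features = "character"
  )
)

setValidity("AccuracyReport", function(object) {
  if (object@overall < 0 || object@overall > 1)
    "overall rate must lie in [0, 1]" else TRUE
})

## ---- accessors and show methods ----

#' @describeIn HaplotypeDataset-class the 0/1 haplotype matrix
#' @param x,object a `HaplotypeDataset`
#' @export
haplotypes <- function(x) x@haplotypes

#' @describeIn HaplotypeDataset-class relative site positions
#' @export
positions <- function(x) x@positions

#' @describeIn HaplotypeDataset-class number of sampled haplotypes
#' @export
sampleSize <- function(x) nrow(x@haplotypes)

#' @describeIn HaplotypeDataset-class number of segregating sites
#' @export
numSites <- function(x) ncol(x@haplotypes)

setMethod("show", "HaplotypeDataset", function(object) {
  cat("HaplotypeDataset:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "segregating sites\n")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "RateProfile", function(object) {
  dir <- if (object@direction == "na") "" else
    paste0(", ", object@direction, " toward present")
  cat(sprintf("RateProfile: %s%s\n", object@shape, dir))
  cat(sprintf("  mean rate %.3g /bp/gen over window of %g generations; background %.3g\n",
              object@meanRate, object@windowT, object@baseRate))
})

setMethod("show", "DiscriminantModel", function(object) {
  cat(sprintf("DiscriminantModel (%s): %d classes, %d features%s\n",
              toupper(object@method), length(object@labels), sum(object@keep),
              if (object@ridge > 0) sprintf(", ridge %.2g", object@ridge) else ""))
})

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf("AccuracyReport (%s): overall assignment rate %.3f\n",
              toupper(object@method), object@overall))
  print(round(object@perClass, 3))
})

# internal constructor
newHaplotypeDataset <- function(haplotypes, positions, provenance = list()) {
  storage.mode(haplotypes) <- "integer"
  new("HaplotypeDataset", haplotypes = haplotypes,
      positions = as.numeric(positions), provenance = provenance)
}
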