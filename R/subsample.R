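## n-tuple subsampling: repeatedly draw n lineages from a dataset, recompute
## the summary suite on each subsample, and aggregate distribution features.
## Young subsamples capture recent recombination; old ones mix old and
## recent signal, so the feature distribution carries temporal information.

statOrder <- c("S", "Rmin", "rmmg", "nHaps", "HapDiv", "WallB", "WallQ",
               "HudsonC", "ZnS")
scaledOrder <- paste0(setdiff(statOrder, "S"), "_scaled")

#' Feature names of the subsampling feature vector
#'
#' The fixed column schema: mean, variance and maximum of each of the nine
#' unscaled summaries (27 features) followed by the same moments of the
#' eight S-scaled summaries (24 features); 51 features in total.
#'
#' @param scaled include the scaled block (default TRUE).
#' @return character vector of feature names such as `"mean_nHaps"`,
#'   `"var_ZnS_scaled"`.
#' @export
featureNames <- function(scaled = TRUE) {
  stats <- c(statOrder, if (scaled) scaledOrder)
  as.vector(t(outer(c("mean_", "var_", "max_"), stats, paste0)))
}

#' Draw one n-tuple subsample
#'
#' Uniformly samples `tupleN` distinct haplotypes without replacement and
#' drops columns that are monomorphic within the subsample (positions of the
#' retained columns are preserved). With `tupleN` equal to the sample size
#' the full dataset is returned with its column set unchanged.
#'
#' @param x a [HaplotypeDataset-class].
#' @param tupleN subsample size (at least 2; the classic choice is a
#'   quartet, `tupleN = 4`).
#' @return a [HaplotypeDataset-class] of `tupleN` haplotypes.
#' @export
drawSubsample <- function(x, tupleN) {
  stopifnot(is(x, "HaplotypeDataset"))
  n <- nrow(x@haplotypes)
  if (tupleN > n) stop("tupleN exceeds the sample size")
  if (tupleN < 2) stop("tupleN must be at least 2")
  rows <- sample.int(n, tupleN)
  h <- x@haplotypes[rows, , drop = FALSE]
  cs <- colSums(h)
  keep <- cs > 0 & cs < tupleN
  newHaplotypeDataset(h[, keep, drop = FALSE], x@positions[keep],
                      provenance = c(x@provenance, list(subsampleRows = rows)))
}

#' Per-subsample summary distributions
#'
#' Draws `nSubsamples` independent n-tuples (a haplotype may appear in many
#' subsamples) and computes the 9 unscaled and 8 scaled summaries on each.
#'
#' @inheritParams drawSubsample
#' @param nSubsamples number of subsamples.
#' @param cmax Hudson's C clamp.
#' @param scaleMode `"divide"` or `"multiply"`, see [scaleByS()].
#' @return numeric matrix `nSubsamples x 17` with `NA` for undefined values.
#' @export
subsampleSummaries <- function(x, tupleN = 4, nSubsamples = 1000, cmax = 1e4,
                               scaleMode = c("divide", "multiply")) {
  scaleMode <- match.arg(scaleMode)
  h <- statInput(x)
  if (tupleN > nrow(h)) stop("tupleN exceeds the sample size")
  subsample_stats_cpp(h, as.integer(tupleN), as.integer(nSubsamples), cmax,
                      scaleMode == "multiply")
}

#' Subsampling feature vector of one dataset
#'
#' The classification input: mean, sample variance (n-1 denominator) and
#' maximum of each summary over the subsample distribution, skipping
#' undefined values. A feature whose statistic was undefined in every
#' subsample is `NA`; the count of defined values per statistic is attached
#' as attribute `nDefined`.
#'
#' @inheritParams subsampleSummaries
#' @return named numeric of length 51 (see [featureNames()]).
#' @examples
#' set.seed(1)
#' d <- simulateDataset(simConfig(sampleN = 20))
#' fv <- featureVector(d, tupleN = 4, nSubsamples = 50)
#' fv[c("mean_S", "mean_nHaps", "max_ZnS")]
#' @export
featureVector <- function(x, tupleN = 4, nSubsamples = 1000, cmax = 1e4,
                          scaleMode = c("divide", "multiply")) {
  sm <- subsampleSummaries(x, tupleN, nSubsamples, cmax, scaleMode)
  feats <- numeric(0)
  ndef <- integer(0)
  for (s in colnames(sm)) {
    v <- sm[, s]
    v <- v[!is.na(v)]
    ndef[s] <- length(v)
    feats[paste0("mean_", s)] <- if (length(v)) mean(v) else NA_real_
    feats[paste0("var_", s)] <- if (length(v) > 1) var(v)
                                else if (length(v) == 1) 0 else NA_real_
    feats[paste0("max_", s)] <- if (length(v)) max(v) else NA_real_
  }
  structure(feats[featureNames()], names = featureNames(), nDefined = ndef)
}

#' Feature matrix over labeled datasets
#'
#' One row per dataset, 51 feature columns plus a `label` factor; the design
#' matrix of the classification experiments. Subsampling for dataset `i`
#' uses a stream seeded deterministically from `(seed, i)`, so any row can
#' be recomputed independently.
#'
#' @param datasets list of [HaplotypeDataset-class] objects.
#' @param labels vector of model labels, one per dataset.
#' @param seed root seed for the subsampling streams (NULL: use the current
#'   RNG state).
#' @inheritParams featureVector
#' @return data.frame with 51 feature columns and a `label` column.
#' @export
featureMatrix <- function(datasets, labels, tupleN = 4, nSubsamples = 1000,
                          cmax = 1e4, seed = NULL,
                          scaleMode = c("divide", "multiply")) {
  stopifnot(length(datasets) == length(labels))
  scaleMode <- match.arg(scaleMode)
  rows <- lapply(seq_along(datasets), function(i) {
    if (!is.null(seed)) set.seed(replicateSeed(seed, i))
    featureVector(datasets[[i]], tupleN, nSubsamples, cmax, scaleMode)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- factor(labels)
  out
}
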