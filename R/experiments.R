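## End-to-end computational experiments: labeled simulation, feature
## extraction, discriminant classification, statistic sweeps and time
## series. Desk-scale defaults (300 datasets/model, 200 subsamples) keep a
## full experiment in the minutes range on one CPU; the original study
## scale (1e4 datasets/model, 1e3 subsamples) is available by argument.

#' Feature subsets of the classification experiments
#'
#' Translates a subset name into feature columns: any single feature name
#' (`"mean_nHaps"`), a statistic name (`"nHaps"`: its mean, variance and
#' maximum), `"all_unscaled"` (27 features), `"all_scaled"` (24) or
#' `"all_combined"` (51).
#'
#' @param name subset name.
#' @return character vector of feature names.
#' @export
featureSubset <- function(name) {
  fn <- featureNames()
  if (name %in% fn) return(name)
  if (name %in% c(statOrder, scaledOrder))
    return(paste0(c("mean_", "var_", "max_"), name))
  switch(name,
    all_unscaled = fn[!grepl("_scaled$", fn)],
    all_scaled = fn[grepl("_scaled$", fn)],
    all_combined = fn,
    stop("unknown feature subset '", name, "'")
  )
}

#' Simulate labeled datasets under several recombination-history models
#'
#' @param models character vector of [profilePreset()] names.
#' @param nPerModel datasets per model.
#' @param config base [simConfig()] (its profile slot is replaced).
#' @param seed root seed; dataset `i` of the pooled design uses a stream
#'   derived from `(seed, i)`.
#' @return list with `datasets` (list) and `labels` (character).
#' @export
simulateLabeledModels <- function(models, nPerModel, config = simConfig(),
                                  seed = 1) {
  datasets <- vector("list", length(models) * nPerModel)
  labels <- character(length(datasets))
  i <- 0
  for (m in models) {
    cfg <- config
    cfg$profile <- profilePreset(m, meanRate = config$profile@meanRate,
                                 windowT = config$profile@windowT)
    for (j in seq_len(nPerModel)) {
      i <- i + 1
      set.seed(replicateSeed(seed, i))
      datasets[[i]] <- simulateDataset(cfg)
      labels[i] <- m
    }
  }
  list(datasets = datasets, labels = labels)
}

runModelExperiment <- function(models, nPerModel, nSubsamples, tupleN, seed,
                               config, featureSets, method, sim = NULL) {
  if (is.null(sim))
    sim <- simulateLabeledModels(models, nPerModel, config, seed)
  feats <- featureMatrix(sim$datasets, sim$labels, tupleN = tupleN,
                         nSubsamples = nSubsamples,
                         cmax = 1e4,
                         seed = seed + 500081)
  x <- feats[, setdiff(names(feats), "label")]
  reports <- lapply(featureSets, function(fs)
    loocvAccuracy(x, feats$label, method = method,
                  features = featureSubset(fs)))
  names(reports) <- featureSets
  list(reports = reports, features = feats, datasets = sim$datasets,
       labels = sim$labels)
}

#' Three-model classification experiment
#'
#' The central test system: datasets are simulated under constant, linearly
#' increasing and linearly decreasing recombination at equal total
#' recombination, n-tuple subsampling features are extracted, and a
#' jackknifed discriminant classifier assigns each dataset back to a model
#' (chance = 1/3). One [AccuracyReport-class] is returned per requested
#' feature subset.
#'
#' @param nPerModel datasets per model (study scale 1e4; default 300).
#' @param nSubsamples subsamples per dataset (study scale 1e3; default 200).
#' @param tupleN subsample size (default 4, a quartet).
#' @param seed root seed.
#' @param config base [simConfig()].
#' @param featureSets feature subsets to evaluate, see [featureSubset()].
#' @param method `"lda"` (default) or `"qda"`.
#' @return list with `reports`, the feature data.frame, datasets and labels.
#' @export
runThreeModel <- function(nPerModel = 300, nSubsamples = 200, tupleN = 4,
                          seed = 1, config = simConfig(),
                          featureSets = c("S", "mean_nHaps", "all_unscaled",
                                          "all_scaled", "all_combined"),
                          method = "lda") {
  runModelExperiment(c("constant", "linear-inc", "linear-dec"), nPerModel,
                     nSubsamples, tupleN, seed, config, featureSets, method)
}

#' Four-model classification experiment
#'
#' Adds the level-versus-trend control: constant-high and constant-low
#' models (85% and 15% of the linear maximum) against the two linear
#' models, chance = 1/4. Distinguishing these shows the classifier detects
#' rate change, not merely low/medium/high recent rates.
#'
#' @inheritParams runThreeModel
#' @export
runFourModel <- function(nPerModel = 300, nSubsamples = 200, tupleN = 4,
                         seed = 1, config = simConfig(),
                         featureSets = "all_combined", method = "lda") {
  runModelExperiment(c("constant-low", "constant-high", "linear-inc",
                       "linear-dec"), nPerModel, nSubsamples, tupleN, seed,
                     config, featureSets, method)
}

#' Subsample-size sweep
#'
#' Recomputes the three-model experiment for a grid of n-tuple sizes,
#' refitting the discriminant for each size. Accuracy typically rises from
#' quartets, peaks at a large fraction of the sample, and falls again as
#' the subsample approaches the full sample (where every subsample is
#' identical and the feature distributions degenerate).
#'
#' @inheritParams runThreeModel
#' @param tupleSizes n-tuple sizes to evaluate.
#' @param sim optional precomputed result of [simulateLabeledModels()] to
#'   reuse across sizes.
#' @return data.frame with `tupleN` and `accuracy`, plus attribute
#'   `reports`.
#' @export
runNtupleSweep <- function(tupleSizes = c(4, 20, 40, 60, 77, 90, 100),
                           nPerModel = 300, nSubsamples = 200, seed = 1,
                           config = simConfig(), method = "lda",
                           featureSet = "all_combined", sim = NULL) {
  if (is.null(sim))
    sim <- simulateLabeledModels(c("constant", "linear-inc", "linear-dec"),
                                 nPerModel, config, seed)
  tupleSizes <- tupleSizes[tupleSizes <= config$sampleN & tupleSizes >= 2]
  reports <- list()
  acc <- numeric(length(tupleSizes))
  for (ti in seq_along(tupleSizes)) {
    res <- runModelExperiment(NULL, nPerModel, nSubsamples, tupleSizes[ti],
                              seed, config, featureSet, method, sim = sim)
    reports[[as.character(tupleSizes[ti])]] <- res$reports[[1]]
    acc[ti] <- res$reports[[1]]@overall
  }
  structure(data.frame(tupleN = tupleSizes, accuracy = acc),
            reports = reports)
}

#' Time series of summary statistics under a changing rate
#'
#' Tracks how the summary suite responds as the sampling time moves back
#' through a changing recombination regime: at each sampling time,
#' `replicates` independent datasets are simulated with the profile seen
#' from that time point, and the mean and 2.5%/97.5% quantiles of each
#' summary are recorded. Summaries lag the rate change: variation observed
#' at a time point was laid down earlier, and old recombination signal is
#' lost only as recombined lineages drift out of the sample.
#'
#' @param profile a [RateProfile-class].
#' @param sampleTimes sampling times, generations before present.
#' @param replicates simulations per time point.
#' @param config base [simConfig()].
#' @param seed root seed.
#' @return long data.frame: `time`, `stat`, `mean`, `q025`, `q975`, plus
#'   the profile's rate at each time in column `rate`.
#' @export
runTimeSeries <- function(profile, sampleTimes = seq(0, 9980, by = 20),
                          replicates = 500, config = simConfig(), seed = 1) {
  config$profile <- profile
  out <- list()
  for (ti in seq_along(sampleTimes)) {
    tt <- sampleTimes[ti]
    sv <- matrix(NA_real_, replicates, 9)
    for (j in seq_len(replicates)) {
      set.seed(replicateSeed(seed, (ti - 1) * replicates + j))
      d <- simulateDataset(config, sampleTime = tt)
      sv[j, ] <- summaryStats(d, cmax = 1e4)
    }
    colnames(sv) <- statOrder
    out[[ti]] <- data.frame(
      time = tt, stat = statOrder,
      mean = colMeans(sv, na.rm = TRUE),
      q025 = apply(sv, 2, quantile, 0.025, na.rm = TRUE),
      q975 = apply(sv, 2, quantile, 0.975, na.rm = TRUE),
      rate = evaluateRate(profile, tt), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Summary-statistic response to constant recombination rates
#'
#' Simulates under a grid of constant population recombination rates
#' (rho per kb) and records the mean and 95% band of each summary: the
#' sensitivity profile of the suite. Mean S is flat (its mean does not
#' depend on recombination) and serves as a negative control.
#'
#' @param rhoPerKb grid of rho values per kb.
#' @inheritParams runTimeSeries
#' @return long data.frame: `rhoPerKb`, `stat`, `mean`, `q025`, `q975`.
#' @export
runConstantSweep <- function(rhoPerKb = 0:10, replicates = 500,
                             config = simConfig(), seed = 1) {
  out <- list()
  for (ri in seq_along(rhoPerKb)) {
    r <- rhoPerKb[ri] / (4000 * config$Ne) # events/bp/gen giving rho/kb
    cfg <- config
    cfg$profile <- makeProfile("constant", meanRate = r,
                               windowT = config$profile@windowT)
    sv <- matrix(NA_real_, replicates, 9)
    for (j in seq_len(replicates)) {
      set.seed(replicateSeed(seed, (ri - 1) * replicates + j))
      d <- simulateDataset(cfg)
      sv[j, ] <- summaryStats(d, cmax = 1e4)
    }
    colnames(sv) <- statOrder
    out[[ri]] <- data.frame(
      rhoPerKb = rhoPerKb[ri], stat = statOrder,
      mean = colMeans(sv, na.rm = TRUE),
      q025 = apply(sv, 2, quantile, 0.025, na.rm = TRUE),
      q975 = apply(sv, 2, quantile, 0.975, na.rm = TRUE), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Correlation structure of the summary suite
#'
#' Pools an equal mix of datasets simulated under constant, linearly
#' increasing and linearly decreasing recombination, computes the
#' full-sample summaries of each dataset, and returns their pairwise
#' Pearson correlation matrices: for all nine summaries, for the eight
#' recombination summaries (S excluded), and for the S-scaled summaries.
#' `offDiagonal` summarizes each matrix by the mean and range of the
#' absolute off-diagonal correlations.
#'
#' @inheritParams runThreeModel
#' @param sim optional precomputed [simulateLabeledModels()] result.
#' @return list with `withS`, `withoutS`, `scaled` correlation matrices,
#'   the summary table `offDiagonal`, and the pooled summary matrix.
#' @export
runCorrelation <- function(nPerModel = 300, config = simConfig(), seed = 1,
                           sim = NULL) {
  if (is.null(sim))
    sim <- simulateLabeledModels(c("constant", "linear-inc", "linear-dec"),
                                 nPerModel, config, seed)
  cmax <- 1e4
  sv <- t(vapply(sim$datasets, summaryStats, numeric(9), cmax = cmax))
  scaled <- t(apply(sv, 1, scaleByS))
  offdiag <- function(m) m[lower.tri(m)]
  mats <- list(withS = cor(sv, use = "pairwise.complete.obs"),
               withoutS = cor(sv[, setdiff(statOrder, "S")],
                              use = "pairwise.complete.obs"),
               scaled = cor(scaled, use = "pairwise.complete.obs"))
  offd <- do.call(rbind, lapply(names(mats), function(nm) {
    v <- abs(offdiag(mats[[nm]]))
    data.frame(matrix = nm, meanAbs = mean(v, na.rm = TRUE),
               minAbs = min(v, na.rm = TRUE), maxAbs = max(v, na.rm = TRUE))
  }))
  c(mats, list(offDiagonal = offd, summaries = sv))
}
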