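# Shared desk-scale experiment results for the acceptance tests, computed
# once per test run. Scales: 300 datasets per model with 200 quartet
# subsamples per dataset (the full operating scale of the method is 1e4 datasets and 1e3
# quartets), and 200 subsamples for the n-tuple-77 evaluation.

deskCache <- new.env(parent = emptyenv())

deskSeed <- 101

deskThreeModel <- function() {
  if (is.null(deskCache$three)) {
    deskCache$three <- runThreeModel(
      nPerModel = 300, nSubsamples = 200, tupleN = 4, seed = deskSeed,
      featureSets = c("mean_S", "mean_nHaps", "S", "all_unscaled",
                      "all_scaled", "all_combined"))
  }
  deskCache$three
}

deskAccuracy77 <- function() {
  if (is.null(deskCache$acc77)) {
    three <- deskThreeModel()
    sw <- runNtupleSweep(tupleSizes = 77, nPerModel = 300,
                         nSubsamples = 200, seed = deskSeed,
                         sim = list(datasets = three$datasets,
                                    labels = three$labels))
    deskCache$acc77 <- sw$accuracy[1]
  }
  deskCache$acc77
}

deskFourModel <- function() {
  if (is.null(deskCache$four)) {
    deskCache$four <- runFourModel(nPerModel = 300, nSubsamples = 200,
                                   tupleN = 4, seed = deskSeed + 1)
  }
  deskCache$four
}

deskCorrelation <- function() {
  if (is.null(deskCache$corr)) {
    three <- deskThreeModel()
    deskCache$corr <- runCorrelation(
      sim = list(datasets = three$datasets, labels = three$labels))
  }
  deskCache$corr
}
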