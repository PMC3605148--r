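# Small-scale structural and determinism checks of the experiment drivers;
# the scientific endpoints at desk scale live in test-acceptance.R.

tinyConfig <- simConfig(sampleN = 25)

test_that("three-model experiment returns coherent reports", {
  res <- runThreeModel(nPerModel = 12, nSubsamples = 30, seed = 3,
                       config = tinyConfig,
                       featureSets = c("S", "all_combined"))
  expect_named(res$reports, c("S", "all_combined"))
  rep <- res$reports$all_combined
  expect_s4_class(rep, "AccuracyReport")
  expect_identical(sum(confusionMatrix(rep)), 36L)
  expect_identical(unname(rowSums(confusionMatrix(rep))), rep(12, 3))
  expect_true(overallAccuracy(rep) >= 0 && overallAccuracy(rep) <= 1)
  expect_identical(dim(res$features), c(36L, 52L))
  expect_identical(levels(res$features$label),
                   c("constant", "linear-dec", "linear-inc"))
})

test_that("experiments are reproducible from their seeds", {
  r1 <- runThreeModel(nPerModel = 6, nSubsamples = 15, seed = 5,
                      config = tinyConfig, featureSets = "mean_nHaps")
  r2 <- runThreeModel(nPerModel = 6, nSubsamples = 15, seed = 5,
                      config = tinyConfig, featureSets = "mean_nHaps")
  expect_identical(r1$features, r2$features)
  expect_identical(confusionMatrix(r1$reports[[1]]),
                   confusionMatrix(r2$reports[[1]]))
})

test_that("four-model experiment uses the level-matched constants", {
  res <- runFourModel(nPerModel = 8, nSubsamples = 20, seed = 7,
                      config = tinyConfig)
  expect_identical(sort(unique(res$labels)),
                   sort(c("constant-low", "constant-high", "linear-inc",
                          "linear-dec")))
  expect_identical(sum(confusionMatrix(res$reports[[1]])), 32L)
})

test_that("the n-tuple sweep reuses datasets across sizes", {
  sim <- simulateLabeledModels(c("constant", "linear-inc", "linear-dec"),
                               8, tinyConfig, seed = 11)
  sw <- runNtupleSweep(tupleSizes = c(4, 10, 25, 40), nPerModel = 8,
                       nSubsamples = 20, seed = 11, config = tinyConfig,
                       sim = sim)
  expect_identical(sw$tupleN, c(4, 10, 25)) # 40 > sample size is dropped
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
})

test_that("feature subsets resolve to the documented schema", {
  expect_identical(featureSubset("all_combined"), featureNames())
  expect_identical(length(featureSubset("all_unscaled")), 27L)
  expect_identical(length(featureSubset("all_scaled")), 24L)
  expect_identical(featureSubset("nHaps"),
                   c("mean_nHaps", "var_nHaps", "max_nHaps"))
  expect_identical(featureSubset("mean_ZnS_scaled"), "mean_ZnS_scaled")
  expect_error(featureSubset("bogus"), "unknown")
})

test_that("correlation study emits labeled matrices with unit diagonals", {
  res <- runCorrelation(nPerModel = 15, config = tinyConfig, seed = 13)
  expect_identical(dim(res$withS), c(9L, 9L))
  expect_identical(dim(res$withoutS), c(8L, 8L))
  # zero-variance statistics (rmmg at full scale) have undefined rows
  d <- diag(res$withS)
  expect_true(all(d[!is.na(d)] == 1))
  expect_gte(sum(!is.na(d)), 8)
  expect_true(all(abs(res$withS[!is.na(res$withS)]) <= 1 + 1e-12))
  expect_identical(res$offDiagonal$matrix, c("withS", "withoutS", "scaled"))
})

test_that("time series tracks the profile grid", {
  ts <- runTimeSeries(profilePreset("constant"),
                      sampleTimes = c(0, 5000), replicates = 15,
                      config = tinyConfig, seed = 17)
  expect_identical(nrow(ts), 18L) # 2 times x 9 statistics
  expect_true(all(ts$q975 >= ts$mean - 1e-12))
  expect_equal(unique(ts$rate), 3.75e-8)
})

test_that("constant sweep covers the rho grid with sane bands", {
  sw <- runConstantSweep(rhoPerKb = c(0, 5), replicates = 25,
                         config = tinyConfig, seed = 19)
  expect_identical(nrow(sw), 18L)
  r0 <- subset(sw, rhoPerKb == 0 & stat == "Rmin")
  expect_identical(r0$mean, 0) # no recombination, no four-gamete violations
})

test_that("smoothCurve reproduces polynomials and matches WLS directly", {
  x <- seq(0, 10, length.out = 25)
  yq <- 2 + 3 * x - 0.5 * x^2
  fit <- smoothCurve(x, yq)
  expect_equal(fit$y, yq, tolerance = 1e-8) # degree-2 exactness
  yc <- rep(4, 25)
  expect_equal(smoothCurve(x, yc)$y, yc, tolerance = 1e-10)
  # independent route: the same weights fed to lm.wfit
  set.seed(23)
  y <- yq + rnorm(25)
  x0 <- x[13]
  n <- length(x)
  d <- abs(x - x0)
  h <- sort(d)[ceiling(0.5 * n)]
  q <- 2 * d / h
  w <- ifelse(q <= 1, 1 - 1.5 * q^2 + 0.75 * q^3,
              ifelse(q <= 2, 0.25 * (2 - q)^3, 0))
  w <- 0.9 * w / sum(w) + 0.1 / n
  ref <- lm(y ~ I(x - x0) + I((x - x0)^2), weights = w)
  expect_equal(smoothCurve(x, y, xout = x0)$y,
               unname(coef(ref)[1]), tolerance = 1e-6)
  expect_error(smoothCurve(1:3, 1:3), "at least 5")
})
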