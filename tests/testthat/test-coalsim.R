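smallConfig <- function(n = 10, theta = 5, profile = profilePreset("constant")) {
  # Ne and locus fixed; mu chosen so 4*Ne*mu*L = theta; profile rescaled so
  # 4*Ne*r*L matches the profile's native rho
  simConfig(Ne = 1e4, sampleN = n, locusL = 1e4, mu = theta / (4 * 1e4 * 1e4),
            profile = profile)
}

test_that("simulation is reproducible and seeds separate replicates", {
  cfg <- smallConfig()
  set.seed(99)
  d1 <- simulateDataset(cfg)
  set.seed(99)
  d2 <- simulateDataset(cfg)
  expect_identical(haplotypes(d1), haplotypes(d2))
  expect_identical(positions(d1), positions(d2))
  set.seed(100)
  d3 <- simulateDataset(cfg)
  expect_false(identical(haplotypes(d1), haplotypes(d3)))
  # replicate streams: regenerating replicate 3 alone matches the batch
  reps <- simulateReplicates(cfg, 4, seed = 5)
  set.seed(recombpast:::replicateSeed(5, 3))
  alone <- simulateDataset(cfg)
  expect_identical(haplotypes(reps[[3]]), haplotypes(alone))
})

test_that("datasets are valid and carry provenance", {
  set.seed(1)
  d <- simulateDataset(smallConfig())
  expect_true(validObject(d))
  expect_true(all(colSums(haplotypes(d)) > 0))
  expect_true(all(colSums(haplotypes(d)) < sampleSize(d)))
  expect_true(!is.unsorted(positions(d), strictly = TRUE))
  expect_identical(d@provenance$shape, "constant")
})

test_that("without recombination every dataset has a single tree", {
  cfg <- smallConfig(n = 8, theta = 10,
                     profile = makeProfile("constant", meanRate = 0))
  set.seed(3)
  for (i in 1:40) {
    d <- simulateDataset(cfg)
    expect_identical(d@provenance$nRecombination, 0)
    if (numSites(d) >= 2) expect_identical(rmin(d), 0)
  }
})

test_that("mean segregating sites follows Watterson's formula", {
  cfg <- smallConfig(n = 10, theta = 5)
  set.seed(11)
  S <- vapply(seq_len(1500), function(i) numSites(simulateDataset(cfg)),
              numeric(1))
  expected <- 5 * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3.5 * se)
  # n = 2: E[S] = theta
  cfg2 <- smallConfig(n = 2, theta = 15)
  set.seed(12)
  S2 <- vapply(seq_len(1500), function(i) numSites(simulateDataset(cfg2)),
               numeric(1))
  expect_lt(abs(mean(S2) - 15), 3.5 * sd(S2) / sqrt(length(S2)))
})

test_that("pair TMRCA averages one coalescent unit", {
  cfg <- smallConfig(n = 2, theta = 1,
                     profile = makeProfile("constant", meanRate = 0))
  set.seed(13)
  tm <- vapply(seq_len(2000), function(i)
    simulateDataset(cfg)@provenance$tmrca, numeric(1))
  expect_lt(abs(mean(tm) - 1) / (sd(tm) / sqrt(length(tm))), 3.5)
})

test_that("recombination events scale linearly with the rate", {
  set.seed(14)
  rates <- c(0, 1, 2, 4) * 3.75e-8
  obs <- do.call(rbind, lapply(rates, function(r) {
    cfg <- smallConfig(n = 20, theta = 5,
                       profile = makeProfile("constant", meanRate = r))
    data.frame(rate = r, nrec = vapply(seq_len(200), function(i)
      simulateDataset(cfg)@provenance$nRecombination, numeric(1)))
  }))
  expect_identical(max(obs$nrec[obs$rate == 0]), 0)
  fit <- summary(lm(nrec ~ rate, data = obs))
  expect_gt(coef(fit)[2, 1], 0)
  expect_lt(coef(fit)[2, 4], 1e-6)
})

test_that("sampling at a time point shifts the profile as specified", {
  # linear profile sampled beyond its window behaves like the constant one
  cfgLin <- smallConfig(n = 15, theta = 8, profile = profilePreset("linear-dec"))
  set.seed(15)
  Sfar <- vapply(seq_len(300), function(i)
    numSites(simulateAtTimepoint(cfgLin, 1e4)), numeric(1))
  cfgConst <- smallConfig(n = 15, theta = 8)
  set.seed(15)
  Sconst <- vapply(seq_len(300), function(i)
    numSites(simulateDataset(cfgConst)), numeric(1))
  expect_identical(Sfar, Sconst) # same epochs, same RNG stream
  expect_error(simulateDataset(cfgLin, sampleTime = -5), "nonnegative")
})

test_that("ms round-trip preserves matrices and positions", {
  cfg <- smallConfig(n = 6, theta = 6)
  set.seed(16)
  reps <- simulateReplicates(cfg, 3, seed = 21)
  f <- tempfile(fileext = ".ms")
  writeMs(reps, f)
  back <- readMs(f)
  expect_identical(length(back), 3L)
  for (i in 1:3) {
    expect_identical(haplotypes(back[[i]]), haplotypes(reps[[i]]))
    expect_equal(positions(back[[i]]), positions(reps[[i]]), tolerance = 1e-5)
  }
})

test_that("handcrafted and degenerate ms blocks parse correctly", {
  f <- tempfile(fileext = ".ms")
  writeLines(c("ms 3 2 -t 5", "1 2 3", "", "//", "segsites: 2",
               "positions: 0.1000 0.5000", "01", "10", "11", "", "//",
               "segsites: 0", ""), f)
  got <- readMs(f)
  expect_identical(length(got), 2L)
  expect_identical(haplotypes(got[[1]]),
                   matrix(c(0L, 1L, 1L, 1L, 0L, 1L), 3, 2))
  expect_equal(positions(got[[1]]), c(0.1, 0.5))
  expect_identical(dim(haplotypes(got[[2]])), c(3L, 0L))
  # malformed input is rejected
  writeLines(c("//", "segsites: 2", "positions: 0.1 0.2", "01", "1"), f)
  expect_error(readMs(f), "ragged")
  writeLines(c("//", "positions: 0.1"), f)
  expect_error(readMs(f), "segsites")
})
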