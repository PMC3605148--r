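test_that("hand-computed fixtures give the expected statistic values", {
  # all four gametes at two sites: one forced recombination event
  d4 <- hapData(c("00", "01", "10", "11"))
  sv <- summaryStats(d4)
  expect_equal(sv[["S"]], 2)
  expect_equal(sv[["Rmin"]], 1)
  expect_equal(sv[["rmmg"]], 1) # max(0, 4 - 2 - 1)
  expect_equal(sv[["nHaps"]], 4)
  expect_equal(sv[["HapDiv"]], 1) # (4/3)(1 - 4/16)
  expect_equal(sv[["WallB"]], 0)
  expect_equal(sv[["WallQ"]], 0)
  expect_equal(sv[["ZnS"]], 0) # D = 1/4 - 1/2 * 1/2 = 0

  # perfect linkage: congruent adjacent pair
  d2 <- hapData(c("00", "00", "11", "11"))
  sv <- summaryStats(d2)
  expect_equal(sv[["Rmin"]], 0)
  expect_equal(sv[["nHaps"]], 2)
  expect_equal(sv[["HapDiv"]], 2 / 3) # (4/3)(1 - 1/2)
  expect_equal(sv[["WallB"]], 1) # B' = 1, S - 1 = 1
  expect_equal(sv[["WallQ"]], 1) # (1 + 1)/2
  expect_equal(sv[["ZnS"]], 1)

  # monomorphic sample
  d0 <- new("HaplotypeDataset", haplotypes = matrix(0L, 4, 0),
            positions = numeric(), provenance = list())
  sv <- summaryStats(d0)
  expect_equal(sv[["S"]], 0)
  expect_equal(sv[["nHaps"]], 1)
  expect_equal(sv[["HapDiv"]], 0)
  expect_equal(sv[["HudsonC"]], 0)
  expect_true(is.na(sv[["WallB"]]) && is.na(sv[["WallQ"]]) &&
              is.na(sv[["ZnS"]]))
})

test_that("Wall's B counts congruent adjacent pairs only", {
  # sites 1-2 congruent (identical bipartition), 2-3 not
  d <- hapData(c("000", "001", "110", "111"))
  sv <- summaryStats(d)
  expect_equal(sv[["WallB"]], 1 / 2)
  expect_equal(sv[["WallQ"]], (1 + 1) / 3)
  # complementary coding is the same bipartition
  dc <- hapData(c("01", "01", "10", "10"))
  expect_equal(summaryStats(dc)[["WallB"]], 1)
})

test_that("ZnS equals direct pairwise r^2 arithmetic on a 3-site fixture", {
  d <- hapData(c("011", "110", "010", "101"))
  expect_equal(summaryStats(d)[["ZnS"]], znsOracle(haplotypes(d)))
})

test_that("Rmin matches the exhaustive interval-cover oracle", {
  # two disjoint incompatible intervals force two events
  d5 <- hapData(c("00100", "01000", "10011", "11111", "00001", "11010"))
  expect_equal(rmin(d5), rminOracle(haplotypes(d5)))
  expect_gte(rmin(d5), 2)
  # random small matrices, exhaustive check
  set.seed(7)
  for (rep in 1:400) {
    n <- sample(3:6, 1)
    S <- sample(2:6, 1)
    m <- randomBinaryMatrix(n, S, p = runif(1, 0.2, 0.8))
    expect_identical(as.integer(rmin(m)), as.integer(rminOracle(m)))
  }
})

test_that("rmmg follows the haplotype-bound formula", {
  set.seed(8)
  for (rep in 1:1000) {
    m <- randomBinaryMatrix(sample(3:8, 1), sample(1:8, 1))
    sv <- summaryStats(m)
    expect_equal(sv[["rmmg"]],
                 max(0, sv[["nHaps"]] - sv[["S"]] - 1))
  }
})

test_that("rmmg never exceeds Rmin on genealogical data", {
  # Both are lower bounds on the true number of recombination events; for
  # arbitrary dense matrices they are not ordered (haplotype-rich, site-poor
  # matrices can push the haplotype bound above the interval bound), but on
  # coalescent-generated samples the interval bound dominates.
  cfg <- simConfig(sampleN = 30)
  set.seed(9001)
  for (i in 1:20) {
    d <- simulateDataset(cfg)
    sm <- subsampleSummaries(d, tupleN = 4, nSubsamples = 100)
    expect_true(all(sm[, "rmmg"] <= sm[, "Rmin"]))
  }
  # frozen non-genealogical counterexample: six distinct haplotypes over
  # three sites, a single four-gamete interval
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 1),
             c(0, 1, 1), c(1, 0, 1), c(1, 1, 0), c(0, 1, 1))
  sv <- summaryStats(m)
  expect_identical(unname(sv[c("Rmin", "rmmg")]), c(1, 2))
  expect_identical(as.integer(sv[["Rmin"]]), as.integer(rminOracle(m)))
})

test_that("bounded statistics stay in [0, 1] and counts are consistent", {
  set.seed(9)
  for (rep in 1:300) {
    m <- randomBinaryMatrix(sample(4:12, 1), sample(0:15, 1))
    sv <- summaryStats(m)
    for (s in c("HapDiv", "WallB", "WallQ", "ZnS"))
      if (!is.na(sv[[s]])) {
        expect_gte(sv[[s]], 0)
        expect_lte(sv[[s]], 1)
      }
    expect_lte(sv[["nHaps"]], nrow(m))
    expect_identical(sv[["HapDiv"]] == 0, sv[["nHaps"]] == 1)
    expect_gte(sv[["HudsonC"]], 0)
  }
})

test_that("statistics are invariant to row order", {
  set.seed(10)
  m <- randomBinaryMatrix(10, 12)
  sv1 <- summaryStats(m)
  sv2 <- summaryStats(m[sample(10), ])
  expect_equal(sv1, sv2)
})

test_that("Hudson's C solves its moment equation with the clamp rules", {
  # expectation is decreasing in C and anchored at thetahat + thetahat^2
  th <- 4.2
  Cs <- c(0, 1, 5, 20, 100)
  ex <- hudsonsCExpectation(Cs, th)
  expect_equal(ex[1], th + th^2)
  expect_true(all(diff(ex) < 0))
  # inverse identity: solving then re-evaluating recovers the observed value
  for (obs in c(ex[2] * 1.0001, (ex[2] + ex[3]) / 2, ex[4])) {
    C <- hudsonsCSolve(th, obs, cmax = 150)
    expect_equal(hudsonsCExpectation(C, th), obs, tolerance = 1e-4)
  }
  # clamps
  expect_equal(hudsonsCSolve(th, th + th^2 + 1, cmax = 150), 0)
  expect_equal(hudsonsCSolve(th, 0, cmax = 150), 150)
  expect_equal(hudsonsCSolve(0, 3, cmax = 150), 0)
})

test_that("scaling by S divides the eight recombination summaries", {
  d <- hapData(c("0011", "0101", "1010", "1100"))
  sv <- summaryStats(d)
  sc <- scaleByS(sv)
  expect_identical(length(sc), 8L)
  expect_equal(unname(sc["nHaps_scaled"]), sv[["nHaps"]] / sv[["S"]])
  # multiplying back by S recovers the originals
  back <- sc * sv[["S"]]
  expect_equal(unname(back), unname(sv[setdiff(names(sv), "S")]))
  # multiply mode
  scm <- scaleByS(sv, mode = "multiply")
  expect_equal(unname(scm["Rmin_scaled"]), sv[["Rmin"]] * sv[["S"]])
  # S = 0: everything undefined
  d0 <- new("HaplotypeDataset", haplotypes = matrix(0L, 3, 0),
            positions = numeric(), provenance = list())
  expect_true(all(is.na(scaleByS(summaryStats(d0)))))
})

test_that("segregating sites are recounted within row subsets", {
  d <- hapData(c("00", "01", "10", "11"))
  expect_equal(segSites(d), 2)
  sub <- haplotypes(d)[1:2, , drop = FALSE] # rows 00, 01
  expect_equal(segSites(sub), 1)
})
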