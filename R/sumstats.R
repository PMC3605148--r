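## The nine-statistic recombination summary suite.
##
## Undefined-statistic convention: statistics whose denominators vanish
## (Wall's B and ZnS at S < 2, scaled values at S = 0) are NA, not 0;
## downstream feature aggregation skips NA values so that young, low-S
## subsamples do not bias the feature distributions.

statInput <- function(x) {
  if (is(x, "HaplotypeDataset")) x@haplotypes
  else if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    x
  } else stop("expected a HaplotypeDataset or a 0/1 matrix")
}

#' Summary statistics of a haplotype sample
#'
#' Computes the suite of nine summaries on a dataset (or a plain 0/1
#' matrix): `S`, the number of segregating sites; `Rmin`, the Hudson-Kaplan
#' minimum number of recombination events from four-gamete violations;
#' `rmmg`, the Myers-Griffiths haplotype bound `max(0, nHaps - S - 1)`, a
#' conservative lower bound on `Rmin`; `nHaps`, the number of distinct
#' haplotypes; `HapDiv`, the sample-corrected haplotype diversity; Wall's
#' `B` and `Q`, counting adjacent segregating sites in complete linkage
#' disequilibrium; `HudsonC`, a moment estimator of the population
#' recombination rate from the variance of pairwise sequence differences;
#' and `ZnS`, the mean pairwise `r^2` across all segregating-site pairs.
#'
#' @param x a [HaplotypeDataset-class] or binary matrix (samples in rows).
#' @param cmax upper clamp for Hudson's C (default 1e4, the conventional
#'   cap of moment-based estimators of the population recombination rate).
#' @return named numeric of length 9; undefined entries are `NA`.
#' @seealso [scaleByS()], [featureVector()]
#' @export
summaryStats <- function(x, cmax = 1e4) {
  h <- statInput(x)
  summary_stats_cpp(h, seq_len(nrow(h)), cmax)
}

#' Scale the recombination summaries by S
#'
#' Divides the eight recombination summaries by the number of segregating
#' sites, a robust proxy for the age of the sample or subsample, yielding
#' age-normalized summaries. Undefined when `S = 0`. `mode = "multiply"`
#' gives the product instead.
#'
#' @param sv a summary vector from [summaryStats()].
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return named numeric of length 8 (suffix `_scaled`).
#' @export
scaleByS <- function(sv, mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  stopifnot(all(c("S", "Rmin") %in% names(sv)))
  S <- sv[["S"]]
  rest <- sv[setdiff(names(sv), "S")]
  out <- if (S == 0) rep(NA_real_, length(rest))
         else if (mode == "divide") rest / S else rest * S
  setNames(as.numeric(out), paste0(names(rest), "_scaled"))
}

#' @rdname summaryStats
#' @details The individual accessors compute one statistic each; they share
#'   the implementation of `summaryStats()`.
#' @export
segSites <- function(x) unname(summaryStats(x)[["S"]])

#' @rdname summaryStats
#' @export
rmin <- function(x) unname(summaryStats(x)[["Rmin"]])

#' @rdname summaryStats
#' @export
rmmg <- function(x) unname(summaryStats(x)[["rmmg"]])

#' @rdname summaryStats
#' @export
nHaplotypes <- function(x) unname(summaryStats(x)[["nHaps"]])

#' @rdname summaryStats
#' @export
haplotypeDiversity <- function(x) unname(summaryStats(x)[["HapDiv"]])

#' @rdname summaryStats
#' @export
wallsB <- function(x) unname(summaryStats(x)[["WallB"]])

#' @rdname summaryStats
#' @export
wallsQ <- function(x) unname(summaryStats(x)[["WallQ"]])

#' @rdname summaryStats
#' @export
hudsonsC <- function(x, cmax = 1e4) unname(summaryStats(x, cmax)[["HudsonC"]])

#' @rdname summaryStats
#' @export
zns <- function(x) unname(summaryStats(x)[["ZnS"]])

#' Hudson's C moment equation
#'
#' The expectation of the variance of pairwise sequence differences given a
#' total population recombination rate `C` and the mean pairwise difference
#' `thetahat`: `thetahat + thetahat^2 * sigmaT2(C)`, where `sigmaT2` is the
#' variance of the locus-averaged pair coalescence time under recombination.
#' `hudsonsCSolve()` inverts it by bisection with the clamp rules used by
#' [summaryStats()] (0 when the observed variance exceeds the C = 0
#' expectation, `cmax` when below the `cmax` expectation).
#'
#' @param C total population recombination rate of the locus.
#' @param thetahat mean number of pairwise differences.
#' @param sksq observed variance of pairwise differences.
#' @param cmax upper clamp.
#' @return expected variance / the estimate of C.
#' @export
hudsonsCExpectation <- function(C, thetahat) {
  vapply(C, sksq_expect_cpp, numeric(1), thetahat = thetahat)
}

#' @rdname hudsonsCExpectation
#' @export
hudsonsCSolve <- function(thetahat, sksq, cmax = 1e4) {
  hudsons_c_cpp(thetahat, sksq, cmax)
}
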