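## Closed-form coalescent expectations that bound the power of any attempt
## to reconstruct past recombination rates: coalescence-time moments and the
## probability that a small subsample spans the basal split of the
## genealogy (and hence carries the oldest recoverable recombination
## signal).

#' Expected coalescence times
#'
#' While `i` lineages remain, the time to the next coalescence is
#' exponential with mean `2 / (i (i - 1))` in units of N generations for a
#' haploid locus (2N generations for autosomal loci); `varTi()` is the
#' squared mean (exponential distribution). Summed over `i = 2..m` the
#' expected tree height telescopes to `2 (1 - 1/m)`: the final two lineages
#' take on average half the total time, so the deep history of a locus is
#' recorded by very few lineages.
#'
#' @param i number of extant lineages (integer, `i >= 2`); vectorized.
#' @return expected waiting time / its variance, coalescent units.
#' @export
expectedTi <- function(i) {
  if (any(i < 2)) stop("i must be at least 2")
  2 / (i * (i - 1))
}

#' @rdname expectedTi
#' @export
varTi <- function(i) expectedTi(i)^2

#' Convert between generations and coalescent time units
#'
#' Autosomal scaling: one coalescent unit is `2 * Ne` generations for a
#' diploid effective size `Ne` (use `Ne/2` to recover the haploid N-units).
#'
#' @param t time in coalescent units / generations.
#' @param Ne diploid effective population size.
#' @export
coalescentToGenerations <- function(t, Ne) t * 2 * Ne

#' @rdname coalescentToGenerations
#' @export
generationsToCoalescent <- function(t, Ne) t / (2 * Ne)

#' Probability a subsample spans the basal split
#'
#' `pRoot(n)` is the expectation over coalescent genealogies of the
#' probability that a uniform subsample of `n` lineages observes both sides
#' of the deepest bifurcation: `(n - 1) / (n + 1)`. Already 0.60 for a
#' quartet, approaching 1 as `n` grows -- but all subsamples spanning the
#' basal split return the same information about the oldest recombination
#' events, so extra subsamples add nothing there.
#'
#' @param n subsample size (`n >= 2`); vectorized.
#' @return probability.
#' @export
pRoot <- function(n) {
  if (any(n < 2)) stop("n must be at least 2")
  (n - 1) / (n + 1)
}

#' @rdname pRoot
#' @details `pRootSplit(a, b, k)` conditions on a fixed basal split with
#'   `a` tips on one side and `b` on the other: the probability that a
#'   uniform `k`-subset contains at least one lineage from each side,
#'   `1 - (choose(a, k) + choose(b, k)) / choose(a + b, k)`. Useful for
#'   highly unbalanced empirical genealogies.
#' @param a,b tip counts on the two sides of the basal split.
#' @param k subsample size (`2 <= k <= a + b`).
#' @export
pRootSplit <- function(a, b, k) {
  if (any(a < 1) || any(b < 1)) stop("a and b must be at least 1")
  if (any(k < 2)) stop("k must be at least 2")
  if (any(k > a + b)) stop("k exceeds the number of tips")
  1 - (choose(a, k) + choose(b, k)) / choose(a + b, k)
}
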