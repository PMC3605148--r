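## Coalescent simulation with a time-varying recombination rate, plus
## ms-format interchange.
##
## Scaling conventions: with Ne diploids the coalescent time unit is 2*Ne
## generations (pair-coalescence rate 1), theta = 4*Ne*mu*L and
## rho = 4*Ne*r*L; per unit coalescent time a lineage recombines at rate
## (rho/2) * span and mutations fall at rate theta/2 per unit sequence
## length, which reproduces Watterson's E[S] = theta * a_n.

#' Simulation configuration
#'
#' Bundles the demographic and locus parameters of a simulation. The
#' population-scaled rates are derived, not stored: `theta = 4 Ne mu L` and
#' `rhoBar = 4 Ne rbar L` with `rbar` the profile's window-mean rate. With
#' the defaults both equal 15, a human-like deme with a strongly
#' recombining 10-kb locus.
#'
#' @param Ne diploid effective population size.
#' @param sampleN haploid sample size.
#' @param locusL locus length in bp.
#' @param mu mutation rate, events/bp/generation.
#' @param profile a [RateProfile-class] for the recombination rate.
#' @param step discretization step for the profile, generations.
#' @param maxEvents guard cap on coalescent events per replicate.
#' @return a `simConfig` list.
#' @export
simConfig <- function(Ne = 1e4, sampleN = 100, locusL = 1e4, mu = 3.75e-8,
                      profile = profilePreset("constant"), step = 20,
                      maxEvents = 1e7) {
  stopifnot(Ne > 0, sampleN >= 2, locusL > 0, mu >= 0,
            is(profile, "RateProfile"), step > 0)
  structure(list(Ne = Ne, sampleN = as.integer(sampleN), locusL = locusL,
                 mu = mu, profile = profile, step = step,
                 maxEvents = maxEvents),
            class = "simConfig")
}

#' @rdname simConfig
#' @param config a `simConfig`.
#' @export
theta <- function(config) 4 * config$Ne * config$mu * config$locusL

#' @rdname simConfig
#' @export
rhoBar <- function(config) 4 * config$Ne * config$profile@meanRate * config$locusL

#' Simulate one haplotype dataset
#'
#' Runs the coalescent with recombination backward in time from `sampleTime`
#' generations before present, with the recombination rate following the
#' configured profile (discretized to piecewise-constant epochs, within
#' which competing exponential waiting times are exact). Infinite-sites
#' mutations are then placed on the ancestral recombination graph. Uses R's
#' random number generator, so results are reproducible under [set.seed()].
#'
#' @param config a [simConfig()].
#' @param sampleTime sampling time, generations before present (default 0).
#' @return a [HaplotypeDataset-class]; provenance records the profile shape,
#'   the sampling time, the realized number of recombination events and the
#'   time to the grand most recent common ancestor (coalescent units).
#' @examples
#' set.seed(1)
#' d <- simulateDataset(simConfig(sampleN = 10))
#' summaryStats(d)
#' @export
simulateDataset <- function(config, sampleTime = 0) {
  stopifnot(inherits(config, "simConfig"))
  if (sampleTime < 0) stop("sampleTime must be nonnegative")
  ep <- discretizeProfile(config$profile, config$step, offset = sampleTime)
  unit <- 2 * config$Ne # generations per coalescent time unit
  res <- sim_dataset_cpp(config$sampleN, theta(config),
                         ep$tEnd / unit,
                         4 * config$Ne * ep$rate * config$locusL,
                         config$maxEvents)
  newHaplotypeDataset(res$haplotypes, res$positions,
    provenance = list(shape = config$profile@shape,
                      direction = config$profile@direction,
                      sampleTime = sampleTime,
                      nRecombination = res$nRecombination,
                      tmrca = res$tmrca))
}

#' @rdname simulateDataset
#' @details `simulateAtTimepoint()` is the explicit-name wrapper used by the
#'   time-series experiment; the profile is evaluated at `sampleTime + t`.
#' @export
simulateAtTimepoint <- function(config, sampleTime) {
  simulateDataset(config, sampleTime = sampleTime)
}

#' Simulate replicate datasets with reproducible per-replicate streams
#'
#' Each replicate gets a deterministic seed derived from `(seed, i)`, so any
#' single replicate can be regenerated independently of the others.
#'
#' @inheritParams simulateDataset
#' @param replicates number of datasets.
#' @param seed root integer seed.
#' @return list of [HaplotypeDataset-class] objects.
#' @export
simulateReplicates <- function(config, replicates, seed, sampleTime = 0) {
  lapply(seq_len(replicates), function(i) {
    set.seed(replicateSeed(seed, i))
    simulateDataset(config, sampleTime = sampleTime)
  })
}

# deterministic 31-bit stream seed from (root seed, index); exact in doubles
replicateSeed <- function(seed, i) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(i) * 7919) %% 2147483647 + 1)
}

## ---- ms-format interchange ----

#' Write datasets in ms format
#'
#' Emits the classic format of Hudson's `ms`: a command-echo line, blank
#' line, then per replicate `//`, `segsites: k`, `positions: ...` and the
#' 0/1 haplotype rows.
#'
#' @param datasets a [HaplotypeDataset-class] or list of them.
#' @param file path or connection.
#' @export
writeMs <- function(datasets, file) {
  if (is(datasets, "HaplotypeDataset")) datasets <- list(datasets)
  n <- if (length(datasets)) nrow(datasets[[1]]@haplotypes) else 0
  out <- c(sprintf("ms %d %d", n, length(datasets)), "", "")
  for (d in datasets) {
    S <- ncol(d@haplotypes)
    block <- c("//", sprintf("segsites: %d", S))
    if (S > 0) {
      block <- c(block,
                 paste("positions:",
                       paste(sprintf("%.6f", d@positions), collapse = " ")),
                 apply(d@haplotypes, 1, paste, collapse = ""))
    }
    out <- c(out, block, "")
  }
  writeLines(out, file)
  invisible(file)
}

#' Read ms-format output
#'
#' Parses output of Hudson's `ms` or [writeMs()]: replicates separated by
#' `//`, each with a `segsites:` line, a `positions:` line and 0/1 rows.
#' A `segsites: 0` replicate yields a dataset with zero sites (the sample
#' size is taken from the `ms` command echo when present).
#'
#' @param file path or connection.
#' @return list of [HaplotypeDataset-class] objects.
#' @export
readMs <- function(file) {
  lines <- readLines(file)
  nsam <- NA_integer_
  if (length(lines) && grepl("^\\s*ms\\s+\\d+\\s+\\d+", lines[1]))
    nsam <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][2])
  reps <- which(trimws(lines) == "//")
  if (!length(reps)) stop("no '//' replicate separators found")
  datasets <- vector("list", length(reps))
  bounds <- c(reps, length(lines) + 1)
  for (r in seq_along(reps)) {
    block <- lines[(bounds[r] + 1):(bounds[r + 1] - 1)]
    segline <- grep("^segsites:", trimws(block), value = TRUE)
    if (length(segline) != 1) stop("malformed replicate: missing segsites")
    S <- as.integer(sub("^segsites:\\s*", "", trimws(segline)))
    if (is.na(S)) stop("malformed segsites line")
    if (S == 0) {
      n <- if (is.na(nsam)) 0L else nsam
      datasets[[r]] <- newHaplotypeDataset(matrix(integer(), n, 0), numeric())
      next
    }
    posline <- grep("^positions:", trimws(block), value = TRUE)
    if (length(posline) != 1) stop("malformed replicate: missing positions")
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "",
                                   trimws(posline)), "\\s+")[[1]])
    if (length(pos) != S) stop("positions do not match segsites")
    rows <- trimws(block[grepl("^[01]+$", trimws(block))])
    if (!length(rows)) stop("no haplotype rows found")
    if (any(nchar(rows) != S)) stop("ragged haplotype rows")
    h <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    # enforce strictly increasing positions in [0, 1) despite printing
    # precision (ms rounds; ties get a nudge)
    o <- order(pos)
    pos <- pos[o]; h <- h[, o, drop = FALSE]
    for (i in seq_along(pos)[-1])
      if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1e-9
    pos <- pmin(pos, 1 - 1e-9 * rev(seq_along(pos)))
    datasets[[r]] <- newHaplotypeDataset(h, pos)
  }
  datasets
}
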