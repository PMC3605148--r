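# Fixtures and brute-force oracles, independent of the package's C++ paths.

hapData <- function(rows, positions = NULL) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (is.null(positions)) positions <- seq(0.1, 0.9, length.out = ncol(m))
  new("HaplotypeDataset", haplotypes = m, positions = positions,
      provenance = list())
}

randomBinaryMatrix <- function(n, S, p = 0.5) {
  matrix(as.integer(runif(n * S) < p), n, S)
}

# drop non-segregating columns (oracle-side normalization)
segColumns <- function(m) {
  if (!ncol(m)) return(m)
  cs <- colSums(m)
  m[, cs > 0 & cs < nrow(m), drop = FALSE]
}

fourGameteIncompatible <- function(m, i, j) {
  g <- unique(paste0(m[, i], m[, j]))
  all(c("00", "01", "10", "11") %in% g)
}

# exhaustive Rmin oracle: minimum number of inter-site gaps whose breakpoints
# cover every four-gamete-incompatible site pair (equivalently, by duality,
# the Hudson-Kaplan bound). Enumerates all gap subsets.
rminOracle <- function(m) {
  m <- segColumns(m)
  S <- ncol(m)
  if (S < 2) return(0L)
  pairs <- list()
  for (i in seq_len(S - 1)) for (j in (i + 1):S)
    if (fourGameteIncompatible(m, i, j)) pairs[[length(pairs) + 1]] <- c(i, j)
  if (!length(pairs)) return(0L)
  gaps <- seq_len(S - 1) # gap g sits between sites g and g+1
  for (size in seq_along(gaps)) {
    combs <- utils::combn(gaps, size, simplify = FALSE)
    for (cc in combs) {
      covered <- vapply(pairs, function(p) any(cc >= p[1] & cc < p[2]),
                        logical(1))
      if (all(covered)) return(size)
    }
  }
  length(gaps)
}

# direct r^2 mean oracle
znsOracle <- function(m) {
  m <- segColumns(m)
  S <- ncol(m)
  if (S < 2) return(NA_real_)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    p1 <- mean(m[, i]); p2 <- mean(m[, j])
    D <- mean(m[, i] * m[, j]) - p1 * p2
    tot <- tot + D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  }
  tot / (S * (S - 1) / 2)
}

# Kingman tree topology by random merging; returns the basal split sizes
kingmanBasalSplit <- function(n) {
  groups <- as.list(seq_len(n))
  while (length(groups) > 2) {
    pick <- sample.int(length(groups), 2)
    groups[[pick[1]]] <- c(groups[[pick[1]]], groups[[pick[2]]])
    groups[[pick[2]]] <- NULL
  }
  c(length(groups[[1]]), length(groups[[2]]))
}
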