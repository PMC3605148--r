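## Gaussian discriminant classification of feature vectors into
## recombination-history models, with jackknife (leave-one-out)
## cross-validation. Uniform priors throughout (the experimental designs
## are balanced); features are standardized inside each training set, NA
## features are imputed with the training-set mean, zero-variance features
## are dropped, and a small ridge is added if a covariance is singular.

prepareFeatures <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  x
}

# standardize + impute on the training set; returns transform closure data
trainTransform <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- is.finite(scl) & scl > 0
  list(imputeMeans = mu, center = ctr, scale = ifelse(keep, scl, 1),
       keep = keep,
       apply = function(z) {
         z <- as.matrix(z)
         for (j in seq_len(ncol(z))) z[is.na(z[, j]), j] <- mu[j]
         scale(z, center = ctr, scale = ifelse(keep, scl, 1))[, keep,
                                                             drop = FALSE]
       })
}

ridgeChol <- function(sigma) {
  d <- ncol(sigma)
  ridge <- 0
  eps <- 1e-6 * sum(diag(sigma)) / d
  repeat {
    ch <- tryCatch(chol(sigma + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, ridge = ridge))
    ridge <- if (ridge == 0) eps else ridge * 10
    if (ridge > 1e6 * eps) stop("covariance matrix is irreparably singular")
  }
}

fitDiscriminant <- function(x, labels, method, standardize = TRUE) {
  x <- prepareFeatures(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (any(table(labels) < 2)) stop("each class needs at least two rows")
  tr <- if (standardize) trainTransform(x) else {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    list(imputeMeans = mu, center = rep(0, ncol(x)), scale = rep(1, ncol(x)),
         keep = rep(TRUE, ncol(x)),
         apply = function(z) {
           z <- as.matrix(z)
           for (j in seq_len(ncol(z))) z[is.na(z[, j]), j] <- mu[j]
           z
         })
  }
  z <- tr$apply(x)
  d <- ncol(z)
  lev <- levels(labels)
  means <- matrix(0, length(lev), d, dimnames = list(lev, colnames(z)))
  ridge <- 0
  classCov <- list()
  if (method == "lda") {
    W <- matrix(0, d, d)
    for (k in lev) {
      zk <- z[labels == k, , drop = FALSE]
      means[k, ] <- colMeans(zk)
      W <- W + crossprod(sweep(zk, 2, means[k, ]))
    }
    sigma <- W / (nrow(z) - length(lev))
    rc <- ridgeChol(sigma)
    ridge <- rc$ridge
    pooled <- sigma + diag(rc$ridge, d)
  } else {
    pooled <- matrix(0, 0, 0)
    for (k in lev) {
      zk <- z[labels == k, , drop = FALSE]
      means[k, ] <- colMeans(zk)
      sk <- crossprod(sweep(zk, 2, means[k, ])) / (nrow(zk) - 1)
      rc <- ridgeChol(sk)
      ridge <- max(ridge, rc$ridge)
      classCov[[k]] <- sk + diag(rc$ridge, ncol(sk))
    }
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("V", seq_len(ncol(x)))
  new("DiscriminantModel", method = method, labels = lev, means = means,
      pooledCov = if (method == "lda") pooled else matrix(0, 0, 0),
      classCov = classCov, center = tr$center, scale = tr$scale,
      keep = tr$keep, imputeMeans = tr$imputeMeans, ridge = ridge,
      featureNames = fn)
}

#' Fit a discriminant classifier
#'
#' `fitLda()` fits a linear discriminant (Gaussian classes, pooled
#' covariance); `fitQda()` a quadratic discriminant (per-class covariance).
#' Class priors are uniform. Features are standardized to zero mean and
#' unit variance on the training set (`standardize = FALSE` disables this;
#' LDA predictions are invariant to affine feature rescaling, so this only
#' matters when a ridge is triggered); `NA` entries are imputed with the
#' training-set feature mean.
#'
#' @param x numeric feature matrix or data.frame (rows = datasets).
#' @param labels class labels, one per row.
#' @param standardize standardize features on the training set.
#' @return a [DiscriminantModel-class].
#' @seealso [predictModel()], [loocvAccuracy()]
#' @export
fitLda <- function(x, labels, standardize = TRUE)
  fitDiscriminant(x, labels, "lda", standardize)

#' @rdname fitLda
#' @export
fitQda <- function(x, labels, standardize = TRUE)
  fitDiscriminant(x, labels, "qda", standardize)

#' Classify feature rows
#'
#' Assigns each row to the class with the highest discriminant score
#' (uniform priors: for LDA the score is minus half the Mahalanobis
#' distance to the class mean; QDA adds the log-determinant term). Ties are
#' broken deterministically in favor of the earlier label in the model's
#' declared label order.
#'
#' @param model a [DiscriminantModel-class].
#' @param x feature matrix with the training columns.
#' @return factor of assigned labels.
#' @export
predictModel <- function(model, x) {
  x <- prepareFeatures(x)
  if (ncol(x) != length(model@keep))
    stop("feature schema mismatch")
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- model@imputeMeans[j]
  z <- scale(x, center = model@center, scale = model@scale)[, model@keep,
                                                            drop = FALSE]
  lev <- model@labels
  scores <- matrix(NA_real_, nrow(z), length(lev))
  chPooled <- if (model@method == "lda") chol(model@pooledCov) else NULL
  for (ki in seq_along(lev)) {
    dev <- sweep(z, 2, model@means[ki, ])
    if (model@method == "lda") {
      y <- backsolve(chPooled, t(dev), transpose = TRUE)
      scores[, ki] <- -0.5 * colSums(y^2)
    } else {
      sk <- model@classCov[[lev[ki]]]
      ch <- chol(sk)
      y <- backsolve(ch, t(dev), transpose = TRUE)
      scores[, ki] <- -0.5 * colSums(y^2) - sum(log(diag(ch)))
    }
  }
  factor(lev[max.col(scores, ties.method = "first")], levels = lev)
}

#' @rdname predictModel
#' @param object,newdata standard `predict` arguments.
#' @param ... unused.
#' @export
setMethod("predict", "DiscriminantModel",
          function(object, newdata, ...) predictModel(object, newdata))

#' Jackknife (leave-one-out) classification accuracy
#'
#' Each dataset row is left out in turn, the discriminant refitted on the
#' remainder, and the held-out row assigned; accuracy is the fraction
#' reassigned to its true model. `refit = "downdate"` uses an exact
#' rank-one downdate of the class mean and pooled scatter instead of a full
#' refit (LDA without standardization only; equivalent up to ridge effects
#' and much faster at large n).
#'
#' @inheritParams fitLda
#' @param method `"lda"` or `"qda"`.
#' @param refit `"refit"` or `"downdate"`.
#' @param features optional character subset of feature columns to use.
#' @return an [AccuracyReport-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' loocvAccuracy(x, rep(c("a", "b"), each = 20))
#' @export
loocvAccuracy <- function(x, labels, method = c("lda", "qda"),
                          refit = c("refit", "downdate"),
                          standardize = TRUE, features = NULL) {
  method <- match.arg(method)
  refit <- match.arg(refit)
  x <- prepareFeatures(if (!is.null(features)) {
    miss <- setdiff(features, colnames(x))
    if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
    x[, features, drop = FALSE]
  } else x)
  labels <- factor(labels)
  n <- nrow(x)
  if (n != length(labels)) stop("labels must match rows")
  if (any(table(labels) < 3)) stop("each class needs at least three rows")
  assigned <- factor(rep(NA_character_, n), levels = levels(labels))

  if (refit == "downdate") {
    if (method != "lda")
      stop("downdate LOOCV is implemented for LDA only")
    # impute once on the full data (training-mean policy), no standardization
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
    lev <- levels(labels)
    d <- ncol(x)
    nk <- table(labels)
    sums <- rowsum(x, labels)
    W <- matrix(0, d, d)
    for (k in lev) {
      zk <- x[labels == k, , drop = FALSE]
      W <- W + crossprod(sweep(zk, 2, sums[k, ] / nk[[k]]))
    }
    for (i in seq_len(n)) {
      ci <- as.character(labels[i])
      xi <- x[i, ]
      mk <- sums[ci, ] / nk[[ci]]
      dev <- xi - mk
      Wi <- W - (nk[[ci]] / (nk[[ci]] - 1)) * tcrossprod(dev)
      sigma <- Wi / (n - 1 - length(lev))
      rc <- ridgeChol(sigma)
      ch <- rc$chol
      best <- NULL
      bestScore <- -Inf
      for (k in lev) {
        mki <- if (k == ci) (sums[k, ] - xi) / (nk[[k]] - 1)
               else sums[k, ] / nk[[k]]
        y <- backsolve(ch, xi - mki, transpose = TRUE)
        sc <- -0.5 * sum(y^2)
        if (sc > bestScore) { bestScore <- sc; best <- k }
      }
      assigned[i] <- best
    }
  } else {
    for (i in seq_len(n)) {
      m <- fitDiscriminant(x[-i, , drop = FALSE], labels[-i], method,
                           standardize)
      assigned[i] <- as.character(predictModel(m, x[i, , drop = FALSE]))
    }
  }
  confusion <- table(true = labels, assigned = assigned)
  perClass <- diag(confusion) / rowSums(confusion)
  new("AccuracyReport", confusion = unclass(confusion),
      perClass = setNames(as.numeric(perClass), levels(labels)),
      overall = sum(diag(confusion)) / n, method = method,
      features = if (is.null(features)) colnames(x) else features)
}

#' @describeIn loocvAccuracy overall assignment rate of a report
#' @param report an [AccuracyReport-class].
#' @export
overallAccuracy <- function(report) report@overall

#' @describeIn loocvAccuracy confusion matrix of a report
#' @export
confusionMatrix <- function(report) report@confusion
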