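#' Binarize a numeric trait with two-cluster k-means
#'
#' One-dimensional two-means has an exact solution: the optimal 2-partition
#' by within-cluster squared distance is a contiguous split of the sorted
#' values, found here by scanning all splits with prefix sums. Every
#' observed isolate is labeled (no abstentions); label 1 is the cluster with
#' the larger mean. Ties in total squared error are broken so that the
#' boundary point falls in the lower-mean cluster. Labels are invariant
#' under increasing affine transforms of the input.
#'
#' @param values numeric vector (NA = missing), named by isolate.
#' @param traitId identifier recorded on the result.
#' @return A [BinarizationResult-class].
#' @export
binarizeKmeans <- function(values, traitId = "trait") {
  obs <- which(!is.na(values))
  x <- values[obs]
  if (length(x) < 4) stop("k-means binarization needs >= 4 observed values",
                          call. = FALSE)
  if (length(unique(x)) < 2)
    stop("constant trait cannot be binarized", call. = FALSE)
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  sseLo <- cs2[k] - cs[k]^2 / k
  sseHi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  sse <- sseLo + sseHi
  # last argmin: boundary point joins the lower cluster on exact ties
  kBest <- max(which(sse <= min(sse) + 0))
  lab <- integer(n)
  lab[o] <- c(rep(0L, kBest), rep(1L, n - kBest))
  means <- c(mean(xs[seq_len(kBest)]), mean(xs[(kBest + 1):n]))
  labels <- rep(NA_integer_, length(values))
  labels[obs] <- lab
  names(labels) <- names(values)
  new("BinarizationResult", traitId = traitId, method = "kmeans",
      labels = labels, means = means, posterior = numeric(0),
      nExcluded = 0L)
}

# Deterministic univariate 2-component Gaussian mixture EM.
# Init: from the exact 1-D two-means partition (cluster means, weights and
# within-cluster variances). Convergence: change in mean per-sample
# log-likelihood below `tol` (1e-3, the scikit-learn GaussianMixture
# convention). Both choices matter: the unconstrained unequal-variance MLE
# in 1-D is a degenerate narrow spike on a few extreme points, and a
# tightly converged EM will drift there even from a good start; stopping at
# this tolerance keeps the two-cluster solution the initialization finds.
# Both are affine-invariant.
# Failure: no convergence within maxIter, a component weight < 2/n, or a
# variance collapsing below 1e-10 x the data variance.
fitGmm2 <- function(x, maxIter = 500L, tol = 1e-3) {
  n <- length(x)
  v0 <- var(x)
  km <- binarizeKmeans(setNames(x, seq_along(x)))
  g <- binaryLabels(km)
  mu <- unname(km@means)
  sig2 <- pmax(c(var(x[g == 0]), var(x[g == 1])), v0 / 100, 1e-12)
  sig2[is.na(sig2)] <- v0 / 100
  w <- pmax(c(mean(g == 0), mean(g == 1)), 1 / n)
  vFloor <- 1e-10 * v0
  ll0 <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(sig2[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(sig2[2]))
    tot <- d1 + d2
    if (any(tot <= 0) || anyNA(tot)) return(list(ok = FALSE, why = "degenerate density"))
    r <- d1 / tot
    ll <- mean(log(tot))
    nk <- c(sum(r), n - sum(r))
    if (any(nk < 2)) return(list(ok = FALSE, why = "component weight < 2/n"))
    mu <- c(sum(r * x) / nk[1], sum((1 - r) * x) / nk[2])
    sig2 <- c(sum(r * (x - mu[1])^2) / nk[1],
              sum((1 - r) * (x - mu[2])^2) / nk[2])
    if (any(sig2 < vFloor)) return(list(ok = FALSE, why = "variance collapse"))
    w <- nk / n
    if (abs(ll - ll0) < tol) { converged <- TRUE; break }
    ll0 <- ll
  }
  if (!converged) return(list(ok = FALSE, why = "no convergence"))
  list(ok = TRUE, mu = mu, sig2 = sig2, w = w, resp = r)
}

#' Binarize a numeric trait with a two-component Gaussian mixture
#'
#' Fits two Gaussians by EM (deterministic quantile initialization) and
#' labels each observed isolate by the larger-mean component if and only if
#' its maximum posterior probability reaches `posteriorCutoff`; isolates
#' below the cutoff abstain (label NA) and are excluded from the
#' association for this trait. On fit failure (non-convergence, a
#' near-empty component, or variance collapse) the `onFailure` policy either
#' skips the trait or falls back to k-means.
#'
#' @param values numeric vector (NA = missing), named by isolate.
#' @param posteriorCutoff minimum posterior for a call (default 0.85).
#' @param onFailure "skip" (raise a skip condition) or "kmeans".
#' @param traitId identifier recorded on the result.
#' @param maxIter EM iteration cap.
#' @return A [BinarizationResult-class]; on skip, an error of class
#'   `pairGWAS_binarization_skip` is signalled.
#' @export
binarizeGmm <- function(values, posteriorCutoff = 0.85,
                        onFailure = c("skip", "kmeans"), traitId = "trait",
                        maxIter = 500L) {
  onFailure <- match.arg(onFailure)
  obs <- which(!is.na(values))
  x <- values[obs]
  if (length(x) < 6) stop("GMM binarization needs >= 6 observed values",
                          call. = FALSE)
  fit <- if (length(unique(x)) < 2) list(ok = FALSE, why = "constant trait")
         else fitGmm2(x, maxIter = maxIter)
  if (!fit$ok) {
    if (onFailure == "kmeans") {
      if (length(unique(x)) < 2)
        stop("constant trait cannot be binarized", call. = FALSE)
      res <- binarizeKmeans(values, traitId = traitId)
      res@method <- "gmm_kmeans_fallback"
      return(res)
    }
    stop(structure(class = c("pairGWAS_binarization_skip", "error",
                             "condition"),
                   list(message = sprintf("GMM fit failed for '%s': %s",
                                          traitId, fit$why),
                        call = NULL)))
  }
  hi <- which.max(fit$mu)              # component coding the trait as 1
  postHi <- if (hi == 1) fit$resp else 1 - fit$resp
  maxPost <- pmax(postHi, 1 - postHi)
  lab <- ifelse(maxPost >= posteriorCutoff,
                as.integer(postHi >= 0.5), NA_integer_)
  labels <- rep(NA_integer_, length(values))
  labels[obs] <- lab
  names(labels) <- names(values)
  posterior <- rep(NA_real_, length(values))
  posterior[obs] <- postHi
  names(posterior) <- names(values)
  new("BinarizationResult", traitId = traitId, method = "gmm",
      labels = labels, means = sort(fit$mu), posterior = posterior,
      nExcluded = sum(is.na(lab)))
}

#' Binarize every numeric trait of a TraitTable
#'
#' Binary traits pass through untouched. Returns the binarized label matrix
#' alongside per-trait [BinarizationResult-class] objects and a log
#' data.frame (written as the binarization log by the pipeline). Traits
#' skipped on GMM failure are dropped from the label matrix.
#'
#' @param traits a [TraitTable-class].
#' @param method "gmm" or "kmeans".
#' @param posteriorCutoff GMM abstention cutoff.
#' @param onFailure GMM failure policy.
#' @return list(labels = isolate x trait integer matrix with NA,
#'   results = named list of BinarizationResult or NULL for binary traits,
#'   log = data.frame).
#' @export
binarizeTraits <- function(traits, method = c("gmm", "kmeans"),
                           posteriorCutoff = 0.85,
                           onFailure = c("skip", "kmeans")) {
  method <- match.arg(method)
  onFailure <- match.arg(onFailure)
  v <- traitValues(traits)
  kinds <- traitKinds(traits)
  labels <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  results <- setNames(vector("list", ncol(v)), colnames(v))
  log <- data.frame(trait = colnames(v), kind = unname(kinds),
                    method = "none", mean_low = NA_real_,
                    mean_high = NA_real_, n_excluded = 0L,
                    outcome = "passthrough", stringsAsFactors = FALSE)
  drop <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    id <- colnames(v)[j]
    if (kinds[[id]] == "binary") {
      labels[, j] <- as.integer(v[, j])
      next
    }
    res <- tryCatch({
      if (method == "gmm")
        binarizeGmm(v[, j], posteriorCutoff = posteriorCutoff,
                    onFailure = onFailure, traitId = id)
      else binarizeKmeans(v[, j], traitId = id)
    }, pairGWAS_binarization_skip = function(e) e,
       error = function(e) e)
    if (inherits(res, "condition")) {
      warning(sprintf("trait '%s' skipped: %s", id, conditionMessage(res)))
      drop[j] <- TRUE
      log$method[j] <- method
      log$outcome[j] <- paste("skipped:", conditionMessage(res))
      next
    }
    labels[, j] <- binaryLabels(res)
    results[[j]] <- res
    log$method[j] <- res@method
    log$mean_low[j] <- res@means[1]
    log$mean_high[j] <- res@means[2]
    log$n_excluded[j] <- res@nExcluded
    log$outcome[j] <- "ok"
  }
  list(labels = labels[, !drop, drop = FALSE],
       results = results[!drop], log = log)
}
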