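# Gaussian mixture modality screen: EM fitting, BIC model selection and
# the unimodal / multimodal verdict that separates stable contacts from
# side-chain rearrangements.

.EM_TOL <- 1e-4        # log-likelihood gain per sample
.EM_MAX_ITER <- 500L
.EM_RETRIES <- 3L
.VAR_FLOOR <- 1e-10
.WEIGHT_FLOOR <- 1e-8

# one EM run from a seeded k-means-style initialization; returns NULL on a
# degenerate fit (collapsed weight or variance, or an empty component)
.emRun <- function(x, k, seed) {
  n <- length(x)
  set.seed(seed)
  if (k == 1L) {
    m <- mean(x); v <- max(var(x) * (n - 1) / n, .VAR_FLOOR)
    ll <- sum(dnorm(x, m, sqrt(v), log = TRUE))
    return(list(weights = 1, means = m, variances = v, logLik = ll,
                converged = TRUE, iterations = 0L))
  }
  if (length(unique(x)) < k) return(NULL)
  km <- tryCatch(suppressWarnings(kmeans(x, centers = k, nstart = 5L)),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  w <- km$size / n
  mu <- as.numeric(km$centers)
  v <- vapply(seq_len(k), function(j) {
    xs <- x[km$cluster == j]
    max(sum((xs - mu[j])^2) / length(xs), .VAR_FLOOR)
  }, numeric(1))

  llOld <- -Inf
  converged <- FALSE
  it <- 0L
  logdens <- matrix(NA_real_, n, k)
  rowMax <- function(m) {
    out <- m[, 1L]
    for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
    out
  }
  while (it < .EM_MAX_ITER) {
    it <- it + 1L
    for (j in seq_len(k))
      logdens[, j] <- log(w[j]) + dnorm(x, mu[j], sqrt(v[j]), log = TRUE)
    mrow <- rowMax(logdens)
    lse <- mrow + log(rowSums(exp(logdens - mrow)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)          # n x k responsibilities
    nk <- colSums(resp)
    if (any(nk < .WEIGHT_FLOOR * n)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], numeric(1))
    if (any(v < .VAR_FLOOR)) return(NULL)
    if (is.finite(llOld) && (ll - llOld) / n < .EM_TOL) {
      converged <- TRUE
      break
    }
    llOld <- ll
  }
  for (j in seq_len(k))
    logdens[, j] <- log(w[j]) + dnorm(x, mu[j], sqrt(v[j]), log = TRUE)
  mrow <- rowMax(logdens)
  ll <- sum(mrow + log(rowSums(exp(logdens - mrow))))
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], variances = v[ord], logLik = ll,
       converged = converged, iterations = it)
}

.bic <- function(logLik, k, n) (3 * k - 1) * log(n) - 2 * logLik

#' Fit a k-component Gaussian mixture to a distance series
#'
#' Expectation-maximization on the empirical density of the series, from a
#' seeded k-means initialization.  Convergence is declared when the
#' per-sample log-likelihood gain drops below 1e-4, within 500 iterations.
#' A degenerate or non-convergent run is retried from fresh seeds (up to 3
#' retries); if all runs fail the fit is returned flagged
#' \code{converged = FALSE} with a warning.  BIC is
#' \eqn{(3k - 1)\,\ln n - 2\,\ln L}: smaller is better.
#'
#' @param x numeric vector of distances (one value per frame).
#' @param k number of Gaussian components (requires
#'   \code{length(x) >= 10 k}).
#' @param seed integer seed for the initialization (recorded in the fit).
#' @param seriesId identifier stored in the fit.
#' @return a \linkS4class{GMMFit} with modality still unclassified.
#' @examples
#' set.seed(7)
#' x <- c(rnorm(500, 2.7, 0.3), rnorm(500, 5.5, 0.4))
#' fitGMM(x, k = 2, seed = 1)
#' @export
fitGMM <- function(x, k, seed = 1L, seriesId = "series") {
  k <- as.integer(k); seed <- as.integer(seed)
  if (k < 1L) stop("k must be >= 1")
  x <- as.numeric(x)
  if (length(x) < 10L * k)
    stop("series too short for k = ", k, " (need >= ", 10L * k, " samples)")
  fit <- NULL
  for (attempt in 0:.EM_RETRIES) {
    fit <- .emRun(x, k, seed + 1000L * attempt)
    if (!is.null(fit) && fit$converged) break
  }
  if (is.null(fit)) {
    warning("GMM fit failed for '", seriesId, "' at k = ", k,
            " after ", .EM_RETRIES + 1L, " attempts")
    return(new("GMMFit", seriesId = seriesId, k = k,
               weights = rep(1 / k, k), means = rep(mean(x), k),
               variances = rep(max(var(x), .VAR_FLOOR), k),
               logLik = NA_real_, bic = Inf, converged = FALSE,
               seed = seed))
  }
  if (!fit$converged)
    warning("GMM fit for '", seriesId, "' at k = ", k,
            " did not converge within ", .EM_MAX_ITER, " iterations")
  new("GMMFit", seriesId = seriesId, k = k, weights = fit$weights,
      means = fit$means, variances = fit$variances, logLik = fit$logLik,
      bic = .bic(fit$logLik, k, length(x)), converged = fit$converged,
      seed = seed)
}

#' Select the number of Gaussians by BIC
#'
#' Fits mixtures with 1 to \code{kMax} components and returns the fit with
#' the smallest BIC; ties break toward fewer components.  Values of k
#' needing more than \code{length(x) / 10} components are skipped.  A
#' zero-variance (constant) series is classified unimodal without fitting.
#'
#' @inheritParams fitGMM
#' @param kMax largest component count tried (default 5).
#' @return the BIC-optimal \linkS4class{GMMFit}, or \code{NULL} (with a
#'   message) if every fit failed.
#' @export
selectModel <- function(x, kMax = 5L, seed = 1L, seriesId = "series") {
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1")
  x <- as.numeric(x)
  if (var(x) == 0) {
    return(new("GMMFit", seriesId = seriesId, k = 1L, weights = 1,
               means = mean(x), variances = 0, logLik = NA_real_,
               bic = -Inf, converged = TRUE, seed = as.integer(seed),
               modality = "unimodal"))
  }
  best <- NULL
  for (k in seq_len(kMax)) {
    if (length(x) < 10L * k) break
    fit <- withCallingHandlers(
      fitGMM(x, k, seed = seed, seriesId = seriesId),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!fit@converged) next
    if (is.null(best) || fit@bic < best@bic) best <- fit
  }
  if (is.null(best))
    message("selectModel: all fits failed for '", seriesId,
            "'; series excluded")
  best
}

#' Classify a mixture fit as unimodal or multimodal
#'
#' Applies the substate merge rules before the verdict: components with
#' weight below \code{minWeight} are dropped, and components whose means
#' lie within \code{minSeparation} Angstrom are merged
#' (weight-averaged).  The series is multimodal iff at least two
#' components survive.  Both thresholds guard against BIC splitting a
#' heavy-tailed unimodal density into spurious substates; setting both to
#' 0 recovers the raw BIC verdict.
#'
#' @param fit a \linkS4class{GMMFit}.
#' @param minWeight weight floor (fraction, default 0.05).
#' @param minSeparation minimum mean separation in Angstrom (default 1.0).
#' @return the fit with \code{modality} and the surviving (pruned/merged)
#'   components set.
#' @export
classifyModality <- function(fit, minWeight = 0.05, minSeparation = 1.0) {
  stopifnot(is(fit, "GMMFit"))
  w <- fit@weights; m <- fit@means; v <- fit@variances
  keep <- w >= minWeight
  if (!any(keep)) keep[which.max(w)] <- TRUE
  w <- w[keep]; m <- m[keep]; v <- v[keep]
  w <- w / sum(w)
  ord <- order(m)
  w <- w[ord]; m <- m[ord]; v <- v[ord]
  # merge adjacent components closer than the separation floor
  i <- 1L
  while (i < length(m)) {
    if (m[i + 1L] - m[i] < minSeparation) {
      wt <- w[i] + w[i + 1L]
      mMerged <- (w[i] * m[i] + w[i + 1L] * m[i + 1L]) / wt
      # moment-matched variance of the merged pair
      vMerged <- (w[i] * (v[i] + m[i]^2) +
                  w[i + 1L] * (v[i + 1L] + m[i + 1L]^2)) / wt - mMerged^2
      w <- c(w[seq_len(i - 1L)], wt, w[-seq_len(i + 1L)])
      m <- c(m[seq_len(i - 1L)], mMerged, m[-seq_len(i + 1L)])
      v <- c(v[seq_len(i - 1L)], vMerged, v[-seq_len(i + 1L)])
    } else i <- i + 1L
  }
  fit@prunedWeights <- w
  fit@prunedMeans <- m
  fit@prunedVariances <- v
  fit@modality <- if (length(m) >= 2L) "multimodal" else "unimodal"
  fit
}

#' Screen side-chain series for rearrangements
#'
#' Runs BIC model selection and modality classification on every series of
#' a side-chain / polar \linkS4class{DistanceSeriesSet}.  Each multimodal
#' series becomes one side-chain \linkS4class{DynamicComponent} (a
#' side-chain rearrangement is characterized by a single distance time
#' series); unimodal series are reported separately as stable contacts.
#' The components and the stable contacts partition the input.
#'
#' @param x a \linkS4class{DistanceSeriesSet} (modes sidechain_vdw /
#'   polar).
#' @param kMax,seed,minWeight,minSeparation see [selectModel()] and
#'   [classifyModality()].
#' @return list with \code{components} (a \linkS4class{ComponentSet}),
#'   \code{stableContacts} (character series ids), \code{fits} (named list
#'   of \linkS4class{GMMFit}), and \code{summary} (one data.frame row per
#'   series: k selected, modality, BIC, surviving substates).
#' @export
screenSidechainComponents <- function(x, kMax = 5L, seed = 1L,
                                      minWeight = 0.05,
                                      minSeparation = 1.0) {
  vals <- SummarizedExperiment::assay(x, "distance")
  ids <- seriesIds(x)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  comps <- list(); stable <- character()
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fit <- selectModel(vals[i, ], kMax = kMax, seed = seed + i,
                       seriesId = ids[i])
    if (is.null(fit)) next
    fit <- classifyModality(fit, minWeight = minWeight,
                            minSeparation = minSeparation)
    fits[[i]] <- fit
    nSub <- length(fit@prunedMeans)
    rows[[i]] <- data.frame(
      series_id = ids[i], k_selected = fit@k, modality = fit@modality,
      n_substates = nSub, bic = fit@bic,
      substate_means = paste(sprintf("%.3f", fit@prunedMeans),
                             collapse = ";"),
      substate_weights = paste(sprintf("%.3f", fit@prunedWeights),
                               collapse = ";"),
      stringsAsFactors = FALSE)
    if (fit@modality == "multimodal") {
      comps[[length(comps) + 1L]] <- new("DynamicComponent",
        componentId = paste0("SC", length(comps) + 1L, "|", ids[i]),
        kind = "sidechain", members = ids[i])
    } else {
      stable <- c(stable, ids[i])
    }
  }
  list(components = new("ComponentSet", components = comps,
                        metadata = list(seed = seed, kMax = kMax,
                                        minWeight = minWeight,
                                        minSeparation = minSeparation)),
       stableContacts = stable,
       fits = fits[!vapply(fits, is.null, logical(1))],
       summary = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}
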