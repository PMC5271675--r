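# Dynamic cross-correlation of distance time series and single-linkage
# extraction of global-domain-motion components.

#' Dynamic cross-correlation of two distance series
#'
#' The zero-lag normalized cross-correlation of two scalar distance time
#' series, i.e. their Pearson coefficient
#' \eqn{r = \mathrm{cov}(a, b) / (\sigma_a \sigma_b)}.  Symmetric,
#' invariant under adding constants and positive rescaling, sign-flipped
#' by negating one series.  Because only distances enter, no structure
#' superimposition is ever needed.
#'
#' @param a,b numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return correlation coefficient in [-1, 1].
#' @examples
#' dcc(1:10, 2 * (1:10) + 3)   #  1
#' dcc(1:10, -(1:10))          # -1
#' @export
dcc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 2L) stop("series must have length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for a zero-variance series")
  cor(a, b)
}

#' Pairwise DCC matrix
#'
#' The full symmetric matrix of zero-lag cross-correlations over a set of
#' distance series.  Zero-variance series cannot carry a defined
#' correlation and are excluded with a logged list.
#'
#' @param x a \linkS4class{DistanceSeriesSet} or a numeric matrix with one
#'   series per row (rownames as series ids).
#' @return symmetric correlation matrix with unit diagonal, dimnames the
#'   usable series ids.
#' @export
dccMatrix <- function(x) {
  vals <- if (is(x, "DistanceSeriesSet")) seriesValues(x) else as.matrix(x)
  if (is.null(rownames(vals)))
    rownames(vals) <- paste0("s", seq_len(nrow(vals)))
  sds <- apply(vals, 1L, sd)
  if (any(sds == 0)) {
    message("dccMatrix: excluding ", sum(sds == 0),
            " zero-variance series: ",
            paste(utils::head(rownames(vals)[sds == 0], 5L),
                  collapse = ", "),
            if (sum(sds == 0) > 5L) ", ..." else "")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2L) stop("need at least 2 usable series")
  m <- cor(t(vals))
  diag(m) <- 1
  m
}

#' Extract domain-motion components by single-linkage clustering
#'
#' Agglomerative nearest-point (single-linkage) clustering of the series
#' on the dissimilarity \eqn{d(i, j) = 1 - r(i, j)}, with the dendrogram
#' cut at \eqn{d = 1 - r_{min}} so that series joined at correlation at or
#' above \code{rMin} fall in one cluster.  Clusters with at least
#' \code{minClusterSize} members are returned as domain components; a
#' domain motion is a collection of highly correlated series, so
#' singletons are discarded from the domain set.
#'
#' Single linkage at a threshold is equivalent to taking connected
#' components of the graph with edges \eqn{r(i, j) \ge r_{min}}.
#'
#' @param dccm symmetric correlation matrix from [dccMatrix()].
#' @param rMin correlation cutoff in (0, 1); default 0.95.
#' @param minClusterSize smallest cluster reported as a domain component
#'   (default 2).
#' @return a \linkS4class{ComponentSet} of \code{kind = "domain"}
#'   components; its metadata carries the \code{hclust} linkage and the
#'   full cluster membership vector.
#' @export
clusterSeries <- function(dccm, rMin = 0.95, minClusterSize = 2L) {
  if (!is.matrix(dccm) || nrow(dccm) != ncol(dccm))
    stop("dccm must be a square matrix")
  if (rMin <= 0 || rMin >= 1) stop("rMin must lie in (0, 1)")
  minClusterSize <- as.integer(minClusterSize)
  ids <- rownames(dccm)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dccm)))

  if (nrow(dccm) < 2L)
    return(new("ComponentSet", components = list(),
               metadata = list(rMin = rMin,
                               minClusterSize = minClusterSize)))

  hc <- hclust(stats::as.dist(1 - dccm), method = "single")
  # inclusive cut: series at exactly rMin belong to one cluster
  memb <- cutree(hc, h = (1 - rMin) + 1e-12)

  comps <- list()
  for (cl in unique(memb[order(match(names(memb), ids))])) {
    members <- ids[memb == cl]
    if (length(members) >= minClusterSize)
      comps[[length(comps) + 1L]] <- new("DynamicComponent",
        componentId = paste0("DOM", length(comps) + 1L),
        kind = "domain", members = members)
  }
  new("ComponentSet", components = comps,
      metadata = list(rMin = rMin, minClusterSize = minClusterSize,
                      linkage = hc, membership = memb))
}

#' Linkage table of a domain component set
#'
#' The agglomeration schedule behind [clusterSeries()] as a data.frame
#' (merge indices and heights), suitable for CSV export.
#'
#' @param components a \linkS4class{ComponentSet} from [clusterSeries()].
#' @return data.frame with columns \code{merge1}, \code{merge2},
#'   \code{height} (dissimilarity 1 - r at the merge).
#' @export
linkageTable <- function(components) {
  hc <- components@metadata$linkage
  if (is.null(hc)) stop("component set carries no linkage")
  data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
             height = hc$height)
}
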