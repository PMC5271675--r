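# DCC-based network over dynamic components: coupling, edges, communities.

#' Coupling between two dynamic components
#'
#' The absolute value of the average DCC coefficient over all cross pairs
#' of member series: the mean is taken first and the absolute value
#' second, so anti-correlated cross pairs cancel.  Components must be
#' disjoint in series membership.
#'
#' @param compX,compY \linkS4class{DynamicComponent} objects.
#' @param dccm full-series correlation matrix covering every member series
#'   of both components.
#' @return coupling coefficient in [0, 1].
#' @examples
#' m <- matrix(c(1, -0.8, -0.8, 1), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' x <- new("DynamicComponent", componentId = "x", kind = "sidechain",
#'          members = "a")
#' y <- new("DynamicComponent", componentId = "y", kind = "sidechain",
#'          members = "b")
#' componentCoupling(x, y, m)  # 0.8
#' @export
componentCoupling <- function(compX, compY, dccm) {
  if (length(intersect(compX@members, compY@members)))
    stop("components '", compX@componentId, "' and '", compY@componentId,
         "' share member series")
  missing <- setdiff(c(compX@members, compY@members), rownames(dccm))
  if (length(missing))
    stop("correlation undefined for member series: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  abs(mean(dccm[compX@members, compY@members]))
}

#' Coupling matrix over a component set
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param dccm full-series correlation matrix covering all member series.
#' @return symmetric matrix of coupling coefficients, diagonal 1 by
#'   convention.
#' @export
couplingMatrix <- function(components, dccm) {
  ids <- componentIds(components)
  n <- length(ids)
  cm <- diag(1, n)
  dimnames(cm) <- list(ids, ids)
  if (n >= 2L)
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n))
        cm[i, j] <- cm[j, i] <-
          componentCoupling(components[[i]], components[[j]], dccm)
  cm
}

#' Build the component network
#'
#' One node per dynamic component, annotated with its kind and size (the
#' number of member series, the node-size convention of the framework).
#' An edge joins two components whose coupling is at or above
#' \code{couplingCutoff} (inclusive, per "minimum average absolute
#' correlation"); edge weight is the coupling.  Isolated nodes are
#' retained unless \code{dropIsolates}.
#'
#' @param components a \linkS4class{ComponentSet} (side-chain and domain
#'   components together).
#' @param dccm full-series correlation matrix covering all member series.
#' @param couplingCutoff minimum absolute average correlation for an edge
#'   (default 0.75).
#' @param dropIsolates drop components with no edge (default FALSE).
#' @return a \linkS4class{ComponentGraph} without community labels.
#' @export
buildNetwork <- function(components, dccm, couplingCutoff = 0.75,
                         dropIsolates = FALSE) {
  if (length(components) < 1L) stop("need at least one component")
  cm <- couplingMatrix(components, dccm)
  adj <- (cm >= couplingCutoff) * cm
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tab <- componentTable(components)
  igraph::V(g)$kind <- tab$kind[match(igraph::V(g)$name,
                                      tab$component_id)]
  igraph::V(g)$size <- tab$size[match(igraph::V(g)$name,
                                      tab$component_id)]
  if (dropIsolates) {
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) g <- igraph::delete_vertices(g, iso)
  }
  nodes <- data.frame(component_id = igraph::V(g)$name,
                      kind = igraph::V(g)$kind,
                      size = igraph::V(g)$size,
                      community = NA_integer_,
                      stringsAsFactors = FALSE)
  new("ComponentGraph", graph = g, coupling = cm, nodes = nodes,
      couplingCutoff = couplingCutoff)
}

#' Detect communities by edge betweenness
#'
#' Girvan-Newman hierarchical edge removal on the network topology; the
#' partition returned is the one maximizing modularity over the removal
#' sequence.  Betweenness is computed on the unweighted topology by
#' default (edge weights remain as attributes); with
#' \code{weightedBetweenness} edges are traversed with length
#' \code{1 / weight}, so strong couplings are short.  Disconnected graph
#' components necessarily end up in different communities.
#'
#' @param x a \linkS4class{ComponentGraph} from [buildNetwork()].
#' @param weightedBetweenness use 1/weight edge lengths (default FALSE).
#' @return the graph with integer community labels filled into its node
#'   table (labels follow node insertion order deterministically).
#' @export
detectCommunities <- function(x, weightedBetweenness = FALSE) {
  g <- x@graph
  if (igraph::vcount(g) == 0L) return(x)
  wts <- if (weightedBetweenness && igraph::ecount(g) > 0)
    1 / igraph::E(g)$weight else NA
  comm <- igraph::cluster_edge_betweenness(
    g, weights = wts, directed = FALSE, modularity = TRUE,
    membership = TRUE)
  memb <- igraph::membership(comm)
  # relabel so community ids follow node insertion order
  lab <- as.integer(factor(memb, levels = unique(memb)))
  x@nodes$community <- lab[match(x@nodes$component_id,
                                 igraph::V(g)$name)]
  igraph::V(x@graph)$community <- lab
  x
}
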