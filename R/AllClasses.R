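#' @import methods
#' @importFrom stats cor cutree dnorm hclust kmeans rnorm runif sd var
#' @importFrom utils write.csv read.csv packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Trajectory of atomic coordinates
#'
#' Holds the Cartesian coordinates of a molecular dynamics trajectory
#' together with its atom and residue tables.  Coordinates are stored as an
#' atoms x 3 x frames array in Angstrom.  Only the 20 standard amino acids
#' are retained; hetero residues, waters, lipids and ions are dropped at
#' load time with a logged count.  Frames are 0-based nowhere: all
#' user-facing frame indices are 1-based.
#'
#' @slot coords numeric array, dim = c(nAtoms, 3, nFrames), Angstrom.
#' @slot atoms data.frame with one row per atom: \code{name} (PDB atom
#'   name), \code{element}, \code{chain}, \code{resno}, \code{resname},
#'   \code{residueIndex} (row of the residue table).
#' @slot residues data.frame with one row per residue: \code{chain},
#'   \code{resno}, \code{resname}.
#' @slot stride integer stride applied at load time.
#' @slot metadata list of provenance fields (source paths, skipped counts).
#'
#' @seealso [readTrajectory()]
#' @export
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame",
                 residues = "data.frame", stride = "integer",
                 metadata = "list"),
  prototype(stride = 1L, metadata = list()))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[3] < 2L)
      msg <- c(msg, "a trajectory needs at least 2 frames")
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "coords and atom table disagree on atom count")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (!all(object@residues$resname %in% .STANDARD_AA))
    msg <- c(msg, "residue table contains non-standard residues")
  if (anyDuplicated(.residueKey(object@residues$chain,
                                object@residues$resno)))
    msg <- c(msg, "residue numbers must be unique within a chain")
  if (length(msg)) msg else TRUE
})

#' Atom selection within a trajectory
#'
#' A named set of atoms of one residue, used as one side of a
#' minimum-distance computation.  The three selection modes follow the
#' contact definitions of the framework: \code{sidechain_nonH} is every
#' non-hydrogen, non-backbone atom; \code{polar_head} is the residue's
#' polar head group (see [polarHeadAtoms()]); \code{calpha} is exactly CA.
#'
#' @slot chain,resno,resname residue identity.
#' @slot mode one of \code{"sidechain_nonH"}, \code{"polar_head"},
#'   \code{"calpha"}.
#' @slot atomNames character vector of selected atom names.
#' @slot atomIdx integer indices into the trajectory atom table.
#' @export
setClass("AtomSelection",
  representation(chain = "character", resno = "integer",
                 resname = "character", mode = "character",
                 atomNames = "character", atomIdx = "integer"))

setValidity("AtomSelection", function(object) {
  if (!object@mode %in% c("sidechain_nonH", "polar_head", "calpha"))
    return("unknown selection mode")
  if (length(object@atomNames) != length(object@atomIdx))
    return("atomNames and atomIdx lengths differ")
  TRUE
})

#' Set of inter-residue distance time series
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are residue-pair
#' distance time series, columns are trajectory frames, and the single
#' assay \code{"distance"} holds distances in Angstrom.  \code{rowData}
#' carries the pair annotation (\code{series_id}, \code{mode},
#' \code{chain_a}, \code{resno_a}, \code{resname_a}, and the \code{_b}
#' counterparts).
#'
#' @seealso [computeSeries()], [dccMatrix()]
#' @export
setClass("DistanceSeriesSet",
         contains = "SummarizedExperiment")

setValidity("DistanceSeriesSet", function(object) {
  if (!"distance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'distance' is required")
  v <- SummarizedExperiment::assay(object, "distance")
  if (nrow(v) > 0 && (any(!is.finite(v)) || any(v < 0)))
    return("distances must be finite and non-negative")
  need <- c("series_id", "mode", "chain_a", "resno_a", "resname_a",
            "chain_b", "resno_b", "resname_b")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    return(paste("rowData must provide:", paste(need, collapse = ", ")))
  TRUE
})

#' Gaussian mixture fit of one distance series
#'
#' Parameters of a univariate Gaussian mixture fitted by
#' expectation-maximization to the probability density of one distance
#' time series, with its BIC score and, once classified, the modality
#' verdict.  \code{prunedWeights}/\code{prunedMeans}/\code{prunedVariances}
#' hold the components surviving the weight floor and mean-separation
#' merge of [classifyModality()].
#'
#' @slot seriesId series identifier.
#' @slot k number of Gaussians fitted.
#' @slot weights,means,variances mixture parameters (weights sum to 1;
#'   means in Angstrom, variances in Angstrom^2).
#' @slot logLik maximized log-likelihood.
#' @slot bic Bayesian information criterion, (3k-1) ln(n) - 2 lnL
#'   (smaller is better).
#' @slot converged logical EM convergence flag.
#' @slot seed integer seed used for initialization.
#' @slot modality \code{"unclassified"}, \code{"unimodal"} or
#'   \code{"multimodal"}.
#' @slot prunedWeights,prunedMeans,prunedVariances surviving components
#'   after classification (empty until classified).
#' @export
setClass("GMMFit",
  representation(seriesId = "character", k = "integer", weights = "numeric",
                 means = "numeric", variances = "numeric", logLik = "numeric",
                 bic = "numeric", converged = "logical", seed = "integer",
                 modality = "character", prunedWeights = "numeric",
                 prunedMeans = "numeric", prunedVariances = "numeric"),
  prototype(modality = "unclassified", prunedWeights = numeric(),
            prunedMeans = numeric(), prunedVariances = numeric()))

setValidity("GMMFit", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@weights) != object@k ||
      length(object@means) != object@k ||
      length(object@variances) != object@k)
    msg <- c(msg, "weights/means/variances must each have length k")
  if (length(object@weights) && (any(object@weights < 0) ||
      abs(sum(object@weights) - 1) > 1e-9))
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(object@variances) && any(object@variances < 0))
    msg <- c(msg, "variances must be non-negative")
  if (!object@modality %in% c("unclassified", "unimodal", "multimodal"))
    msg <- c(msg, "invalid modality")
  if (length(msg)) msg else TRUE
})

#' A dynamic component
#'
#' One node of the component network: either a single rearranging
#' side-chain series (\code{kind = "sidechain"}, always exactly one member)
#' or a cluster of correlated C-alpha distance series forming a domain
#' motion (\code{kind = "domain"}).
#'
#' @slot componentId component identifier.
#' @slot kind \code{"sidechain"} or \code{"domain"}.
#' @slot members character vector of member series ids.
#' @export
setClass("DynamicComponent",
  representation(componentId = "character", kind = "character",
                 members = "character"))

setValidity("DynamicComponent", function(object) {
  if (!object@kind %in% c("sidechain", "domain"))
    return("kind must be 'sidechain' or 'domain'")
  if (object@kind == "sidechain" && length(object@members) != 1L)
    return("a side-chain component has exactly one member series")
  if (length(object@members) < 1L)
    return("a component needs at least one member series")
  if (anyDuplicated(object@members))
    return("member series must be unique")
  TRUE
})

#' Collection of dynamic components
#'
#' An ordered list of \linkS4class{DynamicComponent} objects with
#' list-like access.  Member series are disjoint within each kind.
#'
#' @slot components list of \linkS4class{DynamicComponent}.
#' @slot metadata list (e.g. the hclust linkage behind a domain set).
#' @export
setClass("ComponentSet",
  representation(components = "list", metadata = "list"),
  prototype(components = list(), metadata = list()))

setValidity("ComponentSet", function(object) {
  if (!all(vapply(object@components, is, logical(1), "DynamicComponent")))
    return("all elements must be DynamicComponent objects")
  ids <- vapply(object@components, function(x) x@componentId, character(1))
  if (anyDuplicated(ids)) return("component ids must be unique")
  for (kd in c("sidechain", "domain")) {
    mem <- unlist(lapply(object@components,
                         function(x) if (x@kind == kd) x@members))
    if (anyDuplicated(mem))
      return(sprintf("member series overlap within kind '%s'", kd))
  }
  TRUE
})

#' Network of dynamic components
#'
#' Weighted undirected graph over dynamic components.  Edge weight is the
#' absolute average dynamic cross-correlation between the two components'
#' member series; edges exist only at or above the coupling cutoff.
#' Community labels (filled by [detectCommunities()]) partition the nodes.
#'
#' @slot graph an \pkg{igraph} graph; vertex attributes \code{kind} and
#'   \code{size}, edge attribute \code{weight}.
#' @slot coupling full component-by-component coupling matrix (diagonal 1).
#' @slot nodes data.frame: \code{component_id}, \code{kind}, \code{size},
#'   \code{community} (NA until detected).
#' @slot couplingCutoff the cutoff used to draw edges.
#' @export
setClass("ComponentGraph",
  representation(graph = "ANY", coupling = "matrix", nodes = "data.frame",
                 couplingCutoff = "numeric"))

setValidity("ComponentGraph", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
  if (nrow(object@coupling) != ncol(object@coupling))
    return("coupling matrix must be square")
  if (nrow(object@nodes) != igraph::vcount(object@graph))
    return("node table and graph disagree on node count")
  w <- igraph::E(object@graph)$weight
  if (length(w) && (any(w < 0) || any(w > 1 + 1e-12)))
    return("edge weights must lie in [0, 1]")
  TRUE
})

#' Specification of a synthetic benchmark data set
#'
#' Parameters of the planted structures the synthetic generator emits:
#' two-state (or multi-state) side-chain distance switches, blocks of
#' co-drifting C-alpha distance series sharing a smooth latent trajectory,
#' follower couplings that tie a switch's transition to a block's drift,
#' and stationary background noise series.
#'
#' @slot nFrames,nResidues problem size.
#' @slot switches list; each element a list with \code{pair} (two residue
#'   indices), \code{means} (state means, Angstrom), \code{sds} (state
#'   standard deviations, Angstrom), \code{transitions} (strictly
#'   increasing 1-based frame indices; ignored for followers).
#' @slot domainBlocks list; each element a list with \code{members}
#'   (residue indices, for trajectory realization) and/or \code{nSeries}
#'   (series count, for direct series generation), \code{amplitude}
#'   (latent drift amplitude, Angstrom), \code{noiseSd} (per-series noise
#'   SD, Angstrom).
#' @slot followers list of integer pairs \code{c(switch, block)} coupling
#'   switch transitions to block drift.
#' @slot backgroundSeries number of pure-noise series.
#' @slot noiseSd background / coordinate noise SD in Angstrom.
#' @slot seed integer seed; recorded in every emitted artifact.
#' @export
setClass("SyntheticSpec",
  representation(nFrames = "integer", nResidues = "integer",
                 switches = "list", domainBlocks = "list",
                 followers = "list", backgroundSeries = "integer",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  for (sw in object@switches) {
    if (length(sw$means) < 2L || length(sw$sds) != length(sw$means))
      msg <- c(msg, "each switch needs >= 2 state means with matching sds")
    if (any(sw$sds <= 0)) msg <- c(msg, "switch sds must be positive")
    tr <- sw$transitions
    if (length(tr) && (is.unsorted(tr, strictly = TRUE) || any(tr < 1) ||
        any(tr > object@nFrames)))
      msg <- c(msg, "transition frames must be strictly increasing within [1, nFrames]")
  }
  for (bl in object@domainBlocks) {
    if (is.null(bl$members) && is.null(bl$nSeries))
      msg <- c(msg, "each block needs 'members' or 'nSeries'")
    if (!is.null(bl$noiseSd) && bl$noiseSd <= 0)
      msg <- c(msg, "block noiseSd must be positive")
  }
  for (fl in object@followers) {
    if (length(fl) != 2L || fl[1] > length(object@switches) ||
        fl[2] > length(object@domainBlocks) || any(fl < 1))
      msg <- c(msg, "followers must index an existing (switch, block) pair")
  }
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(msg)) msg else TRUE
})
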