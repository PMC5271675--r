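#' @rdname Trajectory-class
#' @param x,object a \linkS4class{Trajectory}
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname Trajectory-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Trajectory-class
#' @param frame 1-based frame index
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' @rdname DistanceSeriesSet-class
#' @param x a \linkS4class{DistanceSeriesSet}
#' @export
setGeneric("seriesIds", function(x) standardGeneric("seriesIds"))

#' @rdname DistanceSeriesSet-class
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname GMMFit-class
#' @param object a \linkS4class{GMMFit}
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname ComponentSet-class
#' @param x a \linkS4class{ComponentSet}
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))

#' @rdname ComponentSet-class
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname ComponentGraph-class
#' @param x a \linkS4class{ComponentGraph}
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname ComponentGraph-class
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))

#' @rdname ComponentGraph-class
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname ComponentGraph-class
#' @export
setGeneric("componentGraph", function(x) standardGeneric("componentGraph"))
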