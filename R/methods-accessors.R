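# Accessors and show methods for the core classes.

#' @rdname Trajectory-class
#' @aliases nFrames,Trajectory-method
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname Trajectory-class
#' @export
setMethod("residues", "Trajectory", function(x) x@residues)

#' @rdname Trajectory-class
#' @export
setMethod("atomTable", "Trajectory", function(x) x@atoms)

#' @rdname Trajectory-class
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x))
    stop("frame index out of range [1, ", nFrames(x), "]")
  x@coords[, , frame, drop = FALSE][, , 1]
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@coords)[1], "atoms,",
      nrow(object@residues), "residues,", nFrames(object), "frames",
      sprintf("(stride %d)\n", object@stride))
  if (!is.null(object@metadata$skippedResidues) &&
      object@metadata$skippedResidues > 0)
    cat("  skipped non-standard residues:",
        object@metadata$skippedResidues, "\n")
})

#' @rdname DistanceSeriesSet-class
#' @export
setMethod("seriesIds", "DistanceSeriesSet", function(x)
  as.character(SummarizedExperiment::rowData(x)$series_id))

#' @rdname DistanceSeriesSet-class
#' @export
setMethod("seriesValues", "DistanceSeriesSet", function(x) {
  m <- SummarizedExperiment::assay(x, "distance")
  rownames(m) <- seriesIds(x)
  m
})

#' @rdname GMMFit-class
#' @export
setMethod("modality", "GMMFit", function(object) object@modality)

setMethod("show", "GMMFit", function(object) {
  cat(sprintf("GMMFit '%s': k = %d, BIC = %.2f, %s%s\n",
              object@seriesId, object@k, object@bic, object@modality,
              if (object@converged) "" else " [not converged]"))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n  means (A):", paste(sprintf("%.2f", object@means), collapse = " "),
      "\n")
})

#' @rdname ComponentSet-class
#' @export
setMethod("length", "ComponentSet", function(x) length(x@components))

#' @rdname ComponentSet-class
#' @param i index or component id
#' @export
setMethod("[[", "ComponentSet", function(x, i) {
  if (is.character(i)) i <- match(i, componentIds(x))
  x@components[[i]]
})

#' @rdname ComponentSet-class
#' @export
setMethod("componentIds", "ComponentSet", function(x)
  vapply(x@components, function(p) p@componentId, character(1)))

#' @rdname ComponentSet-class
#' @export
setMethod("componentTable", "ComponentSet", function(x) {
  if (length(x) == 0L)
    return(data.frame(component_id = character(), kind = character(),
                      size = integer(), stringsAsFactors = FALSE))
  data.frame(
    component_id = componentIds(x),
    kind = vapply(x@components, function(p) p@kind, character(1)),
    size = vapply(x@components, function(p) length(p@members), integer(1)),
    stringsAsFactors = FALSE)
})

setMethod("show", "ComponentSet", function(object) {
  tab <- componentTable(object)
  cat("ComponentSet:", nrow(tab), "components")
  if (nrow(tab))
    cat(" (", sum(tab$kind == "sidechain"), "sidechain,",
        sum(tab$kind == "domain"), "domain; ",
        sum(tab$size), "member series )")
  cat("\n")
})

setMethod("show", "DynamicComponent", function(object) {
  cat(sprintf("DynamicComponent '%s' (%s, %d series)\n",
              object@componentId, object@kind, length(object@members)))
})

#' @rdname ComponentGraph-class
#' @export
setMethod("nodeTable", "ComponentGraph", function(x) x@nodes)

#' @rdname ComponentGraph-class
#' @export
setMethod("couplings", "ComponentGraph", function(x) x@coupling)

#' @rdname ComponentGraph-class
#' @export
setMethod("communityLabels", "ComponentGraph", function(x) {
  stats::setNames(x@nodes$community, x@nodes$component_id)
})

#' @rdname ComponentGraph-class
#' @export
setMethod("componentGraph", "ComponentGraph", function(x) x@graph)

setMethod("show", "ComponentGraph", function(object) {
  cat("ComponentGraph:", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges (coupling cutoff",
      object@couplingCutoff, ")\n")
  if (!all(is.na(object@nodes$community)))
    cat("  communities:", length(unique(object@nodes$community)), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nResidues, "residues x", object@nFrames,
      "frames;", length(object@switches), "switches,",
      length(object@domainBlocks), "blocks,",
      length(object@followers), "followers; seed", object@seed, "\n")
})
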