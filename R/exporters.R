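# Exporters: community PDB with pseudobond CONECT records, graph/CSV
# dumps, and the run manifest.

# representative atom (index into the trajectory atom table) of one
# residue for a series mode: CA for calpha series; for side-chain series
# the side-chain heavy atom closest to the side-chain geometric center at
# the chosen frame (first in atom order on a tie)
.representativeAtom <- function(traj, chain, resno, mode, frame) {
  if (mode == "calpha") {
    sel <- atomSelection(traj, chain, resno, "calpha")
    .checkSelection(sel)
    return(sel@atomIdx[1])
  }
  sel <- atomSelection(traj, chain, resno, "sidechain_nonH")
  .checkSelection(sel)
  xyz <- traj@coords[sel@atomIdx, , frame, drop = FALSE][, , 1,
                                                         drop = FALSE]
  dim(xyz) <- dim(xyz)[1:2]
  ctr <- colMeans(xyz)
  d2 <- rowSums(sweep(xyz, 2L, ctr)^2)
  sel@atomIdx[which.min(d2)]
}

.formatAtomLine <- function(serial, name, resname, chain, resno, xyz,
                            bfac, element) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, chain, resno, xyz[1], xyz[2], xyz[3],
          1.00, bfac, element)
}

#' Write one community as a PDB file with pseudobonds
#'
#' Emits ATOM records for every heavy atom of every residue participating
#' in the community's series at the chosen frame, and one CONECT record
#' per member series connecting the two residues' representative atoms
#' (CA for C-alpha series; for side-chain series the side-chain heavy atom
#' closest to the side-chain geometric center).  The B-factor column
#' carries the community id so molecular viewers can color by community.
#'
#' @param traj the \linkS4class{Trajectory} the series came from.
#' @param seriesSet the \linkS4class{DistanceSeriesSet} providing the pair
#'   annotation of the member series.
#' @param community a \linkS4class{ComponentSet} (or list of
#'   \linkS4class{DynamicComponent}) holding the community's components.
#' @param path output PDB path.
#' @param frame 1-based frame to export (default: the final frame).
#' @param communityId integer written into the B-factor column.
#' @return invisibly, a data.frame of the emitted pseudobonds
#'   (\code{series_id}, \code{serial_a}, \code{serial_b}).
#' @export
writeCommunityPDB <- function(traj, seriesSet, community, path,
                              frame = nFrames(traj), communityId = 1L) {
  comps <- if (is(community, "ComponentSet")) community@components
           else community
  if (length(comps) == 0L) stop("community is empty")
  members <- unlist(lapply(comps, function(p) p@members))
  if (length(members) == 0L) stop("community is empty")
  rd <- as.data.frame(SummarizedExperiment::rowData(seriesSet))
  hit <- match(members, rd$series_id)
  if (anyNA(hit))
    stop("series not found in series set: ",
         paste(utils::head(members[is.na(hit)], 5L), collapse = ", "))
  rd <- rd[hit, , drop = FALSE]
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(traj)) stop("frame index out of range")

  resKeys <- unique(c(.residueKey(rd$chain_a, rd$resno_a),
                      .residueKey(rd$chain_b, rd$resno_b)))
  at <- traj@atoms
  trajKeys <- .residueKey(at$chain, at$resno)
  if (!all(resKeys %in% trajKeys))
    stop("residue absent from trajectory: ",
         paste(setdiff(resKeys, trajKeys), collapse = ", "))

  keep <- which(trajKeys %in% resKeys &
                !.isHydrogen(at$name, at$element))
  serial <- seq_along(keep)               # renumbered serials
  serialOf <- integer(nrow(at)); serialOf[keep] <- serial

  lines <- character(length(keep))
  for (s in seq_along(keep)) {
    i <- keep[s]
    el <- at$element[i]
    if (is.na(el) || !nzchar(el)) el <- substr(at$name[i], 1L, 1L)
    lines[s] <- .formatAtomLine(serial[s], at$name[i], at$resname[i],
                                at$chain[i], at$resno[i],
                                traj@coords[i, , frame],
                                bfac = as.numeric(communityId),
                                element = el)
  }

  bonds <- data.frame(series_id = rd$series_id,
                      serial_a = NA_integer_, serial_b = NA_integer_,
                      stringsAsFactors = FALSE)
  conect <- character(nrow(rd))
  for (r in seq_len(nrow(rd))) {
    mode <- if (rd$mode[r] == "calpha") "calpha" else "sidechain"
    ia <- .representativeAtom(traj, rd$chain_a[r], rd$resno_a[r], mode,
                              frame)
    ib <- .representativeAtom(traj, rd$chain_b[r], rd$resno_b[r], mode,
                              frame)
    bonds$serial_a[r] <- serialOf[ia]
    bonds$serial_b[r] <- serialOf[ib]
    conect[r] <- sprintf("CONECT%5d%5d", serialOf[ia], serialOf[ib])
  }
  writeLines(c(lines, conect, "END"), path)
  invisible(bonds)
}

#' Export the component network
#'
#' Writes the network as GraphML plus an edge-list CSV (source, target,
#' weight, community of each endpoint) and a node-table CSV
#' (component_id, kind, size, community).
#'
#' @param x a \linkS4class{ComponentGraph}.
#' @param graphmlPath,edgeCsvPath,nodeCsvPath output paths; any may be
#'   NULL to skip that file.
#' @return invisibly, the edge table.
#' @export
exportGraph <- function(x, graphmlPath = NULL, edgeCsvPath = NULL,
                        nodeCsvPath = NULL) {
  g <- x@graph
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edges)) {
    names(edges)[1:2] <- c("source", "target")
    lab <- communityLabels(x)
    edges$community_source <- unname(lab[edges$source])
    edges$community_target <- unname(lab[edges$target])
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), community_source = integer(),
                        community_target = integer())
  }
  if (!is.null(edgeCsvPath)) write.csv(edges, edgeCsvPath,
                                       row.names = FALSE)
  if (!is.null(nodeCsvPath)) write.csv(nodeTable(x), nodeCsvPath,
                                       row.names = FALSE)
  invisible(edges)
}

#' Write / read the run manifest
#'
#' A single YAML file capturing everything needed to reproduce a run:
#' every cutoff, seed and stride, input checksums, package and R versions,
#' and per-stage series / component / community counts.
#'
#' @param manifest named list of stage configurations and counts.
#' @param path output / input path.
#' @return \code{writeRunManifest} returns \code{path} invisibly;
#'   \code{readRunManifest} returns the manifest list.
#' @export
writeRunManifest <- function(manifest, path) {
  stopifnot(is.list(manifest))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname writeRunManifest
#' @export
readRunManifest <- function(path) yaml::read_yaml(path)
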