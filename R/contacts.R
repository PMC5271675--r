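# Candidate-pair enumeration under the contact criteria and distance
# time-series computation.

.CONTACT_MODES <- c("sidechain_vdw", "polar", "calpha")

# map a contact mode to the atom-selection mode of each residue
.selectionModeFor <- function(mode) {
  switch(mode,
    sidechain_vdw = "sidechain_nonH",
    polar = "polar_head",
    calpha = "calpha",
    stop("unknown contact mode '", mode, "'"))
}

# all residue selections for a mode; NULL entries where the selection is
# empty (e.g. glycine side chains, non-polar residues) -- those residues
# are silently skipped by the contact screen
.allSelections <- function(traj, mode) {
  selMode <- .selectionModeFor(mode)
  res <- residues(traj)
  lapply(seq_len(nrow(res)), function(i) {
    sel <- atomSelection(traj, res$chain[i], res$resno[i], selMode)
    if (length(sel@atomIdx) == 0L) NULL else sel
  })
}

#' Enumerate candidate residue pairs
#'
#' Returns every residue pair, at least \code{minSeqSep} residues apart in
#' sequence when on the same chain (inter-chain pairs are always
#' eligible), whose mode-specific minimum distance is at or below
#' \code{cutoff} in at least one frame of the trajectory.  For
#' \code{"polar"} both residues must carry a polar head group; pairs
#' involving a residue with an empty selection (e.g. glycine side chains)
#' are skipped.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param mode \code{"sidechain_vdw"}, \code{"polar"} or \code{"calpha"}.
#' @param cutoff contact cutoff in Angstrom (5 for side-chain and polar
#'   contacts, 15 for C-alpha pairs in the reference protocol).
#' @param minSeqSep minimum intra-chain sequence separation (default 3).
#' @param screenStride evaluate the screen on every
#'   \code{screenStride}-th frame (default 1 = every frame; a coarser
#'   stride trades exactness for speed and is recorded in the result).
#' @return data.frame with one row per eligible pair: chain/resno/resname
#'   for both residues (pair stored canonically, a before b), \code{mode}
#'   and \code{min_dist}, the minimum distance observed during screening.
#' @examples
#' pdb <- system.file("extdata", "toy_switch.pdb", package = "dyncomp")
#' traj <- readTrajectory(pdb)
#' enumeratePairs(traj, "calpha", cutoff = 15)
#' @export
enumeratePairs <- function(traj, mode = .CONTACT_MODES, cutoff,
                           minSeqSep = 3L, screenStride = 1L) {
  mode <- match.arg(mode)
  .assertScalarNumber(cutoff, "cutoff", positive = TRUE)
  minSeqSep <- as.integer(minSeqSep)
  screenStride <- as.integer(screenStride)
  if (screenStride < 1L) stop("screenStride must be >= 1")
  if (screenStride > 1L)
    message("enumeratePairs: screening every ", screenStride, "-th frame")

  res <- residues(traj)
  sels <- .allSelections(traj, mode)
  frames <- seq(1L, nFrames(traj), by = screenStride)

  out <- vector("list", 64L); nOut <- 0L
  n <- nrow(res)
  for (i in seq_len(n - 1L)) {
    if (is.null(sels[[i]])) next
    for (j in seq(i + 1L, n)) {
      if (is.null(sels[[j]])) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) < minSeqSep) next
      d <- .pairSeries(traj, sels[[i]], sels[[j]])[frames]
      dmin <- min(d)
      if (dmin <= cutoff) {
        nOut <- nOut + 1L
        out[[nOut]] <- data.frame(
          chain_a = res$chain[i], resno_a = res$resno[i],
          resname_a = res$resname[i],
          chain_b = res$chain[j], resno_b = res$resno[j],
          resname_b = res$resname[j],
          mode = mode, min_dist = dmin, stringsAsFactors = FALSE)
      }
    }
  }
  if (nOut == 0L)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resno_b = integer(), resname_b = character(),
                      mode = character(), min_dist = numeric(),
                      stringsAsFactors = FALSE))
  pairs <- do.call(rbind, out[seq_len(nOut)])
  rownames(pairs) <- NULL
  pairs
}

#' Compute distance time series for residue pairs
#'
#' One distance value per frame and pair: the minimum distance over the
#' pair's mode-specific atom selections (for \code{calpha} pairs this is
#' the CA-CA distance).  Distances are stored at full floating precision.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pairs data.frame as returned by [enumeratePairs()].
#' @return a \linkS4class{DistanceSeriesSet} with one row per pair.
#' @export
computeSeries <- function(traj, pairs) {
  if (nrow(pairs) == 0L)
    return(.emptySeriesSet(nFrames(traj)))
  vals <- matrix(NA_real_, nrow = nrow(pairs), ncol = nFrames(traj))
  ids <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    selMode <- .selectionModeFor(pairs$mode[r])
    selA <- atomSelection(traj, pairs$chain_a[r], pairs$resno_a[r], selMode)
    selB <- atomSelection(traj, pairs$chain_b[r], pairs$resno_b[r], selMode)
    if (length(selA@atomIdx) == 0L || length(selB@atomIdx) == 0L)
      stop(sprintf("empty %s selection for pair %s:%d - %s:%d", selMode,
                   pairs$chain_a[r], pairs$resno_a[r],
                   pairs$chain_b[r], pairs$resno_b[r]))
    vals[r, ] <- .pairSeries(traj, selA, selB)
    ids[r] <- .seriesId(pairs$chain_a[r], pairs$resname_a[r],
                        pairs$resno_a[r], pairs$chain_b[r],
                        pairs$resname_b[r], pairs$resno_b[r],
                        pairs$mode[r])
  }
  .makeSeriesSet(vals, ids, pairs)
}

.makeSeriesSet <- function(vals, ids, pairs) {
  rd <- S4Vectors::DataFrame(
    series_id = ids,
    mode = pairs$mode,
    chain_a = pairs$chain_a, resno_a = as.integer(pairs$resno_a),
    resname_a = pairs$resname_a,
    chain_b = pairs$chain_b, resno_b = as.integer(pairs$resno_b),
    resname_b = pairs$resname_b)
  rownames(vals) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(distance = vals), rowData = rd)
  new("DistanceSeriesSet", se)
}

.emptySeriesSet <- function(nf) {
  vals <- matrix(numeric(), nrow = 0L, ncol = nf)
  pairs <- data.frame(mode = character(), chain_a = character(),
                      resno_a = integer(), resname_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resname_b = character(), stringsAsFactors = FALSE)
  .makeSeriesSet(vals, character(0), pairs)
}

#' Combine distance series sets
#'
#' Row-binds series sets computed on the same trajectory (the frame counts
#' must agree), e.g. side-chain and C-alpha series ahead of the
#' cross-component correlation stage.
#'
#' @param ... \linkS4class{DistanceSeriesSet} objects.
#' @return a \linkS4class{DistanceSeriesSet}.
#' @export
combineSeries <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) nrow(s) > 0L, logical(1))]
  if (length(sets) == 0L) stop("no non-empty series sets to combine")
  nf <- unique(vapply(sets, ncol, integer(1)))
  if (length(nf) != 1L) stop("series sets have differing frame counts")
  vals <- do.call(rbind, lapply(sets, function(s)
    SummarizedExperiment::assay(s, "distance")))
  rdl <- lapply(sets, function(s)
    as.data.frame(SummarizedExperiment::rowData(s)))
  pairs <- do.call(rbind, rdl)
  .makeSeriesSet(vals, pairs$series_id, pairs)
}

#' Export / import distance series as CSV
#'
#' The CSV layout is one row per series: \code{series_id}, the pair
#' annotation columns, then one column per frame (\code{f1}, \code{f2},
#' ...).  Distances are rounded to 3 decimals on export; in-memory values
#' keep full precision.
#'
#' @param x a \linkS4class{DistanceSeriesSet}.
#' @param path output / input CSV path.
#' @return \code{writeSeriesCSV} returns \code{path} invisibly;
#'   \code{readSeriesCSV} returns a \linkS4class{DistanceSeriesSet}.
#' @export
writeSeriesCSV <- function(x, path) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  vals <- round(SummarizedExperiment::assay(x, "distance"), 3)
  colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  write.csv(cbind(rd, as.data.frame(vals)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSeriesCSV
#' @export
readSeriesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  frameCols <- grep("^f[0-9]+$", names(df))
  vals <- as.matrix(df[, frameCols, drop = FALSE])
  dimnames(vals) <- NULL
  .makeSeriesSet(vals, df$series_id, df[, setdiff(names(df),
                                                  names(df)[frameCols])])
}
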