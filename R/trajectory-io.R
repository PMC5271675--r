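# Trajectory loading and the minimum-distance primitive.

#' Load a topology and trajectory
#'
#' Reads a PDB topology plus an optional trajectory (multi-model PDB or
#' DCD) into a \linkS4class{Trajectory}.  When no trajectory file is given
#' the topology itself must be a multi-model PDB whose models are the
#' frames.  Coordinates are in Angstrom.  Alternate locations are resolved
#' to the highest-occupancy conformer; residues outside the 20 standard
#' amino acids (waters, lipids, ions, hetero groups) are dropped with a
#' logged count.
#'
#' @param topology path to a PDB file.
#' @param trajectory optional path to a trajectory: a DCD file or a
#'   multi-model PDB.  Its frames must match the topology atom count.
#' @param stride keep every \code{stride}-th frame, starting at the first
#'   (so \code{ceiling(rawFrames / stride)} frames are kept).
#' @return a \linkS4class{Trajectory}.
#' @examples
#' pdb <- system.file("extdata", "toy_switch.pdb", package = "dyncomp")
#' traj <- readTrajectory(pdb)
#' nFrames(traj)
#' @export
readTrajectory <- function(topology, trajectory = NULL, stride = 1L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  if (!file.exists(topology)) stop("topology file not found: ", topology)

  top <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  atom <- top$atom

  if (is.null(trajectory)) {
    xyz <- top$xyz                       # frames x (3 * nAtoms)
  } else {
    if (!file.exists(trajectory))
      stop("trajectory file not found: ", trajectory)
    ext <- tolower(tools::file_ext(trajectory))
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
    } else if (ext %in% c("pdb", "ent")) {
      xyz <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)$xyz
    } else {
      stop("unsupported trajectory format '.", ext,
           "': use multi-model PDB or DCD")
    }
  }
  xyz <- unclass(xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) == 0L) stop("trajectory contains zero frames")
  if (ncol(xyz) != 3L * nrow(atom))
    stop(sprintf(
      "atom-count mismatch: topology has %d atoms but frames have %d",
      nrow(atom), ncol(xyz) %/% 3L))

  rawFrames <- nrow(xyz)
  keepFrames <- seq(1L, rawFrames, by = stride)
  if (length(keepFrames) < 2L)
    stop("fewer than 2 frames after striding (", length(keepFrames), ")")

  # highest-occupancy altloc conformer; first wins on ties
  alt <- atom$alt
  occ <- atom$o
  occ[is.na(occ)] <- 1
  keepAtom <- rep(TRUE, nrow(atom))
  hasAlt <- !is.na(alt) & nzchar(alt) & alt != " "
  if (any(hasAlt)) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
    for (k in unique(key[hasAlt])) {
      idx <- which(key == k)
      if (length(idx) > 1L)
        keepAtom[idx[-which.max(occ[idx])]] <- FALSE
    }
  }

  std <- atom$resid %in% .STANDARD_AA
  nSkipRes <- length(unique(paste(atom$chain, atom$resno,
                                  atom$resid)[!std]))
  if (nSkipRes > 0)
    message("readTrajectory: skipping ", nSkipRes,
            " non-standard residue(s)")
  keepAtom <- keepAtom & std

  atomIdx <- which(keepAtom)
  atom <- atom[atomIdx, , drop = FALSE]
  chain <- atom$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "

  nAtoms <- nrow(atom)
  coords <- array(NA_real_, dim = c(nAtoms, 3L, length(keepFrames)))
  xyzCols <- as.vector(rbind(3L * atomIdx - 2L, 3L * atomIdx - 1L,
                             3L * atomIdx))
  for (f in seq_along(keepFrames)) {
    v <- xyz[keepFrames[f], xyzCols]
    coords[, , f] <- matrix(v, ncol = 3L, byrow = TRUE)
  }

  # residue table in file order (insertion codes fold into the ordering)
  rkey <- .residueKey(chain, atom$resno)
  firstSeen <- !duplicated(rkey)
  resTab <- data.frame(chain = chain[firstSeen],
                       resno = atom$resno[firstSeen],
                       resname = atom$resid[firstSeen],
                       stringsAsFactors = FALSE)
  ord <- order(resTab$chain, resTab$resno)
  resTab <- resTab[ord, , drop = FALSE]
  rownames(resTab) <- NULL

  atomTab <- data.frame(
    name = trimws(atom$elety),
    element = trimws(if ("elesy" %in% names(atom)) atom$elesy else
                     rep(NA_character_, nAtoms)),
    chain = chain,
    resno = atom$resno,
    resname = atom$resid,
    residueIndex = match(rkey, .residueKey(resTab$chain, resTab$resno)),
    stringsAsFactors = FALSE)

  new("Trajectory", coords = coords, atoms = atomTab, residues = resTab,
      stride = stride,
      metadata = list(topology = topology,
                      trajectory = if (is.null(trajectory)) NA_character_
                                   else trajectory,
                      rawFrames = rawFrames, skippedResidues = nSkipRes))
}

#' Polar head group atoms of a residue
#'
#' The non-hydrogen polar head group atoms used for polar-interaction
#' distance series, per residue type: for example ARG maps to
#' NE, CZ, NH1, NH2 and TRP to NE1.  Non-polar residues map to an empty
#' set.
#'
#' @param resName a standard 3-letter residue code.
#' @return character vector of atom names (possibly empty).
#' @examples
#' polarHeadAtoms("ARG")
#' polarHeadAtoms("ALA")  # character(0): non-polar
#' @export
polarHeadAtoms <- function(resName) {
  resName <- toupper(resName)
  if (length(resName) != 1L || !resName %in% .STANDARD_AA)
    stop("'", resName, "' is not a standard 3-letter residue code")
  atoms <- .POLAR_HEAD_TABLE[[resName]]
  if (is.null(atoms)) character(0) else atoms
}

#' Select atoms of one residue
#'
#' Builds the \linkS4class{AtomSelection} for one residue under one of the
#' three contact modes.  \code{sidechain_nonH} keeps every heavy atom that
#' is not backbone (N, CA, C, O and terminal oxygens); unknown heavy
#' side-chain atom names of standard residues are included.  Hydrogens are
#' identified by element when present, otherwise by name.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param chain,resno residue identity.
#' @param mode \code{"sidechain_nonH"}, \code{"polar_head"} or
#'   \code{"calpha"}.
#' @return an \linkS4class{AtomSelection}; possibly empty (e.g. glycine
#'   side chain).
#' @export
atomSelection <- function(traj, chain, resno,
                          mode = c("sidechain_nonH", "polar_head",
                                   "calpha")) {
  mode <- match.arg(mode)
  resno <- as.integer(resno)
  at <- traj@atoms
  inRes <- at$chain == chain & at$resno == resno
  if (!any(inRes))
    stop(sprintf("residue %s:%d not found in trajectory", chain, resno))
  resname <- at$resname[inRes][1]

  idx <- switch(mode,
    calpha = which(inRes & at$name == "CA"),
    sidechain_nonH = which(inRes &
      !(at$name %in% .BACKBONE_ATOMS) &
      !.isHydrogen(at$name, at$element)),
    polar_head = which(inRes & at$name %in% polarHeadAtoms(resname)))

  new("AtomSelection", chain = chain, resno = resno, resname = resname,
      mode = mode, atomNames = at$name[idx], atomIdx = as.integer(idx))
}

#' Minimum inter-selection distance in one frame
#'
#' The minimum Euclidean distance over all cross pairs of atoms between
#' two selections, in Angstrom.  Symmetric in its selection arguments.
#' A pair within the same residue is rejected: self-pairs are excluded
#' upstream by the sequence-separation rule.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 1-based frame index.
#' @param selA,selB \linkS4class{AtomSelection} objects on \code{traj}.
#' @return minimum distance in Angstrom.
#' @export
minDistance <- function(traj, frame, selA, selB) {
  .checkSelection(selA)
  .checkSelection(selB)
  if (selA@chain == selB@chain && selA@resno == selB@resno)
    stop(sprintf("self-pair %s:%d is not a valid contact",
                 selA@chain, selA@resno))
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(traj)) stop("frame index out of range")
  a <- traj@coords[selA@atomIdx, , frame, drop = FALSE][, , 1, drop = FALSE]
  b <- traj@coords[selB@atomIdx, , frame, drop = FALSE][, , 1, drop = FALSE]
  dim(a) <- dim(a)[1:2]; dim(b) <- dim(b)[1:2]
  sqrt(min(.crossDist2(a, b)))
}

.checkSelection <- function(sel) {
  if (length(sel@atomIdx) == 0L)
    stop(sprintf("empty %s selection for residue %s:%d (%s)",
                 sel@mode, sel@chain, sel@resno, sel@resname))
}

# squared distances between two nAtom x 3 coordinate matrices
.crossDist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0                       # numerical guard
  d2
}

# full per-frame minimum-distance series for one selection pair
.pairSeries <- function(traj, selA, selB) {
  nf <- nFrames(traj)
  ca <- traj@coords[selA@atomIdx, , , drop = FALSE]
  cb <- traj@coords[selB@atomIdx, , , drop = FALSE]
  best <- rep(Inf, nf)
  for (i in seq_len(dim(ca)[1])) {
    ai <- ca[i, , ]                      # 3 x nf
    for (j in seq_len(dim(cb)[1])) {
      d2 <- colSums((ai - cb[j, , ])^2)
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}
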