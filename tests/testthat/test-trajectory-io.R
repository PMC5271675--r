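# Trajectory loading, atom selection tables and the minimum-distance
# primitive.

twoResFrame <- function(shift = 0) {
  rbind(atomRow("CA", "ALA", "A", 1, 0, 0, 0),
        atomRow("CB", "ALA", "A", 1, 0, 1.5, 0),
        atomRow("CA", "ALA", "A", 2, 3.8 + shift, 0, 0),
        atomRow("CB", "ALA", "A", 2, 3.8 + shift, 1.5, 0))
}

test_that("multi-model PDB models become frames and stride subsamples them", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(lapply(c(0, 1, 2), twoResFrame), path)
  traj <- readTrajectory(path)
  expect_equal(nFrames(traj), 3L)
  expect_equal(nrow(residues(traj)), 2L)

  strided <- readTrajectory(path, stride = 2L)
  expect_equal(nFrames(strided), 2L)  # ceiling(3 / 2): models 1 and 3
  expect_equal(strided@coords[, , 1], traj@coords[, , 1])
  expect_equal(strided@coords[, , 2], traj@coords[, , 3])
})

test_that("atom-count mismatch between topology and trajectory is named", {
  top <- withr::local_tempfile(fileext = ".pdb")
  trj <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(list(twoResFrame(), twoResFrame()), top)
  bigger <- rbind(twoResFrame(), atomRow("CA", "GLY", "A", 3, 8, 0, 0))
  writeTestPDB(list(bigger, bigger), trj)
  expect_error(readTrajectory(top, trj), "4.*5|mismatch")
})

test_that("non-standard residues are skipped with a logged count", {
  path <- withr::local_tempfile(fileext = ".pdb")
  frame <- rbind(twoResFrame(),
                 atomRow("O", "HOH", "A", 99, 20, 20, 20))
  writeTestPDB(list(frame, frame), path)
  expect_message(traj <- readTrajectory(path), "skipping 1 non-standard")
  expect_equal(nrow(residues(traj)), 2L)
  expect_true(all(residues(traj)$resname %in% c("ALA")))
})

test_that("polar head group table matches the per-residue atom lists", {
  expect_setequal(polarHeadAtoms("ARG"), c("NE", "CZ", "NH1", "NH2"))
  expect_setequal(polarHeadAtoms("ASN"), c("CG", "OD1", "ND2"))
  expect_setequal(polarHeadAtoms("ASP"), c("CG", "OD1", "OD2"))
  expect_setequal(polarHeadAtoms("CYS"), "SG")
  expect_setequal(polarHeadAtoms("GLN"), c("CD", "OE1", "NE2"))
  expect_setequal(polarHeadAtoms("GLU"), c("CD", "OE1", "OE2"))
  expect_setequal(polarHeadAtoms("HIS"),
                  c("CG", "ND1", "CE1", "NE2", "CD2"))
  expect_setequal(polarHeadAtoms("LYS"), "NZ")
  expect_setequal(polarHeadAtoms("SER"), "OG")
  expect_setequal(polarHeadAtoms("THR"), "OG1")
  expect_setequal(polarHeadAtoms("TRP"), "NE1")
  expect_setequal(polarHeadAtoms("TYR"), "OH")
  # non-polar residues have empty head groups
  for (res in c("ALA", "GLY", "LEU", "PHE", "MET", "VAL", "ILE", "PRO"))
    expect_length(polarHeadAtoms(res), 0)
  expect_error(polarHeadAtoms("XYZ"), "not a standard")
})

test_that("side-chain selections exclude backbone and hydrogens", {
  path <- withr::local_tempfile(fileext = ".pdb")
  frame <- rbind(
    atomRow("N",  "SER", "A", 1, 0, 0, 0, "N"),
    atomRow("CA", "SER", "A", 1, 1, 0, 0, "C"),
    atomRow("C",  "SER", "A", 1, 2, 0, 0, "C"),
    atomRow("O",  "SER", "A", 1, 3, 0, 0, "O"),
    atomRow("CB", "SER", "A", 1, 1, 1, 0, "C"),
    atomRow("OG", "SER", "A", 1, 1, 2, 0, "O"),
    atomRow("HB2", "SER", "A", 1, 1.5, 1, 0, "H"),
    atomRow("CA", "GLY", "A", 5, 8, 0, 0, "C"))
  writeTestPDB(list(frame, frame), path)
  traj <- readTrajectory(path)

  sc <- atomSelection(traj, "A", 1, "sidechain_nonH")
  expect_setequal(sc@atomNames, c("CB", "OG"))
  expect_setequal(atomSelection(traj, "A", 1, "polar_head")@atomNames, "OG")
  expect_equal(atomSelection(traj, "A", 1, "calpha")@atomNames, "CA")
  # glycine has no side chain: empty selection, flagged at use
  gly <- atomSelection(traj, "A", 5, "sidechain_nonH")
  expect_length(gly@atomIdx, 0)
  expect_error(minDistance(traj, 1, sc, gly), "empty.*5")
})

test_that("minDistance is the cross-pair minimum, symmetric, and rejects self-pairs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  frame <- rbind(
    atomRow("CB", "ALA", "A", 1, 0, 0, 0),
    atomRow("CB", "CYS", "A", 5, 3, 0, 0),
    atomRow("SG", "CYS", "A", 5, 5, 0, 0))
  writeTestPDB(list(frame, frame), path)
  traj <- readTrajectory(path)
  a <- atomSelection(traj, "A", 1, "sidechain_nonH")
  b <- atomSelection(traj, "A", 5, "sidechain_nonH")
  expect_equal(minDistance(traj, 1, a, b), 3.0)
  expect_equal(minDistance(traj, 1, b, a), 3.0)
  expect_error(minDistance(traj, 1, a, a), "self-pair")
})

test_that("minDistance equals the exhaustive double-loop minimum and is rigid-motion invariant", {
  set.seed(11)
  xyzA <- matrix(runif(15, 0, 10), 5, 3)
  xyzB <- matrix(runif(21, 0, 10), 7, 3)
  mkFrame <- function(A, B) {
    rows <- list()
    for (i in seq_len(nrow(A)))
      rows[[length(rows) + 1]] <- atomRow(c("CB", "CG", "CD", "CE", "CZ")[i],
        "LYS", "A", 1, A[i, 1], A[i, 2], A[i, 3], "C")
    for (i in seq_len(nrow(B)))
      rows[[length(rows) + 1]] <- atomRow(
        c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")[i],
        "ARG", "A", 9, B[i, 1], B[i, 2], B[i, 3],
        substr(c("C", "C", "C", "N", "C", "N", "N")[i], 1, 1))
    do.call(rbind, rows)
  }
  # rigid rotation + translation applied to the whole second frame
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  shift <- c(5, -2, 3)
  A2 <- sweep(xyzA %*% R, 2, shift, "+")
  B2 <- sweep(xyzB %*% R, 2, shift, "+")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(list(mkFrame(xyzA, xyzB), mkFrame(A2, B2)), path)
  traj <- readTrajectory(path)
  sa <- atomSelection(traj, "A", 1, "sidechain_nonH")
  sb <- atomSelection(traj, "A", 9, "sidechain_nonH")

  brute <- Inf
  for (i in seq_len(5)) for (j in seq_len(7))
    brute <- min(brute, sqrt(sum((xyzA[i, ] - xyzB[j, ])^2)))
  expect_equal(minDistance(traj, 1, sa, sb), brute, tolerance = 1e-3)
  expect_equal(minDistance(traj, 2, sa, sb), minDistance(traj, 1, sa, sb),
               tolerance = 1e-3)  # PDB precision, rigid-motion invariant
})
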