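# Contact-pair enumeration criteria and distance series computation.

# chain of CA-only residues at given x positions, one frame per row of
# the offsets matrix (offset added to residue 1's x)
caChainPDB <- function(xPos, offsets, path) {
  frames <- lapply(offsets, function(off) {
    do.call(rbind, lapply(seq_along(xPos), function(r)
      atomRow("CA", "ALA", "A", r, xPos[r] + if (r == 1) off else 0,
              0, 0, "C")))
  })
  writeTestPDB(frames, path)
}

test_that("a pair within cutoff in a single frame is included; never-close pairs are not", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # residues 1 and 4: 6 A apart except one frame at 4.8 A
  frames <- lapply(c(6, 6, 4.8, 6), function(d)
    rbind(atomRow("CB", "ALA", "A", 1, 0, 0, 0),
          atomRow("CB", "ALA", "A", 4, d, 0, 0)))
  writeTestPDB(frames, path)
  traj <- readTrajectory(path)
  pairs <- enumeratePairs(traj, "sidechain_vdw", cutoff = 5)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$resno_a, 1L)
  expect_equal(pairs$resno_b, 4L)

  # two residues always 20 A apart are excluded at the 15 A calpha cutoff
  path2 <- withr::local_tempfile(fileext = ".pdb")
  caChainPDB(c(0, 20), c(0, 0), path2)
  # 2 residues => separation 1 < 3: use chain positions 1 and 10 instead
  frames2 <- lapply(1:2, function(f)
    rbind(atomRow("CA", "ALA", "A", 1, 0, 0, 0),
          atomRow("CA", "ALA", "A", 10, 20, 0, 0)))
  writeTestPDB(frames2, path2)
  traj2 <- readTrajectory(path2)
  expect_equal(nrow(enumeratePairs(traj2, "calpha", cutoff = 15)), 0L)
})

test_that("sequence separation applies within a chain; inter-chain pairs are always eligible", {
  path <- withr::local_tempfile(fileext = ".pdb")
  frame <- rbind(atomRow("CA", "ALA", "A", 1, 0, 0, 0),
                 atomRow("CA", "ALA", "A", 2, 3.8, 0, 0),
                 atomRow("CA", "ALA", "B", 1, 0, 4, 0))
  writeTestPDB(list(frame, frame), path)
  traj <- readTrajectory(path)
  pairs <- enumeratePairs(traj, "calpha", cutoff = 15)
  key <- paste0(pairs$chain_a, pairs$resno_a, "-", pairs$chain_b,
                pairs$resno_b)
  expect_false("A1-A2" %in% key)           # separation 1 < 3
  expect_setequal(key, c("A1-B1", "A2-B1"))  # inter-chain: no rule
})

test_that("calpha enumeration equals an exhaustive per-frame brute-force scan", {
  set.seed(21)
  nRes <- 12L
  xPos <- cumsum(c(0, runif(nRes - 1, 3.5, 6.5)))
  path <- withr::local_tempfile(fileext = ".pdb")
  nf <- 6L
  coords <- lapply(seq_len(nf), function(f) xPos + rnorm(nRes, 0, 1.5))
  frames <- lapply(coords, function(xs)
    do.call(rbind, lapply(seq_len(nRes), function(r)
      atomRow("CA", "ALA", "A", r, xs[r], 0, 0, "C"))))
  writeTestPDB(frames, path)
  traj <- readTrajectory(path)
  pairs <- enumeratePairs(traj, "calpha", cutoff = 15)
  got <- sort(paste0(pairs$resno_a, "-", pairs$resno_b))

  expected <- character()
  for (i in seq_len(nRes - 1)) for (j in seq(i + 1, nRes)) {
    if (j - i < 3) next
    dmin <- min(vapply(coords, function(xs) abs(xs[i] - xs[j]),
                       numeric(1)))
    # PDB coordinates are written at 3 decimals; stay off the boundary
    if (dmin <= 15 - 1e-3) expected <- c(expected, paste0(i, "-", j))
  }
  expect_setequal(got, sort(expected))
})

test_that("enumeration is monotone in the cutoff", {
  spec <- e2eSpec(seed = 5L)
  path <- withr::local_tempfile(fileext = ".pdb")
  generateTrajectory(spec, path)
  traj <- readTrajectory(path)
  pairKey <- function(p) {
    if (nrow(p) == 0) return(character(0))
    paste0(p$chain_a, p$resno_a, "-", p$chain_b, p$resno_b)
  }
  for (mode in c("sidechain_vdw", "calpha")) {
    cuts <- c(4, 6, 9, 14, 18)
    sets <- lapply(cuts, function(cc)
      pairKey(enumeratePairs(traj, mode, cutoff = cc)))
    for (i in seq_along(cuts)[-1])
      expect_true(all(sets[[i - 1]] %in% sets[[i]]),
                  info = sprintf("%s cutoff %g vs %g", mode,
                                 cuts[i - 1], cuts[i]))
  }
})

test_that("series have one value per frame, are deterministic, and match planted regimes", {
  spec <- e2eSpec(seed = 9L)
  path <- withr::local_tempfile(fileext = ".pdb")
  gen <- generateTrajectory(spec, path)
  traj <- readTrajectory(path)

  pairs <- enumeratePairs(traj, "sidechain_vdw", cutoff = 5)
  dss <- computeSeries(traj, pairs)
  expect_equal(ncol(dss), nFrames(traj))
  expect_true(all(seriesValues(dss) >= 0))

  # recomputation is bit-identical
  dss2 <- computeSeries(traj, pairs)
  expect_identical(seriesValues(dss), seriesValues(dss2))

  # the planted switch series shows its two state means within noise
  swRow <- which(SummarizedExperiment::rowData(dss)$resno_a == 2 &
                 SummarizedExperiment::rowData(dss)$resno_b == 5)
  expect_length(swRow, 1L)
  d <- seriesValues(dss)[swRow, ]
  lat <- gen$latents[[1]]
  expect_equal(mean(d[lat <= 0]), 2.7, tolerance = 0.1)
  expect_equal(mean(d[lat > 0]), 5.5, tolerance = 0.1)
})

test_that("series CSV round-trips through the documented layout", {
  spec <- e2eSpec(seed = 3L)
  path <- withr::local_tempfile(fileext = ".pdb")
  generateTrajectory(spec, path)
  traj <- readTrajectory(path)
  dss <- computeSeries(traj, enumeratePairs(traj, "calpha", cutoff = 15))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeSeriesCSV(dss, csv)
  back <- readSeriesCSV(csv)
  expect_equal(seriesIds(back), seriesIds(dss))
  # export rounds to 3 decimals by contract
  expect_equal(seriesValues(back), round(seriesValues(dss), 3),
               ignore_attr = TRUE)
})
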