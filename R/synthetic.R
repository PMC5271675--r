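# Seeded synthetic benchmark generator: planted side-chain switches,
# co-drifting domain blocks, follower couplings and background noise,
# emitted either as bare distance series or as a multi-model PDB
# trajectory realizing the same plants geometrically.

#' Construct a synthetic benchmark specification
#'
#' @param nFrames,nResidues problem size (defaults: 500 frames, 12
#'   residues, the scale of the end-to-end benchmark).
#' @param switches,domainBlocks,followers see
#'   \linkS4class{SyntheticSpec}.
#' @param backgroundSeries number of stationary pure-noise series (series
#'   generation only).
#' @param noiseSd background / coordinate noise SD in Angstrom (default
#'   0.08, a thermal-jitter scale small against the planted signals).
#' @param seed integer seed recorded in every emitted artifact.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- syntheticSpec(
#'   switches = list(list(pair = c(2, 5), means = c(2.7, 5.5),
#'                        sds = c(0.3, 0.3), transitions = integer())),
#'   domainBlocks = list(list(members = 7:12, amplitude = 2,
#'                            noiseSd = 0.1)),
#'   followers = list(c(1, 1)), seed = 42)
#' @export
syntheticSpec <- function(nFrames = 500L, nResidues = 12L,
                          switches = list(), domainBlocks = list(),
                          followers = list(), backgroundSeries = 0L,
                          noiseSd = 0.08, seed = 1L) {
  new("SyntheticSpec", nFrames = as.integer(nFrames),
      nResidues = as.integer(nResidues), switches = switches,
      domainBlocks = domainBlocks, followers = followers,
      backgroundSeries = as.integer(backgroundSeries),
      noiseSd = noiseSd, seed = as.integer(seed))
}

# smooth latent drift of block `index`: the compressed-timescale analogue
# of a domain motion spanning a long stretch of the trajectory, plus
# low-pass filtered Gaussian noise.  Block 1 gets an amplitude-scaled
# tanh ramp centered mid-series; later blocks get successive cosine
# harmonics, which are orthogonal to the ramp and to each other, so
# distinct blocks are uncorrelated by construction.
.latentDrift <- function(nf, amplitude, index = 1L) {
  t <- seq_len(nf)
  base <- if (index == 1L)
    tanh((t - (nf + 1) / 2) / (nf / 10))
  else
    cos(2 * pi * (index - 1L) * (t - 1) / (nf - 1))
  drift <- amplitude * base
  if (amplitude > 0) {
    wn <- rnorm(nf, 0, amplitude * 0.05)
    drift <- drift + as.numeric(stats::filter(0.1 * wn, 0.9,
                                              method = "recursive"))
  }
  drift
}

# piecewise state path of a switch: state 1 up to the first transition,
# cycling through the states at each subsequent transition
.switchStates <- function(nf, nStates, transitions) {
  state <- integer(nf)
  cur <- 1L; prev <- 1L
  for (tr in c(transitions, nf + 1L)) {
    if (tr > prev) state[prev:min(tr - 1L, nf)] <- cur
    cur <- cur %% nStates + 1L
    prev <- tr
  }
  state
}

#' Generate a planted distance-series set
#'
#' Emits the series the pipeline stages consume, with ground-truth labels:
#' switch series are piecewise-constant means plus Gaussian noise (a
#' follower switch transitions where its block's latent drift crosses
#' zero, so switch and block are strongly correlated by construction);
#' block series share a smooth latent drift, scaled per member, plus
#' independent noise; background series are stationary noise around a
#' fixed mean.  Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{series} (a \linkS4class{DistanceSeriesSet}),
#'   \code{truth} (data.frame: series_id, role = switch/block/background,
#'   group index) and \code{latents} (list of per-block latent drifts).
#' @export
generateSeriesSet <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed)
  nf <- spec@nFrames
  vals <- list(); ids <- character(); rows <- list(); truth <- list()

  latents <- lapply(seq_along(spec@domainBlocks), function(b) {
    bl <- spec@domainBlocks[[b]]
    .latentDrift(nf, if (is.null(bl$amplitude)) 2 else bl$amplitude, b)
  })

  followerOf <- rep(NA_integer_, length(spec@switches))
  for (fl in spec@followers) followerOf[fl[1]] <- fl[2]

  addSeries <- function(values, id, mode, ra, rb, role, group) {
    vals[[length(vals) + 1L]] <<- pmax(values, 0)
    ids <<- c(ids, id)
    rows[[length(rows) + 1L]] <<- data.frame(
      mode = mode, chain_a = "A", resno_a = ra, resname_a = "ALA",
      chain_b = "A", resno_b = rb, resname_b = "ALA",
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      series_id = id, role = role, group = group,
      stringsAsFactors = FALSE)
  }

  for (s in seq_along(spec@switches)) {
    sw <- spec@switches[[s]]
    state <- if (!is.na(followerOf[s]))
      ifelse(latents[[followerOf[s]]] > 0, 2L, 1L)
    else .switchStates(nf, length(sw$means), sw$transitions)
    d <- sw$means[state] + rnorm(nf, 0, sw$sds[state])
    pr <- if (is.null(sw$pair)) c(s, s + 3L) else sw$pair
    addSeries(d, .seriesId("A", "ALA", pr[1], "A", "ALA", pr[2],
                           "sidechain_vdw"),
              "sidechain_vdw", pr[1], pr[2], "switch", s)
  }

  for (b in seq_along(spec@domainBlocks)) {
    bl <- spec@domainBlocks[[b]]
    nSeries <- if (!is.null(bl$nSeries)) bl$nSeries
               else length(bl$members)
    nsd <- if (is.null(bl$noiseSd)) 0.1 else bl$noiseSd
    for (s in seq_len(nSeries)) {
      base <- runif(1, 8, 15)
      scale <- runif(1, 0.8, 1.2)
      d <- base + scale * latents[[b]] + rnorm(nf, 0, nsd)
      ra <- 100L * b + s
      addSeries(d, .seriesId("A", "ALA", ra, "A", "ALA", ra + 50L,
                             "calpha"),
                "calpha", ra, ra + 50L, "block", b)
    }
  }

  for (s in seq_len(spec@backgroundSeries)) {
    base <- runif(1, 4, 12)
    d <- base + rnorm(nf, 0, spec@noiseSd)
    ra <- 900L + 2L * s
    addSeries(d, .seriesId("A", "ALA", ra, "A", "ALA", ra + 51L,
                           "calpha"),
              "calpha", ra, ra + 51L, "background", s)
  }

  if (length(vals) == 0L) stop("spec plants no series")
  list(series = .makeSeriesSet(do.call(rbind, vals), ids,
                               do.call(rbind, rows)),
       truth = do.call(rbind, truth),
       latents = latents)
}

# serpentine coordinates of the static body: rows of 3 residues, 3.8 A
# within a row, 4.8 A between rows, direction alternating per row.  A
# switch pair (i, i+3) is spatially adjacent only in the middle column.
.serpentinePos <- function(r) {
  row <- (r - 1L) %/% 3L
  col <- (r - 1L) %% 3L
  x <- if (row %% 2L == 0L) col * 3.8 else (2L - col) * 3.8
  c(x, row * 4.8, 0)
}

#' Realize a synthetic spec as a multi-model PDB trajectory
#'
#' Builds a coarse polyalanine chain (CA + CB per residue) whose
#' inter-residue distances realize the planted structures: switch-pair
#' residues sit on adjacent serpentine rows and the partner's CB is placed
#' along the pair axis at exactly the planted state distance, so the
#' side-chain minimum-distance series reproduces the plant; domain-block
#' residues form a rigid arm displaced along its own axis by the block's
#' latent drift, so static-to-block C-alpha distances co-vary linearly
#' with the drift.  All other atoms receive isotropic Gaussian jitter of
#' SD \code{noiseSd}.  The result is written as a parseable multi-model
#' PDB so the full pipeline is exercised end to end.
#'
#' Geometric constraints (violations raise an error naming them): at most
#' one domain block, occupying a contiguous suffix of the chain; every
#' switch pair is \code{(i, i + 3)} with \code{i} in the serpentine middle
#' column (i.e. \code{i mod 3 == 2}) and both residues static.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param path output PDB path.
#' @return invisibly, a list with \code{path}, \code{truth} (planted
#'   ground truth: switch pairs with state means, block residue members,
#'   follower couplings), \code{latents} and \code{spec}.
#' @export
generateTrajectory <- function(spec, path) {
  stopifnot(is(spec, "SyntheticSpec"))
  n <- spec@nResidues
  if (n < 6L) stop("need at least 6 residues")
  nf <- spec@nFrames
  if (length(spec@domainBlocks) > 1L)
    stop("geometric infeasibility: at most one domain block can be ",
         "realized on the serpentine-plus-arm template")

  block <- integer(0)
  amplitude <- 0
  if (length(spec@domainBlocks) == 1L) {
    bl <- spec@domainBlocks[[1]]
    if (is.null(bl$members))
      stop("trajectory realization needs explicit block 'members'")
    block <- sort(as.integer(bl$members))
    amplitude <- if (is.null(bl$amplitude)) 2 else bl$amplitude
    if (!identical(block, seq(min(block), n)))
      stop("geometric infeasibility: block members must be a contiguous ",
           "suffix of the chain (got ", paste(block, collapse = ","),
           " of ", n, " residues)")
  }
  static <- setdiff(seq_len(n), block)

  for (sw in spec@switches) {
    pr <- sw$pair
    if (pr[2] - pr[1] != 3L || (pr[1] - 1L) %% 3L != 1L)
      stop("geometric infeasibility: switch pair (", pr[1], ",", pr[2],
           ") must be (i, i+3) with i in the serpentine middle column")
    if (!all(pr %in% static))
      stop("geometric infeasibility: switch pair (", pr[1], ",", pr[2],
           ") overlaps the domain block")
  }

  # static CA scaffold
  ca0 <- matrix(NA_real_, n, 3)
  for (r in static) ca0[r, ] <- .serpentinePos(r)
  maxStaticX <- max(ca0[static, 1])
  if (length(block)) {
    xStart <- maxStaticX + max(7.4, amplitude + 5.5)
    for (r in block)
      ca0[r, ] <- c(xStart + (r - min(block)) * 3.8, 2.4, 0)
  }
  # CB atoms sit 2.5 A above the backbone plane so that only planted
  # switch pairs (whose CBs are re-placed in-plane along the pair axis)
  # can come within the 5 A side-chain contact cutoff
  cb0 <- ca0 + matrix(rep(c(0, 0, 2.5), each = n), n, 3)

  set.seed(spec@seed)
  latents <- lapply(seq_along(spec@domainBlocks), function(b) {
    bl <- spec@domainBlocks[[b]]
    .latentDrift(nf, if (is.null(bl$amplitude)) 2 else bl$amplitude, b)
  })
  followerOf <- rep(NA_integer_, length(spec@switches))
  for (fl in spec@followers) followerOf[fl[1]] <- fl[2]

  switchDist <- vector("list", length(spec@switches))
  for (s in seq_along(spec@switches)) {
    sw <- spec@switches[[s]]
    state <- if (!is.na(followerOf[s]))
      ifelse(latents[[followerOf[s]]] > 0, 2L, 1L)
    else .switchStates(nf, length(sw$means), sw$transitions)
    switchDist[[s]] <- pmax(sw$means[state] + rnorm(nf, 0, sw$sds[state]),
                            0.5)
  }

  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    ca <- ca0 + matrix(rnorm(3 * n, 0, spec@noiseSd), n, 3)
    cb <- cb0 + matrix(rnorm(3 * n, 0, spec@noiseSd), n, 3)
    if (length(block)) {
      ca[block, 1] <- ca[block, 1] + latents[[1]][f]
      cb[block, 1] <- cb[block, 1] + latents[[1]][f]
    }
    for (s in seq_along(spec@switches)) {
      pr <- spec@switches[[s]]$pair
      u <- ca0[pr[2], ] - ca0[pr[1], ]
      u <- u / sqrt(sum(u^2))
      cb[pr[1], ] <- ca[pr[1], ] + u * 1.0
      cb[pr[2], ] <- cb[pr[1], ] + u * switchDist[[s]][f]
    }
    lines <- character(2L * n)
    for (r in seq_len(n)) {
      lines[2L * r - 1L] <- .formatAtomLine(2L * r - 1L, "CA", "ALA", "A",
                                            r, ca[r, ], 0, "C")
      lines[2L * r] <- .formatAtomLine(2L * r, "CB", "ALA", "A", r,
                                       cb[r, ], 0, "C")
    }
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)

  truth <- list(
    switches = lapply(seq_along(spec@switches), function(s)
      c(spec@switches[[s]][c("pair", "means", "sds")],
        list(follower = followerOf[s]))),
    blockMembers = block,
    seed = spec@seed)
  invisible(list(path = path, truth = truth, latents = latents,
                 spec = spec))
}
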