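# Independent oracles and fixture builders shared across the suite.

# direct-summation Pearson coefficient (textbook formula), kept free of
# stats::cor so it can cross-check dcc()
pearsonOracle <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# connected components of the thresholded correlation graph by plain BFS;
# returns an integer membership vector in node order
bfsComponents <- function(corMat, rMin) {
  n <- nrow(corMat)
  adj <- corMat >= rMin
  diag(adj) <- FALSE
  memb <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(memb[s])) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(memb[v])) next
      memb[v] <- comp
      queue <- c(queue, which(adj[v, ] & is.na(memb)))
    }
  }
  memb
}

# correlation matrix of clustered random series: g groups of latent-driven
# series plus independent noise series, giving entries both above and
# below any high threshold
clusteredCorMatrix <- function(nSeries, nGroups, seed, n = 80L,
                               noise = 0.05) {
  set.seed(seed)
  nGroups <- max(1L, min(nGroups, nSeries %/% 2L))
  grp <- sample(c(rep(seq_len(nGroups), 2),
                  sample(0:nGroups, nSeries - 2 * nGroups,
                         replace = TRUE)))
  latent <- matrix(rnorm(n * nGroups), n, nGroups)
  vals <- sapply(seq_len(nSeries), function(i) {
    if (grp[i] == 0) rnorm(n)
    else latent[, grp[i]] + rnorm(n, 0, noise)
  })
  cor(vals)
}

# Rand index between two partitions
randIndex <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree) - n) / (n * (n - 1))
}

# write a minimal (multi-model) PDB from a list of frames; each frame is a
# data.frame with name, resname, chain, resno, x, y, z, element
writeTestPDB <- function(frames, path) {
  fmtAtom <- function(serial, a) {
    nm <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else
      sprintf("%-4s", a$name)
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, a$resname, a$chain, a$resno, a$x, a$y, a$z,
            a$element)
  }
  lines <- character()
  for (f in seq_along(frames)) {
    df <- frames[[f]]
    body <- vapply(seq_len(nrow(df)), function(i)
      fmtAtom(i, df[i, ]), character(1))
    lines <- c(lines, sprintf("MODEL     %4d", f), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# a single-frame atom table replicated with optional per-frame offsets
atomRow <- function(name, resname, chain, resno, x, y, z,
                    element = substr(name, 1, 1)) {
  data.frame(name = name, resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}

# the canonical end-to-end spec: one switch (2,5) following one domain
# block (residues 7..12), 12 residues x 500 frames
e2eSpec <- function(seed = 42L) {
  syntheticSpec(
    nFrames = 500L, nResidues = 12L,
    switches = list(list(pair = c(2L, 5L), means = c(2.7, 5.5),
                         sds = c(0.3, 0.3), transitions = integer())),
    domainBlocks = list(list(members = 7:12, amplitude = 2,
                             noiseSd = 0.1)),
    followers = list(c(1L, 1L)), seed = seed)
}
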