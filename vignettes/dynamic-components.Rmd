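---
title: "Detecting coupled side-chain rearrangements and domain motions in MD trajectories"
author: "dyncomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coupled side-chain rearrangements and domain motions in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomp)
```

## The problem and the model

A microsecond-scale MD simulation of a tightly packed protein such as a
G protein-coupled receptor produces thousands of inter-residue distance
time series. Buried in them are two kinds of functionally interesting
events: *side-chain rearrangements* — single inter-residue interactions
that switch abruptly and persistently between distance substates — and
*global domain motions* — many backbone distances drifting together as a
transmembrane helix or loop moves as a body. `dyncomp` detects both,
couples them, and reduces the trajectory to a network of communities,
each community being one protein sector's coherent dynamic behavior.

The two detectors deliberately use different statistics, because the two
motions have different signatures:

* A rearranging side chain produces a **multimodal distance density**.
  We fit univariate Gaussian mixtures to each series' density by
  expectation–maximization, select the number of components by BIC, and
  call the series rearranging when at least two substates survive the
  pruning rules below. The verdict is density-based and therefore blind
  to *when* the transition happens; time-resolved change-point
  localization is out of scope by design.
* A domain motion produces **correlated distance drifts**. All Cα–Cα
  series (pairs within 15 Å at any point, at least 3 residues apart in
  sequence) are pairwise cross-correlated at zero lag (Pearson r — the
  "DCC"), and single-linkage clusters at r ≥ 0.95 with at least 2
  members become domain components.

Working on scalar distances rather than Cartesian coordinates removes
global translation/rotation, so the pipeline never superimposes
structures; this is an assumption-free simplification, not an
approximation.

Components are then coupled by the absolute *average* cross-component
DCC, c(x,y) = |mean r(i,j)|. The order matters: averaging before taking
the absolute value lets anti-correlated member pairs cancel, so a
component that is half-correlated, half-anti-correlated with another
couples weakly. At the clustering stage, in contrast, *signed* r is
used, so anti-correlated Cα series never join one domain cluster; only
the network stage takes absolute values. Edges at c ≥ 0.75 (inclusive)
and Girvan–Newman edge-betweenness partitioning — cut at the
modularity maximum over the removal sequence — give the communities.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| side-chain contact cutoff | 5 | Å | a pair "in contact at any point": heavy-atom vdW touching distance |
| Cα pair cutoff | 15 | Å | backbone pairs close enough to report on shared domain motion |
| sequence separation | ≥ 3 | residues | excludes trivially correlated short-range neighbors; applied within a chain only, inter-chain (receptor–ligand) pairs are always eligible |
| `kMax` | 5 | – | more than 5 substates is not interpretable at these series lengths |
| `minWeight` | 0.05 | fraction | a substate occupied < 5 % of the time is indistinguishable from a heavy tail |
| `minSeparation` | 1.0 | Å | substates closer than 1 Å are within thermal noise of each other; both guards settable to 0 to recover the raw BIC verdict |
| `rMin` | 0.95 | – | only near-lockstep Cα series constitute one rigid motion |
| `minClusterSize` | 2 | series | a "collective" motion needs at least two correlated series; singletons are discarded from the domain set |
| `couplingCutoff` | 0.75 | – | deliberately looser than `rMin`: fast side-chain dynamics couple imperfectly to slow domain drifts |

## Numerical contracts

* **EM**: seeded k-means initialization (`nstart = 5`), convergence when
  the per-sample log-likelihood gain falls below 1e-4, cap 500
  iterations. The log-likelihood is non-decreasing by construction
  (log-sum-exp throughout). A run that collapses a component (weight
  < 1e-8·n or variance < 1e-10) is degenerate and is retried from up to
  3 fresh derived seeds; a series whose fits all fail is excluded with a
  logged reason. BIC = (3k − 1) ln n − 2 ln L with ties broken toward
  smaller k; k values needing more than n/10 components are skipped.
  Constant (zero-variance) series are classified unimodal without
  fitting.
* **Clustering**: `hclust(method = "single")` on the dissimilarity
  d = 1 − r, cut at (1 − rMin) + 1e-12 so that a pair at exactly rMin is
  inside a cluster (the cutoff is inclusive everywhere in the package).
  Single linkage at a threshold is equivalent to connected components of
  the graph {r(i,j) ≥ rMin}; the test suite asserts that equivalence
  exactly against a hand-written BFS. Note the dissimilarity is 1 − r,
  *not* a correlation fed directly as a distance: feeding r itself as a
  condensed distance matrix would treat highly correlated series as
  maximally distant and contradict extracting clusters *above* 0.95.
  Zero-variance series are excluded before the matrix with a logged
  list.
* **Communities**: edge betweenness runs on the unweighted topology by
  default (weights kept as attributes; an option traverses edges at
  length 1/weight). Labels are renumbered in node-insertion order, so
  the partition is deterministic. Isolated components are retained by
  default and community counts are reported both with and without them
  in the run manifest.
* **Degenerate inputs**: glycine has no side-chain heavy atoms and
  non-polar residues no polar head group — pairs involving an empty
  selection are silently skipped during screening but raise an
  identifying error if forced through `minDistance`. Self-pairs are
  rejected. Hydrogens are identified by the element field when present,
  else by name. Altloc conformers resolve to highest occupancy, first
  on ties. Terminal oxygens (OXT/OT1/OT2) count as backbone; unknown
  heavy side-chain atoms of standard residues are conservatively
  *included* in the vdW selection.

## The synthetic benchmark: what it emulates, and what not

No reference trajectory is distributable at desk scale, so validation is
property-based on a seeded generator that plants exactly the structures
the detectors look for, at compressed problem sizes chosen once:

* **Switches**: piecewise-constant means (defaults 2.7 / 5.5 Å with
  σ = 0.3 Å, the scale of a hydrogen-bond-forming/breaking tyrosine
  pair) with Gaussian noise; benchmark series are 500–1000 frames.
* **Blocks**: member series share a smooth latent drift plus independent
  noise. The drift is a tanh ramp (amplitude 2 Å, width n/10) for the
  first block and successive cosine harmonics for further blocks — all
  smooth, mutually near-orthogonal shapes, standing in for the
  hundreds-of-nanoseconds incremental changes of real domain motions at
  compressed frame counts — plus low-pass filtered noise.
* **Followers**: a follower switch changes state where its block's
  latent crosses zero, so switch–block coupling is high by construction.
* **Trajectory realization**: `generateTrajectory()` writes a coarse
  polyalanine chain (CA + CB) as a multi-model PDB: switch partners sit
  on adjacent serpentine rows with the partner CB placed along the pair
  axis at exactly the planted distance; block residues form a rigid arm
  translated along its axis by the latent, so static-to-block Cα
  distances inherit the drift linearly; everything else jitters with
  σ = 0.08 Å per coordinate. The 12-residue × 500-frame default
  exercises every stage end to end in seconds.

The generator emulates the *statistical* structure the method assumes —
it does not emulate force-field physics, solvent or membrane contacts,
anharmonic side-chain rotamer kinetics, or the sheer series count of a
real receptor (where the screen faces ~10³–10⁴ series). Passing tests
therefore demonstrate correctness of the detectors and their couplings
under the stated noise model, not field performance on any particular
receptor.

Tests bracket both regimes: plants with mean separation ≫ `minSeparation`
and drift ≫ noise must be recovered; plants below those floors
(e.g. 4.0 vs 4.4 Å substates, or drift amplitude 0.05 Å under 0.3 Å
noise) must be missed.

## Design choices on genuinely open points

* vdW and polar series of the same residue pair are kept as *separate*
  series; both feed the GMM screen.
* A side-chain component always contains exactly one series; domain
  components contain ≥ 2. Side-chain components may couple to each other
  as well as to domain nodes — the network is drawn over all components
  without restriction.
* The representative atom for side-chain pseudobonds is the side-chain
  heavy atom closest to the side-chain geometric center at the exported
  frame (CA for Cα series); community PDBs use CONECT records and encode
  the community id in the B-factor so any standard viewer can color by
  community. The exported frame defaults to the last.
* Trajectory input is multi-model PDB or DCD; XTC is not read.
* The command line is one thin wrapper (`run`, `synth`) over the exported
  functions rather than one subcommand per stage: the per-stage artifacts
  are all written by `runPipeline(outdir=)`, and in R the functions
  themselves are the per-stage interface.

## Limitations

* The modality screen cannot say *when* a switch fires, only that the
  density is multimodal; pair it with a change-point method when timing
  matters.
* Zero-lag correlation misses lagged or nonlinear coupling
  (mutual-information generalizations are out of scope).
* Single linkage chains: two rigid bodies connected by a gradient of
  intermediate series can merge at 0.95; the duality with thresholded
  connected components makes this behavior explicit rather than hiding
  it.
* On real receptors the all-pairs Cα DCC matrix is O(n²) in both time
  and memory (~6000 series is routine but minutes-scale); optional
  screening stride and frame down-sampling are provided and logged.
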