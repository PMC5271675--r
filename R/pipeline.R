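# End-to-end pipeline: trajectory -> contacts -> GMM screen -> DCC
# clustering -> component network -> communities -> exports.

#' Run the full dynamic-components pipeline
#'
#' Executes every stage of the framework on one trajectory: enumerate
#' side-chain (van der Waals and polar) contact pairs at
#' \code{contactCutoff} and C-alpha pairs at \code{calphaCutoff}; screen
#' the side-chain series for multimodal (rearranging) distance densities;
#' cluster the C-alpha DCC matrix at \code{rMin} into domain-motion
#' components; couple all components by absolute average DCC and draw
#' edges at \code{couplingCutoff}; partition the network into communities
#' by edge betweenness.  When \code{outdir} is given, per-stage CSVs, the
#' GraphML network, one pseudobond PDB per community and a YAML run
#' manifest are written there.
#'
#' @param topology,trajectory,stride see [readTrajectory()].
#' @param contactCutoff side-chain / polar contact cutoff in Angstrom
#'   (default 5).
#' @param calphaCutoff C-alpha pair cutoff in Angstrom (default 15).
#' @param rMin DCC cluster extraction cutoff (default 0.95).
#' @param couplingCutoff network edge cutoff (default 0.75).
#' @param minSeqSep minimum intra-chain sequence separation (default 3).
#' @param kMax,minWeight,minSeparation GMM screen settings, see
#'   [selectModel()] and [classifyModality()].
#' @param minClusterSize smallest domain cluster kept (default 2).
#' @param seed integer seed for the (seeded) GMM initializations.
#' @param outdir optional output directory.
#' @param exportFrame frame used for community PDBs (default: final
#'   frame).
#' @return a list with every stage product: \code{trajectory},
#'   \code{sidechainSeries}, \code{screen} (GMM screen output),
#'   \code{calphaSeries}, \code{dccm}, \code{domainComponents},
#'   \code{components} (combined set), \code{network} (a
#'   \linkS4class{ComponentGraph} with communities), and \code{manifest}.
#' @export
runPipeline <- function(topology, trajectory = NULL, stride = 1L,
                        contactCutoff = 5, calphaCutoff = 15,
                        rMin = 0.95, couplingCutoff = 0.75,
                        minSeqSep = 3L, kMax = 5L, minWeight = 0.05,
                        minSeparation = 1.0, minClusterSize = 2L,
                        seed = 1L, outdir = NULL,
                        exportFrame = NULL) {
  traj <- readTrajectory(topology, trajectory, stride = stride)

  # side-chain stage: vdW and polar series are kept as separate entries
  scSeries <- lapply(c("sidechain_vdw", "polar"), function(m) {
    pairs <- enumeratePairs(traj, m, cutoff = contactCutoff,
                            minSeqSep = minSeqSep)
    computeSeries(traj, pairs)
  })
  nonEmpty <- vapply(scSeries, function(s) nrow(s) > 0L, logical(1))
  sidechainSeries <- if (any(nonEmpty))
    do.call(combineSeries, scSeries[nonEmpty]) else .emptySeriesSet(
      nFrames(traj))

  screen <- if (nrow(sidechainSeries) > 0L)
    screenSidechainComponents(sidechainSeries, kMax = kMax, seed = seed,
                              minWeight = minWeight,
                              minSeparation = minSeparation)
  else list(components = new("ComponentSet"), stableContacts = character(),
            fits = list(), summary = NULL)

  # domain stage
  caPairs <- enumeratePairs(traj, "calpha", cutoff = calphaCutoff,
                            minSeqSep = minSeqSep)
  calphaSeries <- computeSeries(traj, caPairs)
  domainComponents <- new("ComponentSet")
  caDccm <- NULL
  if (nrow(calphaSeries) >= 2L) {
    caDccm <- dccMatrix(calphaSeries)
    domainComponents <- clusterSeries(caDccm, rMin = rMin,
                                      minClusterSize = minClusterSize)
  }

  # network stage over all components, on the union of member series
  components <- new("ComponentSet",
    components = c(screen$components@components,
                   domainComponents@components))
  network <- NULL
  fullDccm <- NULL
  if (length(components) > 0L) {
    used <- unlist(lapply(components@components, function(p) p@members))
    sets <- list()
    if (nrow(sidechainSeries) > 0L) sets <- c(sets, sidechainSeries)
    if (nrow(calphaSeries) > 0L) sets <- c(sets, calphaSeries)
    allSeries <- do.call(combineSeries, sets)
    allSeries <- allSeries[match(used, seriesIds(allSeries)), ]
    fullDccm <- if (nrow(allSeries) >= 2L) dccMatrix(allSeries) else
      matrix(1, 1, 1, dimnames = list(used, used))
    network <- buildNetwork(components, fullDccm,
                            couplingCutoff = couplingCutoff)
    network <- detectCommunities(network)
  }

  nCommunities <- if (is.null(network)) 0L else
    length(unique(nodeTable(network)$community))
  isolated <- if (is.null(network)) 0L else
    sum(igraph::degree(network@graph) == 0)

  manifest <- list(
    package = as.character(packageVersion("dyncomp")),
    r_version = as.character(getRversion()),
    inputs = list(
      topology = topology,
      topology_md5 = unname(tools::md5sum(topology)),
      trajectory = if (is.null(trajectory)) NA else trajectory,
      trajectory_md5 = if (is.null(trajectory)) NA else
        unname(tools::md5sum(trajectory)),
      stride = as.integer(stride)),
    cutoffs = list(contact = contactCutoff, calpha = calphaCutoff,
                   r_min = rMin, coupling = couplingCutoff),
    gmm = list(k_max = as.integer(kMax), min_weight = minWeight,
               min_separation = minSeparation, seed = as.integer(seed)),
    clustering = list(min_cluster_size = as.integer(minClusterSize),
                      min_seq_sep = as.integer(minSeqSep)),
    counts = list(
      frames = nFrames(traj),
      residues = nrow(residues(traj)),
      sidechain_series = nrow(sidechainSeries),
      multimodal_series = length(screen$components),
      stable_contacts = length(screen$stableContacts),
      calpha_series = nrow(calphaSeries),
      domain_components = length(domainComponents),
      network_nodes = if (is.null(network)) 0L else
        nrow(nodeTable(network)),
      network_edges = if (is.null(network)) 0L else
        igraph::ecount(network@graph),
      isolated_nodes = isolated,
      communities = nCommunities,
      communities_excluding_isolates = if (is.null(network)) 0L else
        length(unique(nodeTable(network)$community[
          igraph::degree(network@graph) > 0]))))

  result <- list(trajectory = traj, sidechainSeries = sidechainSeries,
                 screen = screen, calphaSeries = calphaSeries,
                 dccm = caDccm, domainComponents = domainComponents,
                 components = components, network = network,
                 fullDccm = fullDccm, manifest = manifest)

  if (!is.null(outdir)) .writePipelineOutputs(result, outdir, exportFrame)
  result
}

.writePipelineOutputs <- function(result, outdir, exportFrame = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  if (nrow(result$sidechainSeries) > 0L)
    writeSeriesCSV(result$sidechainSeries, p("sidechain_series.csv"))
  if (nrow(result$calphaSeries) > 0L)
    writeSeriesCSV(result$calphaSeries, p("calpha_series.csv"))
  if (!is.null(result$screen$summary))
    write.csv(result$screen$summary, p("gmm_screen.csv"),
              row.names = FALSE)
  if (!is.null(result$dccm))
    write.csv(as.data.frame(result$dccm), p("dcc_matrix.csv"))
  if (length(result$domainComponents) > 0L) {
    memb <- do.call(rbind, lapply(
      result$domainComponents@components, function(pp)
        data.frame(component_id = pp@componentId, series_id = pp@members,
                   stringsAsFactors = FALSE)))
    write.csv(memb, p("domain_membership.csv"), row.names = FALSE)
    write.csv(linkageTable(result$domainComponents), p("linkage.csv"),
              row.names = FALSE)
  }
  if (!is.null(result$network)) {
    exportGraph(result$network, p("network.graphml"), p("edges.csv"),
                p("nodes.csv"))
    traj <- result$trajectory
    frame <- if (is.null(exportFrame)) nFrames(traj) else
      as.integer(exportFrame)
    allSeries <- tryCatch(
      combineSeries(result$sidechainSeries, result$calphaSeries),
      error = function(e) NULL)
    labels <- communityLabels(result$network)
    if (!is.null(allSeries)) {
      for (cm in sort(unique(labels))) {
        ids <- names(labels)[labels == cm]
        comps <- result$components@components[
          componentIds(result$components) %in% ids]
        writeCommunityPDB(traj, allSeries,
                          comps, p(sprintf("community_%02d.pdb", cm)),
                          frame = frame, communityId = cm)
      }
    }
  }
  writeRunManifest(result$manifest, p("run_manifest.yaml"))
  invisible(outdir)
}
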