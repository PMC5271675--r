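# Component coupling, network construction and community detection.

mkComp <- function(id, members, kind = "domain") {
  if (length(members) == 1) kind <- "sidechain"
  new("DynamicComponent", componentId = id, kind = kind,
      members = members)
}

# correlation matrix of planted component structure: each component's
# member series follow the component group's latent, so within-group
# couplings are high and cross-group couplings low
componentFixture <- function(seed, nGroups = 2L, compsPerGroup = 3L,
                             membersPerComp = 2L, n = 300L,
                             noise = 0.15) {
  set.seed(seed)
  latent <- matrix(rnorm(n * nGroups), n, nGroups)
  comps <- list(); vals <- list(); ids <- character()
  plant <- integer()
  for (g in seq_len(nGroups)) for (cc in seq_len(compsPerGroup)) {
    mem <- character(membersPerComp)
    for (s in seq_len(membersPerComp)) {
      id <- sprintf("g%d_c%d_s%d", g, cc, s)
      vals[[id]] <- latent[, g] + rnorm(n, 0, noise)
      mem[s] <- id
    }
    comps[[length(comps) + 1]] <- mkComp(sprintf("g%d_c%d", g, cc), mem)
    plant <- c(plant, g)
  }
  m <- cor(do.call(cbind, vals))
  list(components = new("ComponentSet", components = comps),
       dccm = m, plant = plant)
}

test_that("coupling is |mean r|: averaged first, absolute second", {
  ids <- c("a", "b", "c")
  m <- diag(3); dimnames(m) <- list(ids, ids)
  m["a", "c"] <- m["c", "a"] <- 0.9
  m["b", "c"] <- m["c", "b"] <- -0.9
  m["a", "b"] <- m["b", "a"] <- -0.8

  x <- mkComp("x", c("a", "b"))
  y <- mkComp("y", "c")
  # the decisive cancellation case: mean(0.9, -0.9) = 0, then abs
  expect_equal(componentCoupling(x, y, m), 0.0)
  # single cross pair: absolute of one value
  expect_equal(componentCoupling(mkComp("a1", "a"), mkComp("b1", "b"), m),
               0.8)
  expect_error(componentCoupling(x, mkComp("z", c("b", "c")), m),
               "share member series")
})

test_that("coupling equals the double-loop mean oracle and the averaging bound holds", {
  set.seed(8)
  n <- 200L
  ids <- paste0("s", 1:7)
  vals <- matrix(rnorm(7 * n), nrow = 7, dimnames = list(ids, NULL))
  m <- cor(t(vals))
  x <- mkComp("x", ids[1:3])
  y <- mkComp("y", ids[4:7])
  oracle <- 0
  for (i in 1:3) for (j in 4:7) oracle <- oracle + m[ids[i], ids[j]]
  oracle <- abs(oracle / 12)
  cpl <- componentCoupling(x, y, m)
  expect_equal(cpl, oracle, tolerance = 1e-12)
  expect_lte(cpl, max(abs(m[ids[1:3], ids[4:7]])))
})

test_that("network edges respect the inclusive coupling cutoff", {
  ids <- c("a", "b")
  m <- diag(2); dimnames(m) <- list(ids, ids)
  m["a", "b"] <- m["b", "a"] <- -0.75   # coupling |−0.75| = 0.75 exactly
  comps <- new("ComponentSet", components = list(mkComp("x", "a"),
                                                 mkComp("y", "b")))
  g <- buildNetwork(comps, m, couplingCutoff = 0.75)
  expect_equal(igraph::ecount(g@graph), 1L)   # >= is inclusive
  expect_equal(igraph::E(g@graph)$weight, 0.75)

  single <- buildNetwork(new("ComponentSet",
                             components = list(mkComp("x", "a"))),
                         diag(1, 1, 1) |>
                           (\(mm) {dimnames(mm) <- list("a", "a"); mm})())
  expect_equal(igraph::vcount(single@graph), 1L)
  expect_equal(igraph::ecount(single@graph), 0L)
})

test_that("edge set equals an independently thresholded coupling matrix and shrinks with the cutoff", {
  fx <- componentFixture(seed = 3)
  g <- buildNetwork(fx$components, fx$dccm, couplingCutoff = 0.75)
  cm <- couplings(g)
  edges <- igraph::as_data_frame(g@graph, what = "edges")
  gotEdges <- sort(paste(pmin(edges$from, edges$to),
                         pmax(edges$from, edges$to)))
  ids <- componentIds(fx$components)
  expEdges <- character()
  for (i in seq_along(ids)[-length(ids)])
    for (j in seq((i + 1), length(ids)))
      if (cm[ids[i], ids[j]] >= 0.75)
        expEdges <- c(expEdges, paste(pmin(ids[i], ids[j]),
                                      pmax(ids[i], ids[j])))
  expect_setequal(gotEdges, sort(expEdges))

  # monotone: a higher cutoff only removes edges
  for (cut in c(0.8, 0.9, 0.97)) {
    g2 <- buildNetwork(fx$components, fx$dccm, couplingCutoff = cut)
    e2 <- igraph::as_data_frame(g2@graph, what = "edges")
    got2 <- paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to))
    expect_true(all(got2 %in% gotEdges))
    gotEdges <- got2
  }
})

test_that("two cliques joined by one bridge split at the bridge; uniform graphs do not split", {
  adj <- matrix(0, 8, 8)
  ids <- paste0("n", 1:8)
  dimnames(adj) <- list(ids, ids)
  adj[1:4, 1:4] <- 0.9; adj[5:8, 5:8] <- 0.9
  adj[4, 5] <- adj[5, 4] <- 0.9          # the bridge
  diag(adj) <- 1
  comps <- new("ComponentSet",
               components = lapply(ids, function(i) mkComp(i, i)))
  g <- detectCommunities(buildNetwork(comps, adj, couplingCutoff = 0.75))
  lab <- communityLabels(g)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[c("n1", "n2", "n3", "n4")])), 1L)
  expect_equal(length(unique(lab[c("n5", "n6", "n7", "n8")])), 1L)
  expect_false(lab[["n1"]] == lab[["n8"]])

  # fully connected uniform-weight graph: a single community
  full <- matrix(0.9, 5, 5); diag(full) <- 1
  dimnames(full) <- list(paste0("m", 1:5), paste0("m", 1:5))
  compsF <- new("ComponentSet",
                components = lapply(paste0("m", 1:5),
                                    function(i) mkComp(i, i)))
  gF <- detectCommunities(buildNetwork(compsF, full,
                                       couplingCutoff = 0.75))
  expect_equal(length(unique(communityLabels(gF))), 1L)
})

test_that("planted two-block component sets are recovered exactly (Rand index 1)", {
  for (seed in 1:20) {
    fx <- componentFixture(seed = 1000 + seed)
    g <- detectCommunities(buildNetwork(fx$components, fx$dccm,
                                        couplingCutoff = 0.75))
    lab <- communityLabels(g)[componentIds(fx$components)]
    expect_equal(randIndex(unname(lab), fx$plant), 1.0,
                 info = paste("seed", seed))
  }
})

test_that("community labels partition the nodes and disconnected parts never share one", {
  fx <- componentFixture(seed = 55, nGroups = 3L)
  g <- detectCommunities(buildNetwork(fx$components, fx$dccm,
                                      couplingCutoff = 0.75))
  lab <- communityLabels(g)
  expect_false(anyNA(lab))
  expect_equal(length(lab), length(fx$plant))
  igc <- igraph::components(g@graph)$membership
  # nodes in different graph components have different community labels
  for (i in seq_along(lab)) for (j in seq_along(lab))
    if (igc[i] != igc[j]) expect_false(lab[i] == lab[j])
})
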