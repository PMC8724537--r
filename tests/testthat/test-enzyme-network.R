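toyDb <- function() {
  ## hand-enumerable: P1 chains r1 -> r2 (shared C2), P1 r2 -> r3 shares
  ## only ATP (currency, no edge); P2 connects e4 -> e1 via C9
  data.frame(
    pathway_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    reaction_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    ec = c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4", "1.1.1.1",
           "9.9.9.9"),
    substrates = c("C1", "C2", "ATP;C5", "C8", "C9", "C20"),
    products = c("C2;ATP", "C3", "C6", "C9;NADH", "C10", "C21"),
    stringsAsFactors = FALSE)
}

test_that("EC extraction validates, de-duplicates and flags partials", {
  annot <- data.frame(gene_id = paste0("g", 1:6),
                      EC = c("1.1.1.1", "1.1.1.1", "2.7.1.40;3.5.1.-",
                             "2.7.x", "", "7.2.2.19"),
                      stringsAsFactors = FALSE)
  expect_warning(ecs <- extractEC(annot), "2.7.x")
  expect_setequal(ecs$ec, c("1.1.1.1", "2.7.1.40", "3.5.1.-", "7.2.2.19"))
  expect_setequal(strsplit(ecs$genes[ecs$ec == "1.1.1.1"], ";")[[1]],
                  c("g1", "g2"))
  expect_true(ecs$partial[ecs$ec == "3.5.1.-"])
  expect_false(any(ecs$partial[ecs$ec != "3.5.1.-"]))
  ## 19 genes with 19 distinct ECs yield 19 prospective nodes
  many <- data.frame(gene_id = paste0("G", 1:19),
                     EC = sprintf("1.1.1.%d", 1:19))
  expect_equal(nrow(extractEC(many)), 19)
})

test_that("network construction follows product->substrate sharing", {
  net <- buildEnzymeNetwork("1.1.1.1", toyDb())
  ## P1 and P2 are retrieved (they contain the query), P3 is not
  expect_setequal(net@nodes$ec,
                  c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"))
  el <- igraph::as_edgelist(net@graph)
  ## C2 chains 1.1.1.1 -> 2.2.2.2; C9 chains 4.4.4.4 -> 1.1.1.1
  expect_true(any(el[, 1] == "1.1.1.1" & el[, 2] == "2.2.2.2"))
  expect_true(any(el[, 1] == "4.4.4.4" & el[, 2] == "1.1.1.1"))
  ## ATP sharing alone creates no edge into 3.3.3.3
  expect_false(any(el[, 2] == "3.3.3.3" | el[, 1] == "3.3.3.3"))
  expect_equal(igraph::ecount(net@graph), 2)
  ## disconnected query members are retained as nodes
  expect_true("3.3.3.3" %in% igraph::V(net@graph)$name)
  ## no pathway hit: empty network with warning
  expect_warning(empty <- buildEnzymeNetwork("8.8.8.8", toyDb()),
                 "no pathway")
  expect_equal(igraph::vcount(empty@graph), 0)
})

test_that("small-graph topology matches hand calculations", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  tp <- networkTopology(path3)
  tab <- tp@nodeTable
  b <- tab[tab$node == "B", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$stress, 1)
  expect_equal(b$eccentricity, 1)
  expect_equal(tp@graphStats$diameter, 2)
  a <- tab[tab$node == "A", ]
  expect_equal(a$betweenness, 0)
  expect_equal(a$avg.path.length, 1.5)
  ## 4-cycle: full symmetry, neighborhood connectivity 2 everywhere
  cyc <- igraph::make_ring(4)
  igraph::V(cyc)$name <- letters[1:4]
  tc <- networkTopology(cyc)@nodeTable
  expect_equal(length(unique(tc$betweenness)), 1)
  expect_true(all(tc$neighborhood.connectivity == 2))
  expect_true(all(tc$eccentricity == 2))
})

test_that("topology equals the path-enumeration oracle on random graphs", {
  for (s in 1:5) {
    fx <- randomConnectedGraph(12, 0.25, seed = s)
    tp <- networkTopology(fx$graph)@nodeTable
    oracle <- topologyOracle(fx$am)
    expect_equal(tp$betweenness, oracle$betweenness, tolerance = 1e-12)
    expect_identical(tp$stress, oracle$stress)  # exact integers
    expect_equal(tp$eccentricity, oracle$eccentricity)
    expect_equal(tp$avg.path.length, oracle$avg.path.length,
                 tolerance = 1e-12)
  }
})

test_that("mean neighbor count equals 2E/N on simple graphs", {
  for (s in 1:3) {
    fx <- randomConnectedGraph(10, 0.3, seed = 100 + s)
    gs <- networkTopology(fx$graph)@graphStats
    expect_equal(gs$mean.neighbors, 2 * gs$n.edges / gs$n.nodes)
  }
})

test_that("hub calling is the Tukey rule and scale-invariant", {
  mkReport <- function(deg) {
    new("TopologyReport",
        nodeTable = data.frame(node = paste0("n", seq_along(deg)),
                               degree.in = 0L, degree.out = 0L,
                               degree = as.integer(deg), betweenness = 0,
                               stress = 0, eccentricity = 0,
                               avg.path.length = 0,
                               neighborhood.connectivity = 0),
        graphStats = list())
  }
  expect_equal(detectHubs(mkReport(c(1, 1, 1, 1, 20))), "n5")
  expect_equal(length(detectHubs(mkReport(rep(3, 8)))), 0)
  set.seed(9)
  deg <- c(rpois(40, 3) + 1, 40, 55)   # planted heavy tail
  rep1 <- mkReport(deg)
  q <- quantile(deg, c(0.25, 0.75), type = 7)
  direct <- paste0("n", which(deg > q[2] + 1.5 * (q[2] - q[1])))
  expect_setequal(detectHubs(rep1), direct)
  expect_setequal(detectHubs(mkReport(deg * 7)), direct)
  expect_error(detectHubs(mkReport(c(1, 2, 3))), ">= 4 nodes")
})

test_that("persistent communities recover planted cliques", {
  cl2 <- igraph::graph_from_edgelist(
    rbind(t(combn(1:6, 2)), t(combn(7:12, 2)), c(1, 7)), directed = FALSE)
  igraph::V(cl2)$name <- paste0("v", 1:12)
  ch <- detectCommunities(cl2, persistenceMin = 2, seed = 1)
  expect_equal(nrow(ch@table), 2)
  expect_true(any(vapply(ch@members, setequal, logical(1),
                         paste0("v", 1:6))))
  expect_true(any(vapply(ch@members, setequal, logical(1),
                         paste0("v", 7:12))))
  ## identical rerun under the same seed
  ch2 <- detectCommunities(cl2, persistenceMin = 2, seed = 1)
  expect_identical(ch@table, ch2@table)
  ## complete graph: a single community at low resolution
  k8 <- igraph::make_full_graph(8)
  igraph::V(k8)$name <- paste0("k", 1:8)
  chK <- detectCommunities(k8, resolutions = c(0.1, 0.15, 0.2),
                           persistenceMin = 2, seed = 1)
  expect_equal(nrow(chK@table), 1)
  expect_equal(chK@table$size, 8)
  ## edgeless network warns and reports nothing
  e0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e0)$name <- c("x", "y", "z")
  expect_warning(ch0 <- detectCommunities(e0), "edgeless")
  expect_equal(nrow(ch0@table), 0)
})

test_that("an end-to-end enzyme network from synthetic inputs is sane", {
  db <- simulatePathwayDb(28, sprintf("1.1.1.%d", 1:19),
                          sharedCompoundRate = 0.8, seed = 4)
  net <- buildEnzymeNetwork(sprintf("1.1.1.%d", 1:5), db)
  expect_gt(igraph::vcount(net@graph), 5)  # pathway neighbours included
  tp <- networkTopology(net)
  expect_equal(tp@graphStats$diameter,
               max(tp@nodeTable$eccentricity[
                 igraph::components(net@simple)$membership ==
                   which.max(igraph::components(net@simple)$csize)]))
  expect_true(all(tp@nodeTable$betweenness >= 0 &
                    tp@nodeTable$betweenness <= 1))
})
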