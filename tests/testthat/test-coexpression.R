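plantedExpr <- function(seed, moduleSizes = c(50, 50), nNoise = 300,
                        nHk = 500, corWithin = 0.95, ns = 24) {
  sim <- simulateGenotypes(20, data.frame(n = length(moduleSizes), r2 = 1),
                           qtl = data.frame(
                             marker = seq_along(moduleSizes),
                             effect = rep(1, length(moduleSizes))),
                           seed = 1)
  simulateExpression(sim$genotypes, sim$truth,
                     nModules = length(moduleSizes),
                     moduleSizes = moduleSizes, corWithin = corWithin,
                     nSamplesExpr = ns, nNoiseGenes = nNoise,
                     nHousekeeping = nHk, seed = seed)
}

test_that("CPM filtering and quantile normalization behave by definition", {
  set.seed(1)
  counts <- matrix(rnbinom(50 * 6, mu = 300, size = 10), 50, 6,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  counts[3, ] <- 0                      # all-zero gene must go
  E <- preprocessCounts(counts, minCpm = 10)
  expect_false("g3" %in% rownames(E@logCPM))
  ## after quantile normalization the sorted columns coincide
  for (j in 2:ncol(E@logCPM))
    expect_equal(sort(E@logCPM[, 1]), sort(E@logCPM[, j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  ## scaling all library sizes leaves the retained set identical
  E10 <- preprocessCounts(counts * 10, minCpm = 10)
  expect_identical(rownames(E@logCPM), rownames(E10@logCPM))
  ## idempotence: normalizing the normalized matrix changes nothing
  expect_identical(quantileNormalize(E@logCPM), E@logCPM)
  ## zero library size names the sample
  bad <- counts; bad[, 2] <- 0
  expect_error(preprocessCounts(bad), "s2")
})

test_that("soft threshold: connectivity falls with power, fit drives choice", {
  X <- scaleFreeExpr(seed = 1)
  sft <- pickSoftThreshold(X, powers = 1:12)
  expect_true(all(diff(sft$fitTable$mean.k) < 0))
  expect_gte(sft$scaleFreeR2, 0.85)
  expect_equal(sft$beta,
               sft$fitTable$power[which(sft$fitTable$sft.R2 >= 0.85)[1]])
  ## white noise cannot reach the target: argmax + warning
  set.seed(2)
  W <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(paste0("g", 1:60),
                                                      NULL))
  expect_warning(sftW <- pickSoftThreshold(W, powers = 1:6), "argmax")
  expect_equal(sftW$beta,
               sftW$fitTable$power[which.max(sftW$fitTable$sft.R2)])
  expect_error(pickSoftThreshold(W[1:10, ]), ">= 30 genes")
  Wc <- W; Wc[5, ] <- 2
  expect_error(pickSoftThreshold(Wc), "constant")
})

test_that("TOM matches the triple-loop oracle and its limits", {
  set.seed(3)
  X <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("g", 1:5), NULL))
  tom <- tomMatrix(X, beta = 6)
  expect_equal(tom, tomOracle(X, 6), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(tom, t(tom))
  expect_equal(unname(diag(tom)), rep(1, 5))
  ## two perfectly correlated genes: overlap 1
  X2 <- rbind(g1 = 1:8, g2 = (1:8) * 2)
  expect_equal(unname(tomMatrix(X2, 4)[1, 2]), 1)
  ## near-independent genes: overlap near 0
  set.seed(4)
  X3 <- matrix(rnorm(2 * 2000), 2, 2000,
               dimnames = list(c("a", "b"), NULL))
  expect_lt(tomMatrix(X3, 6)[1, 2], 0.01)
})

test_that("planted modules are recovered by the adaptive cut", {
  ex <- plantedExpr(seed = 5)
  E <- preprocessCounts(ex$counts)
  truth <- ex$truth@moduleAssignment[rownames(E@logCPM)]
  cm <- cutModules(1 - tomMatrix(E, 6), minModuleSize = 30)
  expect_gt(ariOracle(cm$modules, truth[names(cm$modules)]), 0.9)
  sizes <- table(cm$modules[cm$modules != "0"])
  expect_true(all(sizes >= 30))
})

test_that("white noise yields no modules and tiny panels warn", {
  unassigned <- vapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 24), 100, 24,
                dimnames = list(paste0("g", 1:100), NULL))
    all(cutModules(1 - tomMatrix(X, 6), minModuleSize = 30)$modules == "0")
  }, logical(1))
  expect_true(all(unassigned))
  expect_warning(cm <- cutModules(matrix(0.5, 3, 3) + 0.5 * diag(3) * 0,
                                  minModuleSize = 30),
                 "fewer genes")
  expect_true(all(cm$modules == "0"))
})

test_that("seeded module selection picks exactly the seeded labels", {
  modules <- setNames(rep(c("1", "2", "3", "0"), each = 10),
                      paste0("g", 1:40))
  expect_equal(selectSeededModules(modules, "g1"), "1")
  expect_equal(selectSeededModules(modules, c("g1", "g2")), "1")
  expect_equal(selectSeededModules(modules, c("g1", "g11", "g21")),
               c("1", "2", "3"))
  ## unassigned or absent seeds select nothing
  expect_warning(sel <- selectSeededModules(modules, "g31"), "no seed")
  expect_equal(length(sel), 0)
  expect_message(selectSeededModules(modules, c("g1", "ghost")), "ghost")
})

test_that("seeded subnetwork edges respect the |r| cutoff and HITS", {
  ## star: one hub correlated with 10 spokes, spokes mutually uncorrelated
  set.seed(6)
  ns <- 2000   # large so spoke-spoke |r| stays well below the cutoff
  hub <- rnorm(ns)
  X <- rbind(hub = hub,
             t(sapply(1:10, function(i) 0.9 * hub + sqrt(1 - 0.81) *
                        rnorm(ns))))
  rownames(X) <- c("hub", paste0("sp", 1:10))
  modules <- setNames(rep("1", 11), rownames(X))
  sn <- buildSeededSubnetwork(X, modules, "1", minAbsR = 0.85)
  expect_equal(unname(hubScores(sn)["hub"]), 1)
  expect_equal(max(hubScores(sn)), 1)
  ## r below the cutoff never creates an edge
  set.seed(7)
  a <- rnorm(ns)
  b <- 0.49 * a + sqrt(1 - 0.49^2) * rnorm(ns)
  b <- b + (0.49 - cor(a, b)) * a   # nudge to r ~ 0.49
  X2 <- rbind(a = a, b = b)
  sn2 <- buildSeededSubnetwork(X2, setNames(c("1", "1"), c("a", "b")), "1",
                               minAbsR = max(0.5, abs(cor(a, b)) + 0.001))
  expect_equal(igraph::ecount(sn2@graph), 0)
  expect_error(buildSeededSubnetwork(X2, setNames("0", "zzz"), "9"),
               "empty node set")
})

test_that("HITS hub scores equal the power-iteration oracle", {
  set.seed(8)
  X <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(paste0("g", 1:8), NULL))
  modules <- setNames(rep("1", 8), rownames(X))
  sn <- buildSeededSubnetwork(X, modules, "1", minAbsR = 0.1)
  A <- igraph::as_adjacency_matrix(sn@graph, attr = "weight",
                                   sparse = FALSE)
  oracle <- hitsOracle(A)
  expect_equal(unname(hubScores(sn)[rownames(A)]), unname(oracle),
               tolerance = 1e-8)
  ## uniform edge-weight scaling leaves scores unchanged
  expect_equal(GrowthOmics:::.hitsHub(A * 10), GrowthOmics:::.hitsHub(A),
               tolerance = 1e-10)
})

test_that("the full coexpression model wraps the stages consistently", {
  ex <- plantedExpr(seed = 9, moduleSizes = c(40, 40), nNoise = 100,
                    nHk = 200)
  E <- preprocessCounts(ex$counts)
  cmod <- suppressWarnings(coexpressionModel(E, beta = 6,
                                             minModuleSize = 30))
  expect_s4_class(cmod, "CoexpressionModel")
  expect_equal(cmod@beta, 6)
  expect_equal(dim(cmod@tom), rep(nrow(E@logCPM), 2))
  expect_setequal(names(moduleLabels(cmod)), rownames(E@logCPM))
  hubs <- topHubs(buildSeededSubnetwork(
    E, moduleLabels(cmod), selectSeededModules(
      moduleLabels(cmod), names(ex$truth@moduleAssignment)[1])), k = 10)
  expect_lte(nrow(hubs), 10)
  expect_equal(hubs$hub.score[1], 1)
})
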