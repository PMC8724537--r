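test_that("same seed reproduces genotypes byte-identically", {
  a <- simulateGenotypes(30, data.frame(n = c(4, 4), r2 = c(0.5, 0.9)),
                         missingRate = 0.05, seed = 11)
  b <- simulateGenotypes(30, data.frame(n = c(4, 4), r2 = c(0.5, 0.9)),
                         missingRate = 0.05, seed = 11)
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(markerInfo(a$genotypes), markerInfo(b$genotypes))
  c <- simulateGenotypes(30, data.frame(n = c(4, 4), r2 = c(0.5, 0.9)),
                         missingRate = 0.05, seed = 12)
  expect_false(identical(dosage(a$genotypes), dosage(c$genotypes)))
})

test_that("perfect within-block LD gives identical dosage columns", {
  sim <- simulateGenotypes(50, data.frame(n = 5, r2 = 1), seed = 3)
  d <- dosage(sim$genotypes)
  for (j in 2:5) expect_identical(unname(d[, j]), unname(d[, 1]))
})

test_that("zero within-block r2 gives near-independent markers", {
  sim <- simulateGenotypes(2000, data.frame(n = c(5, 5), r2 = c(0, 0)),
                           seed = 8)
  r2 <- ldR2(sim$genotypes)$r2
  expect_lt(mean(r2, na.rm = TRUE), 0.01)
})

test_that("LD calibration hits the block target and TE blocks are damped", {
  sim <- simulateGenotypes(800, data.frame(n = rep(6, 8), r2 = rep(0.8, 8)),
                           teFraction = 0.5, seed = 5)
  blockOf <- sim$truth@ldBlockMap
  teBlocks <- unique(blockOf[markerInfo(sim$genotypes)$id[
    markerInfo(sim$genotypes)$pos >= sim$truth@teRegions$start[1] &
      markerInfo(sim$genotypes)$pos <= sim$truth@teRegions$end[1]]])
  ld <- ldR2(sim$genotypes, window = 10000)
  mk <- markerInfo(sim$genotypes)
  bA <- blockOf[ld$markerA]
  within <- ld[bA == blockOf[ld$markerB], ]
  isTe <- bA[bA == blockOf[ld$markerB]] %in%
    unique(blockOf)[sapply(unique(blockOf), function(b) {
      ids <- names(blockOf)[blockOf == b]
      p <- mk$pos[match(ids, mk$id)]
      any(sim$truth@teRegions$start <= min(p) &
            sim$truth@teRegions$end >= max(p))
    })]
  expect_equal(mean(within$r2[!isTe]), 0.8, tolerance = 0.05)
  expect_equal(mean(within$r2[isTe]), 0.2, tolerance = 0.05)
})

test_that("genotype generator validates its inputs", {
  expect_error(simulateGenotypes(1, data.frame(n = 3, r2 = 0.5)))
  expect_error(simulateGenotypes(10, data.frame(n = numeric(), r2 = numeric())))
  expect_error(simulateGenotypes(10, data.frame(n = 3, r2 = 0.5),
                                 mafRange = c(0, 0.6)))
})

test_that("noise-free phenotypes reduce to the fixed-effect surface", {
  sim <- simulateGenotypes(10, data.frame(n = 3, r2 = 1),
                           varianceComponents = c(sigmaG2 = 0,
                                                  sigmaGW2 = 0,
                                                  sigmaE2 = 0),
                           seed = 2)
  ids <- rownames(dosage(sim$genotypes))
  des <- fullDesign(ids)
  zeroFx <- list(block = c(b1 = 0), replicate = c(r1 = 0),
                 water = c(low = 0), month = c(m1 = 0))
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, des, mu = 10,
                           fixedEffects = zeroFx, seed = 1)
  expect_true(all(abs(ph$value - 10) < 1e-12))
})

test_that("simulated residual variance matches the requested component", {
  sim <- simulateGenotypes(437, data.frame(n = 3, r2 = 0.5),
                           varianceComponents = c(sigmaG2 = 4.56,
                                                  sigmaGW2 = 0.0001,
                                                  sigmaE2 = 26.69),
                           seed = 1)
  ids <- rownames(dosage(sim$genotypes))
  des <- fullDesign(ids)
  zeroFx <- list(block = c(b1 = 0), replicate = c(r1 = 0),
                 water = c(low = 0), month = c(m1 = 0))
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, des, mu = 0,
                           fixedEffects = zeroFx, seed = 2)
  ## residual after removing the per-genotype x water means is pure eps
  cell <- paste(ph$genotype, ph$water)
  eps <- ph$value - ave(ph$value, cell)
  nCell <- ave(rep(1, nrow(ph)), cell, FUN = sum)
  essVar <- sum(eps^2) / (nrow(ph) - length(unique(cell)))
  expect_equal(essVar, 26.69, tolerance = 0.10 * 26.69)
})

test_that("a planted QTL effect is recovered by regression", {
  sim <- simulateGenotypes(437, data.frame(n = 5, r2 = 0.5),
                           mafRange = c(0.09, 0.11),
                           qtl = data.frame(marker = 3, effect = -1.00),
                           varianceComponents = c(sigmaG2 = 0.5,
                                                  sigmaGW2 = 0.0001,
                                                  sigmaE2 = 26.69),
                           seed = 4)
  ids <- rownames(dosage(sim$genotypes))
  des <- fullDesign(ids)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, des, seed = 5)
  ybar <- tapply(ph$value, ph$genotype, mean)[ids]
  d3 <- dosage(sim$genotypes)[, 3]
  fit <- summary(lm(ybar ~ d3))
  est <- fit$coefficients["d3", "Estimate"]
  se <- fit$coefficients["d3", "Std. Error"]
  expect_lt(abs(est - (-1.00)), 2 * se)
})

test_that("phenotype simulation rejects designs with unknown genotypes", {
  sim <- simulateGenotypes(5, data.frame(n = 2, r2 = 1), seed = 1)
  des <- fullDesign(c(rownames(dosage(sim$genotypes)), "GHOST"))
  expect_error(simulatePhenotypes(sim$genotypes, sim$truth, des),
               "absent")
})

test_that("CPM profiles are invariant to library-size scaling", {
  sim <- simulateGenotypes(10, data.frame(n = 2, r2 = 1),
                           qtl = data.frame(marker = 1, effect = 1),
                           seed = 1)
  ex <- simulateExpression(sim$genotypes, sim$truth, nModules = 1,
                           moduleSizes = 40, corWithin = 0.9,
                           nSamplesExpr = 10, nHousekeeping = 40, seed = 3)
  E1 <- preprocessCounts(ex$counts)
  E2 <- preprocessCounts(ex$counts * 10)
  expect_identical(rownames(E1@logCPM), rownames(E2@logCPM))
  expect_equal(E1@logCPM, E2@logCPM, tolerance = 1e-3)
})

test_that("expression generator plants recoverable modules", {
  sim <- simulateGenotypes(10, data.frame(n = 4, r2 = 1),
                           qtl = data.frame(marker = c(1, 3),
                                            effect = c(1, -1)),
                           seed = 1)
  ex <- simulateExpression(sim$genotypes, sim$truth, nModules = 2,
                           moduleSizes = c(50, 50), corWithin = 0.95,
                           nSamplesExpr = 24, seed = 7)
  X <- log2(ex$counts + 1)
  truthLab <- ex$truth@moduleAssignment
  planted <- names(truthLab)[truthLab != "0"]
  hc <- hclust(as.dist(1 - cor(t(X[planted, ]))), method = "average")
  found <- cutree(hc, k = 2)
  expect_gt(ariOracle(found, truthLab[planted]), 0.9)
  ## QTL flanking genes sit in distinct modules next to their QTL
  mk <- markerInfo(sim$genotypes)
  for (k in 1:2) {
    gi <- names(truthLab)[truthLab == as.character(k)][1]
    arow <- ex$annotation[ex$annotation$gene_id == gi, ]
    qpos <- mk$pos[mk$id == sim$truth@qtlMarkers$id[k]]
    expect_equal(arow$chrom, mk$chrom[mk$id == sim$truth@qtlMarkers$id[k]])
    expect_lt(abs(arow$start - qpos), 5000)
  }
})

test_that("single-module expression labels every planted gene together", {
  sim <- simulateGenotypes(5, data.frame(n = 2, r2 = 1), seed = 1)
  ex <- simulateExpression(sim$genotypes, sim$truth, nModules = 1,
                           moduleSizes = 30, corWithin = 0.5,
                           nSamplesExpr = 8, nHousekeeping = 0, seed = 2)
  expect_true(all(ex$truth@moduleAssignment == "1"))
  expect_error(simulateExpression(sim$genotypes, sim$truth, nModules = 2,
                                  moduleSizes = 30, corWithin = 0.5,
                                  nSamplesExpr = 8))
})

test_that("pathway generator is seed-reproducible and chains compounds", {
  ecs <- sprintf("1.1.1.%d", 1:19)
  a <- simulatePathwayDb(28, ecs, sharedCompoundRate = 0.8, seed = 9)
  b <- simulatePathwayDb(28, ecs, sharedCompoundRate = 0.8, seed = 9)
  expect_identical(a, b)
  expect_equal(length(unique(a$pathway_id)), 28)
  ## with no compound sharing, non-cofactor compounds never repeat within
  ## a pathway, so the derived graph has no product->substrate edges
  z <- simulatePathwayDb(10, ecs, sharedCompoundRate = 0, cofactorRate = 0,
                         seed = 2)
  net <- buildEnzymeNetwork(ecs, z)
  expect_equal(igraph::ecount(net@graph), 0)
  expect_error(simulatePathwayDb(3, character(), 0.5))
})
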