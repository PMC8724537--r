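## Synthetic inputs with the statistical structure the pipeline assumes:
## LD-block genotypes with low-LD TE regions, the multi-environment mixed
## phenotype model with planted additive QTLs, a modular expression matrix,
## and a toy pathway flat file. Every generator is fully determined by its
## seed (set.seed() is called at entry).

#' Simulate an LD-block genotype panel
#'
#' Markers are generated in blocks sharing a latent biallelic haplotype:
#' within a block each marker copies the latent allele and flips it
#' independently per haplotype with probability `f`, solved analytically
#' so that the expected pairwise dosage r-squared equals the block target
#' (between two flipped copies `r = (1-2f)^2 p(1-p)/(q(1-q))` with
#' `q = p + f(1-2p)`, which reduces to the symmetric closed form
#' `f = (1 - r2^(1/4))/2` at `p = 0.5`).
#' A fraction of blocks is labelled as TE-dense and generated with the
#' block r-squared multiplied by `teR2Factor`, emulating the lower LD
#' observed in transposable-element-rich regions.
#'
#' @param nSamples number of diploid samples (>= 2).
#' @param blocks data.frame with columns `n` (markers per block, > 0) and
#'   `r2` (target within-block r-squared in [0, 1]).
#' @param teFraction proportion of blocks drawn as TE-dense.
#' @param mafRange interval in (0, 0.5] from which the latent allele
#'   frequency of each block is drawn.
#' @param missingRate proportion of entries set to missing uniformly at
#'   random (default 0.05, exercising the QC filters).
#' @param qtl optional data.frame (`marker` = column index, `effect` in
#'   trait units per alt allele) of planted additive QTLs, recorded in the
#'   returned truth.
#' @param varianceComponents named numeric (`sigmaG2`, `sigmaGW2`,
#'   `sigmaE2`) recorded in the truth for [simulatePhenotypes()].
#' @param teR2Factor multiplier applied to the block r-squared of TE blocks
#'   (default 0.25).
#' @param spacing mean bp between adjacent markers; blocks are separated by
#'   a 50 kb gap; positions are strictly increasing.
#' @param chrom chromosome name for the panel.
#' @param seed integer; fully determines the output.
#' @return list with elements `genotypes` ([GenotypeMatrix-class]) and
#'   `truth` ([SimulationTruth-class]).
#' @export
simulateGenotypes <- function(nSamples, blocks, teFraction = 0,
                              mafRange = c(0.1, 0.5), missingRate = 0,
                              qtl = NULL,
                              varianceComponents = c(sigmaG2 = 0,
                                                     sigmaGW2 = 0,
                                                     sigmaE2 = 1),
                              teR2Factor = 0.25, spacing = 1000,
                              chrom = "chr1", seed = 1) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) == 0) stop("blocks list is empty")
  if (any(blocks$n <= 0)) stop("block marker counts must be positive")
  if (any(blocks$r2 < 0 | blocks$r2 > 1))
    stop("within-block r2 must lie in [0, 1]")
  if (mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("mafRange must be a subset of (0, 0.5]")
  set.seed(seed)

  nb <- nrow(blocks)
  nTe <- round(teFraction * nb)
  teBlocks <- if (nTe > 0) sort(sample.int(nb, nTe)) else integer()

  mTotal <- sum(blocks$n)
  haps <- array(0L, dim = c(nSamples, 2, mTotal))
  pos <- integer(mTotal)
  blockMap <- integer(mTotal)
  col <- 0L
  cursor <- 0L
  teRegions <- data.frame(chrom = character(), start = integer(),
                          end = integer())
  ## marker-marker correlation after symmetric flipping at rate f of a
  ## latent Bernoulli(p) allele: r = (1-2f)^2 * p(1-p) / (q(1-q)) with
  ## q = p + f(1-2p); solve r^2 = target exactly (reduces to
  ## f = (1 - r2^(1/4))/2 at p = 0.5)
  flipRateFor <- function(r2, p) {
    if (r2 >= 1) return(0)
    if (r2 <= 0) return(0.5)
    rOf <- function(f) {
      q <- p + f * (1 - 2 * p)
      ((1 - 2 * f)^2 * p * (1 - p) / (q * (1 - q)))^2
    }
    stats::uniroot(function(f) rOf(f) - r2, c(0, 0.5), tol = 1e-12)$root
  }
  for (b in seq_len(nb)) {
    m <- blocks$n[b]
    r2 <- blocks$r2[b] * if (b %in% teBlocks) teR2Factor else 1
    p <- runif(1, mafRange[1], mafRange[2])
    f <- flipRateFor(r2, p)
    z <- matrix(rbinom(nSamples * 2, 1, p), nSamples, 2)
    idx <- col + seq_len(m)
    for (j in idx) {
      flip <- matrix(rbinom(nSamples * 2, 1, f), nSamples, 2)
      haps[, , j] <- ifelse(flip == 1, 1L - z, z)
    }
    step <- pmax(1L, as.integer(round(runif(m, 0.5, 1.5) * spacing)))
    pos[idx] <- cursor + cumsum(step)
    blockMap[idx] <- b
    if (b %in% teBlocks)
      teRegions <- rbind(teRegions,
                         data.frame(chrom = chrom, start = min(pos[idx]),
                                    end = max(pos[idx])))
    cursor <- max(pos[idx]) + 50000L
    col <- col + m
  }
  dos <- haps[, 1, ] + haps[, 2, ]
  dos <- matrix(as.numeric(dos), nSamples, mTotal)
  ids <- sprintf("SNP%05d", seq_len(mTotal))
  if (missingRate > 0) {
    nMiss <- round(missingRate * length(dos))
    dos[sample.int(length(dos), nMiss)] <- NA
  }
  markers <- data.frame(id = ids, chrom = chrom, pos = pos,
                        ref = "A", alt = "T",
                        stringsAsFactors = FALSE)
  G <- GenotypeMatrix(dos, markers)
  rownames(G@dosage) <- sprintf("S%04d", seq_len(nSamples))

  qtlMarkers <- data.frame(id = character(), effect = numeric())
  if (!is.null(qtl)) {
    if (any(qtl$marker < 1 | qtl$marker > mTotal))
      stop("QTL marker index outside the panel")
    qtlMarkers <- data.frame(id = ids[qtl$marker], effect = qtl$effect,
                             stringsAsFactors = FALSE)
  }
  truth <- new("SimulationTruth", qtlMarkers = qtlMarkers,
               varianceComponents = varianceComponents,
               moduleAssignment = character(),
               ldBlockMap = setNames(blockMap, ids),
               teRegions = teRegions, seed = as.integer(seed))
  list(genotypes = G, truth = truth)
}

#' Simulate phenotypes under the multi-environment mixed model
#'
#' Records follow
#' `y = mu + block + replicate + water + month + g + gw + e`, where the
#' genotypic value `g` is the planted QTL sum `sum(alpha * dosage)` plus a
#' polygenic residual `N(0, sigmaG2)`, `gw ~ N(0, sigmaGW2)` per
#' genotype-by-water-level cell and `e ~ N(0, sigmaE2)` per record.
#' Fixed-effect level values default to `N(0, 1)` draws (reproducible from
#' `seed`); missing QTL dosages are replaced by the marker mean.
#'
#' @param G [GenotypeMatrix-class]; rownames are the genotype ids.
#' @param truth [SimulationTruth-class] holding the QTLs and variance
#'   components.
#' @param design data.frame with one row per phenotypic record and columns
#'   `genotype`, `block`, `replicate`, `water`, `month`; every genotype must
#'   exist in `G`.
#' @param mu trait mean (cm).
#' @param fixedEffects optional named list (`block`, `replicate`, `water`,
#'   `month`) of named numeric level effects; unnamed levels default to 0.
#' @param seed integer RNG seed.
#' @return data.frame (`sample`, `genotype`, `block`, `replicate`, `water`,
#'   `month`, `value`): the phenotype table consumed by [fitMixedModel()].
#' @export
simulatePhenotypes <- function(G, truth, design, mu = 10,
                               fixedEffects = NULL, seed = 1) {
  stopifnot(is(G, "GenotypeMatrix"), is(truth, "SimulationTruth"))
  vc <- truth@varianceComponents
  if (any(vc < 0)) stop("variance components must be non-negative")
  ids <- rownames(G@dosage)
  if (!all(design$genotype %in% ids))
    stop("design contains genotypes absent from the panel")
  set.seed(seed)

  effFor <- function(fac) {
    lev <- sort(unique(as.character(design[[fac]])))
    if (!is.null(fixedEffects[[fac]])) {
      e <- setNames(rep(0, length(lev)), lev)
      e[names(fixedEffects[[fac]])] <- fixedEffects[[fac]]
      e
    } else setNames(rnorm(length(lev)), lev)
  }
  eb <- effFor("block"); er <- effFor("replicate")
  ew <- effFor("water"); em <- effFor("month")

  gQtl <- rep(0, length(ids))
  if (nrow(truth@qtlMarkers)) {
    for (k in seq_len(nrow(truth@qtlMarkers))) {
      d <- G@dosage[, truth@qtlMarkers$id[k]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      gQtl <- gQtl + truth@qtlMarkers$effect[k] * d
    }
  }
  g <- setNames(gQtl + rnorm(length(ids), 0, sqrt(vc[["sigmaG2"]])), ids)
  wLev <- sort(unique(as.character(design$water)))
  gw <- matrix(rnorm(length(ids) * length(wLev), 0, sqrt(vc[["sigmaGW2"]])),
               length(ids), length(wLev),
               dimnames = list(ids, wLev))
  eps <- rnorm(nrow(design), 0, sqrt(vc[["sigmaE2"]]))
  y <- mu + eb[as.character(design$block)] +
    er[as.character(design$replicate)] +
    ew[as.character(design$water)] + em[as.character(design$month)] +
    g[design$genotype] + gw[cbind(design$genotype,
                                  as.character(design$water))] + eps
  data.frame(sample = paste0(design$genotype, "_", seq_len(nrow(design))),
             genotype = design$genotype, block = design$block,
             replicate = design$replicate, water = design$water,
             month = design$month, value = as.numeric(y),
             stringsAsFactors = FALSE)
}

#' Simulate a modular expression matrix with annotation
#'
#' Counts follow a negative binomial (dispersion `dispersion`) with a
#' log-link on a Gaussian latent factor model: each planted module has an
#' eigengene profile over samples, and its member genes load on it with
#' `sqrt(corWithin)` so that latent within-module correlation equals
#' `corWithin` (log-CPM correlation is mildly attenuated by counting
#' noise). Each planted QTL's flanking gene is placed in a distinct module
#' adjacent to the QTL position; remaining genes are laid out sequentially
#' on a separate chromosome. A subset of genes receives GO terms and EC
#' numbers drawn from `ecPool`.
#'
#' @param G [GenotypeMatrix-class] (supplies QTL coordinates).
#' @param truth [SimulationTruth-class]; its QTLs seed the modules.
#' @param nModules number of planted modules.
#' @param moduleSizes integer vector of length `nModules`.
#' @param corWithin target latent within-module correlation in (0, 1).
#' @param nSamplesExpr number of expression samples.
#' @param nNoiseGenes additional unstructured genes.
#' @param nHousekeeping stable, highly expressed background genes (default
#'   `sum(moduleSizes)`): they anchor the library size so that CPM
#'   normalization does not strip the module signal, as the bulk of a
#'   real transcriptome does; labelled `"0"` like noise genes.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param signalSd latent log-scale signal standard deviation (default 1.5).
#' @param ecPool character vector of EC numbers used in annotation.
#' @param annotatedFraction fraction of genes given GO/EC terms.
#' @param seed integer RNG seed.
#' @return list: `counts` (genes x samples integer matrix), `annotation`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `product`,
#'   `GO`, `EC`), and `truth` with `moduleAssignment` filled in.
#' @export
simulateExpression <- function(G, truth, nModules, moduleSizes, corWithin,
                               nSamplesExpr, nNoiseGenes = 0,
                               nHousekeeping = sum(moduleSizes),
                               dispersion = 0.1, signalSd = 1.5,
                               ecPool = paste0("1.1.1.", 1:5),
                               annotatedFraction = 0.5, seed = 1) {
  stopifnot(is(truth, "SimulationTruth"))
  if (corWithin <= 0 || corWithin >= 1) stop("corWithin must be in (0, 1)")
  if (length(moduleSizes) != nModules)
    stop("moduleSizes must have length nModules")
  nGenes <- sum(moduleSizes) + nNoiseGenes + nHousekeeping
  set.seed(seed)

  moduleOf <- rep(c(seq_len(nModules), 0L, 0L),
                  c(moduleSizes, nNoiseGenes, nHousekeeping))
  hk <- seq_len(nHousekeeping) + sum(moduleSizes) + nNoiseGenes
  eigen <- matrix(rnorm(nModules * nSamplesExpr), nModules, nSamplesExpr)
  latent <- matrix(rnorm(nGenes * nSamplesExpr), nGenes, nSamplesExpr)
  for (m in seq_len(nModules)) {
    sel <- moduleOf == m
    latent[sel, ] <- sqrt(corWithin) *
      matrix(eigen[m, ], sum(sel), nSamplesExpr, byrow = TRUE) +
      sqrt(1 - corWithin) * latent[sel, ]
  }
  sdOf <- rep(signalSd, nGenes)
  sdOf[hk] <- 0.1  # housekeeping: nearly flat profiles
  logBase <- runif(nGenes, log(200), log(2000))
  logBase[hk] <- runif(length(hk), log(2000), log(10000))
  libFactor <- exp(rnorm(nSamplesExpr, 0, 0.2))
  mu <- exp(logBase + sdOf * latent) *
    matrix(libFactor, nGenes, nSamplesExpr, byrow = TRUE)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nGenes, nSamplesExpr)
  geneIds <- sprintf("GENE%05d", seq_len(nGenes))
  dimnames(counts) <- list(geneIds,
                           sprintf("E%03d", seq_len(nSamplesExpr)))

  ## annotation: QTL-flanking genes first, one per module (distinct modules)
  ann <- data.frame(gene_id = geneIds, chrom = "chrExpr",
                    start = 0L, end = 0L, strand = "+",
                    product = "hypothetical protein", GO = "", EC = "",
                    stringsAsFactors = FALSE)
  nQtl <- nrow(truth@qtlMarkers)
  if (nQtl > nModules)
    stop("need at least one module per planted QTL")
  if (nQtl > 0) {
    mk <- markerInfo(G)
    for (k in seq_len(nQtl)) {
      gi <- which(moduleOf == k)[1]  # first gene of module k flanks QTL k
      row <- mk[mk$id == truth@qtlMarkers$id[k], ]
      ann$chrom[gi] <- row$chrom
      ann$start[gi] <- row$pos + 200L
      ann$end[gi] <- row$pos + 1200L
    }
  }
  rest <- which(ann$chrom == "chrExpr")
  starts <- seq(1L, by = 2000L, length.out = length(rest))
  ann$start[rest] <- starts
  ann$end[rest] <- starts + 1500L
  ann$strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  annSel <- sample.int(nGenes, round(annotatedFraction * nGenes))
  ann$GO[annSel] <- sprintf("GO:%07d", sample.int(50, length(annSel),
                                                  replace = TRUE))
  ann$EC[annSel] <- sample(ecPool, length(annSel), replace = TRUE)

  truth@moduleAssignment <- setNames(as.character(moduleOf), geneIds)
  list(counts = counts, annotation = ann, truth = truth)
}

#' Currency (cofactor) compounds excluded from enzyme-graph edges
#'
#' Fixed list of ubiquitous cofactors; sharing only one of these never
#' creates an edge in [buildEnzymeNetwork()], since otherwise nearly every
#' enzyme pair would connect.
#' @return character vector of compound identifiers.
#' @export
currencyCompounds <- function() {
  c("ATP", "ADP", "NAD+", "NADH", "NADP+", "NADPH", "H2O", "H+",
    "CO2", "Pi", "PPi", "CoA", "O2")
}

#' Simulate a KEGG-like pathway flat file
#'
#' Each pathway is a chain of reactions (EC, substrates, products). With
#' probability `sharedCompoundRate` a reaction reuses the product of its
#' predecessor as a substrate, so the derived enzyme graph is connected
#' with positive probability; with probability `cofactorRate` a reaction
#' additionally carries a currency cofactor pair (see
#' [currencyCompounds()]), which must never create edges.
#'
#' @param nPathways number of pathways (> 0).
#' @param ecPool non-empty character vector of EC numbers to draw from.
#' @param sharedCompoundRate probability of chaining adjacent reactions
#'   through a shared compound.
#' @param reactionsPerPathway reactions per pathway (default 3).
#' @param cofactorRate probability a reaction carries currency cofactors.
#' @param seed integer RNG seed.
#' @return data.frame (`pathway_id`, `reaction_id`, `ec`, `substrates`,
#'   `products`), compound lists `;`-separated — the TSV dialect read by
#'   [readPathwayDb()].
#' @export
simulatePathwayDb <- function(nPathways, ecPool, sharedCompoundRate,
                              reactionsPerPathway = 3, cofactorRate = 0.2,
                              seed = 1) {
  if (length(ecPool) == 0) stop("ecPool must be non-empty")
  set.seed(seed)
  rows <- list()
  cmpd <- function() sprintf("C%05d", sample.int(99999, 1))
  for (p in seq_len(nPathways)) {
    prevProduct <- NULL
    for (r in seq_len(reactionsPerPathway)) {
      subs <- cmpd()
      if (!is.null(prevProduct) && runif(1) < sharedCompoundRate)
        subs <- prevProduct
      prod <- cmpd()
      if (runif(1) < cofactorRate) {
        cof <- sample(currencyCompounds(), 2)
        subs <- paste(c(subs, cof[1]), collapse = ";")
        prod <- paste(c(prod, cof[2]), collapse = ";")
      }
      rows[[length(rows) + 1]] <- data.frame(
        pathway_id = sprintf("PWY%03d", p),
        reaction_id = sprintf("PWY%03d_R%02d", p, r),
        ec = sample(ecPool, 1), substrates = subs, products = prod,
        stringsAsFactors = FALSE)
      prevProduct <- strsplit(prod, ";", fixed = TRUE)[[1]][1]
    }
  }
  do.call(rbind, rows)
}
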