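#' @import methods
#' @importFrom stats var cor quantile rnorm rbinom runif setNames median
#'   complete.cases prcomp pchisq pt coef lm resid sd rnbinom aggregate
#' @importFrom utils read.delim write.table head
NULL

#' GenotypeMatrix: samples-by-markers dosage panel
#'
#' Holds a biallelic SNP panel as an integer dosage matrix (counts of the
#' alternate allele, 0/1/2, `NA` for missing) together with marker metadata
#' (chromosome, 1-based position, ref/alt alleles). Positions must be
#' strictly increasing within each chromosome.
#'
#' @slot dosage numeric matrix, samples in rows, markers in columns; values
#'   in \{0, 1, 2, NA\}.
#' @slot markers data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per dosage column.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", markers = "data.frame"),
  validity = function(object) {
    msg <- character()
    mk <- object@markers
    if (ncol(object@dosage) != nrow(mk))
      msg <- c(msg, "dosage columns and marker rows differ")
    need <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(mk)))
      msg <- c(msg, paste("markers lacks columns:",
                          paste(setdiff(need, names(mk)), collapse = ", ")))
    d <- object@dosage
    ok <- is.na(d) | d %in% c(0, 1, 2)
    if (!all(ok)) msg <- c(msg, "dosage values outside {0,1,2,NA}")
    if (all(need %in% names(mk)) && nrow(mk) > 1) {
      for (ch in unique(mk$chrom)) {
        p <- mk$pos[mk$chrom == ch]
        if (any(diff(p) <= 0)) {
          msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x markers matrix of alt-allele dosages (0/1/2/NA).
#' @param markers data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, markers) {
  dosage <- as.matrix(dosage)
  if (!is.null(markers$id)) colnames(dosage) <- markers$id
  markers$chrom <- as.character(markers$chrom)
  new("GenotypeMatrix", dosage = dosage, markers = markers)
}

#' SimulationTruth: ground truth of a synthetic dataset
#'
#' @slot qtlMarkers data.frame (`id`, `effect`): planted additive QTLs, the
#'   effect is per copy of the alternate allele, in trait units.
#' @slot varianceComponents named numeric: `sigmaG2`, `sigmaGW2`, `sigmaE2`
#'   (trait units squared).
#' @slot moduleAssignment named character: gene id -> planted module label.
#' @slot ldBlockMap named integer: marker id -> LD block id.
#' @slot teRegions data.frame (`chrom`, `start`, `end`): low-LD TE-dense
#'   intervals.
#' @slot seed integer seed that fully determines the outputs.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(qtlMarkers = "data.frame", varianceComponents = "numeric",
                 moduleAssignment = "character", ldBlockMap = "integer",
                 teRegions = "data.frame", seed = "integer"))

#' VarianceComponents: REML fit of the growth-trait mixed model
#'
#' @slot sigmaG2,sigmaGW2,sigmaE2 variance components for genotype,
#'   genotype-by-water-level interaction and residual, in trait units squared.
#' @slot mu estimated intercept (trait units).
#' @slot blups named numeric, genotype BLUPs (sum to ~0).
#' @slot gwBlups data.frame (`genotype`, `water`, `blup`).
#' @slot logLik REML log-likelihood at convergence.
#' @slot converged logical convergence flag (non-convergence is flagged,
#'   never silent).
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigmaG2 = "numeric", sigmaGW2 = "numeric",
                 sigmaE2 = "numeric", mu = "numeric", blups = "numeric",
                 gwBlups = "data.frame", logLik = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (any(c(object@sigmaG2, object@sigmaGW2, object@sigmaE2) < 0))
      "variance components must be non-negative" else TRUE
  })

#' LdDecayFit: exponential LD decay curve y = a + b * exp(-c * x)
#'
#' `a + b` is the expected r-squared at distance zero; `c` (per bp) controls
#' the decay rate.
#'
#' @slot a,b r-squared units; @slot c per-bp decay rate (>= 0);
#' @slot sse residual sum of squares of the fit.
#' @exportClass LdDecayFit
setClass("LdDecayFit",
  representation(a = "numeric", b = "numeric", c = "numeric", sse = "numeric"),
  validity = function(object)
    if (object@c < 0) "decay rate c must be >= 0" else TRUE)

#' AssociationResult: per-marker association scan output
#'
#' @slot table data.frame with one row per tested marker: `marker`, `chrom`,
#'   `pos`, `p`, `effect` (trait units per alt allele), `maf`, and after
#'   [snpStatistics()] also `va` (2p(1-p)a^2) and `pve`.
#' @slot covariates character description of the covariates used.
#' @slot pseudoQTNs character, marker ids used as pseudo-QTN covariates in
#'   the final iteration.
#' @slot threshold numeric p-value significance threshold (NA until set).
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(table = "data.frame", covariates = "character",
                 pseudoQTNs = "character", threshold = "numeric"))

#' MarkerSets: significant markers and their LD expansion
#'
#' @slot snpsGWAS marker ids below the significance threshold.
#' @slot snpsLD marker ids linked at r^2 >= the cutoff to >= 1 snpGWAS
#'   (excluding the snpsGWAS themselves).
#' @slot ldEdges data.frame (`markerA`, `markerB`, `r2`) of qualifying pairs.
#' @exportClass MarkerSets
setClass("MarkerSets",
  representation(snpsGWAS = "character", snpsLD = "character",
                 ldEdges = "data.frame"))

#' ExpressionMatrix: filtered, normalized expression
#'
#' @slot counts raw gene x sample counts of the retained genes.
#' @slot libSizes column sums of the *full* raw count matrix.
#' @slot logCPM quantile-normalized log2(CPM + 1) matrix of retained genes.
#' @slot removed character, gene ids dropped by the CPM filter.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(counts = "matrix", libSizes = "numeric", logCPM = "matrix",
                 removed = "character"))

#' CoexpressionModel: soft threshold, TOM and module partition
#'
#' @slot beta soft-threshold power actually used.
#' @slot fitTable per-candidate-power scale-free fit table (`power`, `sft.R2`,
#'   `mean.k`).
#' @slot scaleFreeR2 signed scale-free topology fit at `beta`.
#' @slot tom topological overlap matrix (symmetric, unit diagonal).
#' @slot modules named character: gene -> module label, `"0"` = unassigned.
#' @slot mergeHeights UPGMA dendrogram merge heights.
#' @exportClass CoexpressionModel
setClass("CoexpressionModel",
  representation(beta = "numeric", fitTable = "data.frame",
                 scaleFreeR2 = "numeric", tom = "matrix",
                 modules = "character", mergeHeights = "numeric"))

#' SeededSubnetwork: GWAS-seeded coexpression subnetwork with hub scores
#'
#' @slot graph undirected igraph; edges carry the signed Pearson `r` as
#'   `weight` sign-carrier and `absr` as |r|.
#' @slot hubScores named numeric in [0, 1], max exactly 1 (Kleinberg HITS
#'   hub scores on the |r|-weighted adjacency).
#' @slot seedGenes,extraGenes character: GWAS-assigned genes and snpsLD genes.
#' @exportClass SeededSubnetwork
setClass("SeededSubnetwork",
  representation(graph = "ANY", hubScores = "numeric",
                 seedGenes = "character", extraGenes = "character"))

#' EnzymeNetwork: EC-node metabolic graph
#'
#' @slot graph directed igraph, nodes = EC numbers, edge a->b when a product
#'   compound of a reaction of a is a substrate of a reaction of b within a
#'   retrieved pathway (currency compounds excluded).
#' @slot simple the underlying undirected simple graph (no self-loops,
#'   no multi-edges).
#' @slot nodes data.frame (`ec`, `pathways`, `genes`, `query`): provenance.
#' @exportClass EnzymeNetwork
setClass("EnzymeNetwork",
  representation(graph = "ANY", simple = "ANY", nodes = "data.frame"))

#' TopologyReport: per-node and graph-level topology measures
#'
#' @slot nodeTable per node: `node`, `degree.in`, `degree.out`, `degree`,
#'   `betweenness` (normalized to [0,1]), `stress` (integer path counts),
#'   `eccentricity`, `avg.path.length`, `neighborhood.connectivity`.
#' @slot graphStats list: `n.nodes`, `n.edges`, `mean.neighbors`
#'   (2E/N on the simple graph), `mean.degree.directed`, `diameter`.
#' @exportClass TopologyReport
setClass("TopologyReport",
  representation(nodeTable = "data.frame", graphStats = "list"))

#' CommunityHierarchy: persistent multi-resolution communities
#'
#' @slot table data.frame per reported community: `label`, `size`,
#'   `res.min`, `res.max`, `persistence`.
#' @slot members list of character vectors, node sets per community label.
#' @slot containment data.frame (`parent`, `child`) containment edges across
#'   resolution levels (child fully inside parent, parent from a coarser
#'   resolution).
#' @exportClass CommunityHierarchy
setClass("CommunityHierarchy",
  representation(table = "data.frame", members = "list",
                 containment = "data.frame"))

## ---- show methods -------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypeMatrix: %d samples x %d markers (%d chromosome%s)\n",
              nrow(d), ncol(d), length(unique(object@markers$chrom)),
              if (length(unique(object@markers$chrom)) == 1) "" else "s"))
  miss <- mean(is.na(d))
  cat(sprintf("  missing rate: %.2f%%\n", 100 * miss))
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (REML)\n")
  cat(sprintf("  sigmaG2 = %.4g  sigmaGW2 = %.4g  sigmaE2 = %.4g\n",
              object@sigmaG2, object@sigmaGW2, object@sigmaE2))
  cat(sprintf("  mu = %.4g, %d genotype BLUPs, logLik = %.4f%s\n",
              object@mu, length(object@blups), object@logLik,
              if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "LdDecayFit", function(object)
  cat(sprintf("LdDecayFit: r2(x) = %.4g + %.4g * exp(-%.4g * x), SSE = %.4g\n",
              object@a, object@b, object@c, object@sse)))

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d markers scanned", nrow(object@table)))
  if (!is.na(object@threshold))
    cat(sprintf(", threshold p <= %.3g (%d significant)", object@threshold,
                sum(object@table$p <= object@threshold, na.rm = TRUE)))
  cat("\n  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

setMethod("show", "MarkerSets", function(object)
  cat(sprintf("MarkerSets: %d snpsGWAS, %d snpsLD, %d LD edges\n",
              length(object@snpsGWAS), length(object@snpsLD),
              nrow(object@ldEdges))))

setMethod("show", "ExpressionMatrix", function(object)
  cat(sprintf(paste0("ExpressionMatrix: %d genes x %d samples retained ",
                     "(%d removed by CPM filter)\n"),
              nrow(object@logCPM), ncol(object@logCPM),
              length(object@removed))))

setMethod("show", "CoexpressionModel", function(object) {
  tab <- table(object@modules[object@modules != "0"])
  cat(sprintf(paste0("CoexpressionModel: beta = %d (scale-free R2 = %.3f), ",
                     "%d genes, %d modules (%d unassigned)\n"),
              object@beta, object@scaleFreeR2, length(object@modules),
              length(tab), sum(object@modules == "0")))
})

setMethod("show", "EnzymeNetwork", function(object)
  cat(sprintf("EnzymeNetwork: %d EC nodes, %d directed edges (%d simple)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              igraph::ecount(object@simple))))

setMethod("show", "CommunityHierarchy", function(object)
  cat(sprintf("CommunityHierarchy: %d persistent communities, sizes %s\n",
              nrow(object@table),
              if (nrow(object@table)) paste0(min(object@table$size), "-",
                                             max(object@table$size)) else "-")))

## ---- accessors ----------------------------------------------------------

#' Accessors for pipeline objects
#'
#' `dosage()` and `markerInfo()` expose the dosage matrix and marker
#' metadata of a [GenotypeMatrix-class]; `blups()` the genotype BLUP vector
#' of a [VarianceComponents-class]; `assocTable()` the per-marker table of an
#' [AssociationResult-class]; `moduleLabels()` the module partition of a
#' [CoexpressionModel-class]; `hubScores()` the HITS hub scores of a
#' [SeededSubnetwork-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("blups", function(x) standardGeneric("blups"))
#' @rdname accessors
#' @export
setMethod("blups", "VarianceComponents", function(x) x@blups)

#' @rdname accessors
#' @export
setGeneric("assocTable", function(x) standardGeneric("assocTable"))
#' @rdname accessors
#' @export
setMethod("assocTable", "AssociationResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setMethod("moduleLabels", "CoexpressionModel", function(x) x@modules)

#' @rdname accessors
#' @export
setGeneric("hubScores", function(x) standardGeneric("hubScores"))
#' @rdname accessors
#' @export
setMethod("hubScores", "SeededSubnetwork", function(x) x@hubScores)
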