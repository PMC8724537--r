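## WGCNA-style coexpression: CPM filtering + quantile normalization, soft
## threshold by scale-free topology fit, topological overlap, UPGMA with
## an adaptive (variable-height) branch cut, GWAS-seeded module selection
## and Kleinberg HITS hub scoring of the seeded subnetwork.

#' Filter and normalize an expression count matrix
#'
#' Computes counts per million (CPM), retains genes whose mean CPM (or,
#' with `rule = "any"`, CPM in at least one sample) is at least `minCpm`,
#' log2(CPM + 1)-transforms, then quantile-normalizes (see
#' [quantileNormalize()]) so every sample column has an identical
#' distribution.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param minCpm CPM retention threshold (default 10).
#' @param rule `"mean"` (default) or `"any"` sample rule for retention.
#' @return An [ExpressionMatrix-class] object.
#' @export
preprocessCounts <- function(counts, minCpm = 10,
                             rule = c("mean", "any")) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- if (rule == "mean") rowMeans(cpm) >= minCpm
          else apply(cpm, 1, max) >= minCpm
  logcpm <- log2(cpm[keep, , drop = FALSE] + 1)
  norm <- quantileNormalize(logcpm)
  new("ExpressionMatrix", counts = counts[keep, , drop = FALSE],
      libSizes = lib, logCPM = norm,
      removed = rownames(counts)[!keep] %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile normalization with stable tie handling
#'
#' Replaces each column by the mean sorted profile at the column's ranks,
#' ties broken by row order (`ties.method = "first"`). All columns end up
#' with identical sorted values, and the transform is exactly idempotent.
#'
#' @param x numeric matrix (features x samples).
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(x) {
  meanSorted <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col)
    meanSorted[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(x)
  out
}

.exprMatrix <- function(X) {
  if (is(X, "ExpressionMatrix")) X@logCPM else as.matrix(X)
}

## HITS hub scores of a symmetric non-negative adjacency, normalized to
## max 1: the Perron (principal) eigenvector of A, which equals the
## principal eigenvector of A'A whenever that eigenvalue is simple. On
## bipartite subgraphs (a star, say) A'A has a degenerate top eigenspace
## and eigensolvers return an arbitrary vector from it; the shifted power
## iteration on A + cI (c = max row sum) removes the +/- degeneracy and
## converges to the non-negative hub vector. Invariant to uniform
## edge-weight scaling.
.hitsHub <- function(A, tol = 1e-14, maxIter = 100000) {
  cc <- max(rowSums(A))
  if (cc <= 0) return(setNames(rep(0, nrow(A)), rownames(A)))
  h <- rep(1, nrow(A))
  for (i in seq_len(maxIter)) {
    h2 <- as.numeric(A %*% h) + cc * h
    h2 <- h2 / max(h2)
    if (max(abs(h2 - h)) < tol) { h <- h2; break }
    h <- h2
  }
  setNames(h, rownames(A))
}

.geneCor <- function(X) {
  if (any(apply(X, 1, stats::sd) == 0))
    stop("constant gene row(s): remove before correlation")
  cor(t(X), use = "pairwise.complete.obs")
}

## R2 of the log10 p(k) ~ log10 k regression, sign-flipped when the slope
## is positive (a scale-free network must have a falling degree law).
.scaleFreeFit <- function(k, nBreaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  cuts <- cut(k, nBreaks)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  if (sum(ok) < 2) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2] > 0) -r2 else r2
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' the connectivity distribution is regressed as `log10 p(k)` on
#' `log10 k`, and the signed fit R2 recorded. Returns the smallest power
#' reaching `targetR2`; if none does, the power of maximal fit is returned
#' with a warning.
#'
#' @param X [ExpressionMatrix-class] or normalized gene x sample matrix
#'   (>= 30 genes).
#' @param powers candidate integer powers (default 1:20).
#' @param targetR2 scale-free fit target (default 0.85).
#' @param nBreaks connectivity histogram bins for the fit (default 10).
#' @return list: `beta`, `fitTable` (`power`, `sft.R2`, `mean.k`),
#'   `scaleFreeR2` at the chosen power.
#' @export
pickSoftThreshold <- function(X, powers = 1:20, targetR2 = 0.85,
                              nBreaks = 10) {
  X <- .exprMatrix(X)
  if (nrow(X) < 30) stop("need >= 30 genes for a meaningful fit")
  r <- abs(.geneCor(X))
  diag(r) <- 0
  fitTable <- data.frame(power = powers, sft.R2 = NA_real_,
                         mean.k = NA_real_)
  for (i in seq_along(powers)) {
    a <- r^powers[i]
    k <- rowSums(a)
    fitTable$sft.R2[i] <- .scaleFreeFit(k, nBreaks)
    fitTable$mean.k[i] <- mean(k)
  }
  hit <- which(fitTable$sft.R2 >= targetR2)
  if (length(hit)) beta <- powers[hit[1]]
  else {
    beta <- powers[which.max(fitTable$sft.R2)]
    warning(sprintf(
      "no power reaches scale-free fit R2 >= %.2f; using argmax power %d",
      targetR2, beta))
  }
  list(beta = beta, fitTable = fitTable,
       scaleFreeR2 = fitTable$sft.R2[match(beta, powers)])
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor|^beta` with zero diagonal;
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; unit diagonal. Dissimilarity is `1 - TOM`.
#'
#' @param X [ExpressionMatrix-class] or normalized gene x sample matrix.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric TOM matrix with entries in [0, 1].
#' @export
tomMatrix <- function(X, beta) {
  if (beta < 1) stop("beta must be >= 1")
  X <- .exprMatrix(X)
  a <- abs(.geneCor(X))^beta
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  minK <- outer(k, k, pmin)
  tom <- (l + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(X), rownames(X))
  tom
}

#' Cut a TOM dendrogram into modules (adaptive variable-height cut)
#'
#' UPGMA (average-linkage) clustering of the dissimilarity, then a
#' recursive cohesion-based branch cut: a branch becomes a module when a
#' large cohesive core remains after pruning stragglers — members
#' farthest from the rest are pruned until the mean within-branch
#' dissimilarity falls below `coreScatterFrac` times the mean overall
#' dissimilarity (pruning at most 15% of the branch), after which
#' individual members still far from the core are pruned. The core counts
#' only if it keeps `minModuleSize` genes. Branches with no such core are
#' split at their top merge and the rule recurses, so modules can be read
#' off at different heights of the tree. Genes in no qualifying branch
#' are labelled `"0"` (unassigned).
#'
#' @param diss square dissimilarity matrix (1 - TOM).
#' @param minModuleSize minimum module size (default 30).
#' @param coreScatterFrac cohesion fraction (default 0.75).
#' @return list: `modules` (named character, `"0"` = unassigned) and
#'   `mergeHeights` (UPGMA merge heights).
#' @export
cutModules <- function(diss, minModuleSize = 30, coreScatterFrac = 0.75) {
  diss <- as.matrix(diss)
  n <- nrow(diss)
  genes <- rownames(diss) %||% as.character(seq_len(n))
  if (n < minModuleSize) {
    warning("fewer genes than minModuleSize: everything unassigned")
    return(list(modules = setNames(rep("0", n), genes),
                mergeHeights = numeric()))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  overall <- mean(diss[upper.tri(diss)])
  thresh <- coreScatterFrac * overall
  labels <- setNames(rep("0", n), genes)
  nextLab <- 0L

  leavesOf <- function(node) {
    ## node: negative = leaf index, positive = merge row
    if (node < 0) return(-node)
    c(leavesOf(hc$merge[node, 1]), leavesOf(hc$merge[node, 2]))
  }
  ## iteratively prune the member farthest from the rest until the branch
  ## is cohesive; fail when that would discard most of the branch (a
  ## branch that is really several modules, or noise, has no large core)
  trimToCore <- function(mem) {
    minKeep <- max(minModuleSize, ceiling(0.85 * length(mem)))
    S <- rowSums(diss[mem, mem, drop = FALSE])   # updated incrementally
    total <- sum(S) / 2
    dropWorst <- function() {
      i <- which.max(S)
      total <<- total - S[i]
      S <<- (S - diss[mem, mem[i]])[-i]
      mem <<- mem[-i]
    }
    ## phase 1: overall cohesion, pruning at most 15% of the branch
    repeat {
      m <- length(mem)
      if (total / (m * (m - 1) / 2) < thresh) break
      if (m - 1 < minKeep) return(NULL)
      dropWorst()
    }
    ## phase 2: prune individual stragglers still far from the core
    while (length(mem) > minModuleSize &&
           max(S) / (length(mem) - 1) > thresh)
      dropWorst()
    if (length(mem) >= minModuleSize) mem else NULL
  }
  walk <- function(node) {
    mem <- leavesOf(node)
    if (length(mem) < minModuleSize) return(invisible())
    core <- trimToCore(mem)
    if (!is.null(core)) {
      nextLab <<- nextLab + 1L
      labels[genes[core]] <<- as.character(nextLab)
      return(invisible())
    }
    if (node > 0) {
      walk(hc$merge[node, 1])
      walk(hc$merge[node, 2])
    }
    invisible()
  }
  walk(n - 1L)  # root merge row
  list(modules = labels, mergeHeights = hc$height)
}

#' Build a full coexpression model
#'
#' Convenience wrapper: soft threshold (unless `beta` is given), TOM and
#' module cut in one call.
#'
#' @param X [ExpressionMatrix-class] or normalized matrix.
#' @param beta optional fixed power; otherwise chosen by
#'   [pickSoftThreshold()].
#' @param minModuleSize,coreScatterFrac passed to [cutModules()].
#' @param ... passed to [pickSoftThreshold()].
#' @return A [CoexpressionModel-class] object.
#' @export
coexpressionModel <- function(X, beta = NULL, minModuleSize = 30,
                              coreScatterFrac = 0.75, ...) {
  if (is.null(beta)) {
    sft <- pickSoftThreshold(X, ...)
    beta <- sft$beta
    fitTable <- sft$fitTable
    r2 <- sft$scaleFreeR2
  } else {
    fitTable <- data.frame(power = beta, sft.R2 = NA_real_,
                           mean.k = NA_real_)
    r2 <- NA_real_
  }
  tom <- tomMatrix(X, beta)
  cm <- cutModules(1 - tom, minModuleSize, coreScatterFrac)
  new("CoexpressionModel", beta = as.numeric(beta), fitTable = fitTable,
      scaleFreeR2 = r2, tom = tom, modules = cm$modules,
      mergeHeights = cm$mergeHeights)
}

#' Select the modules containing GWAS-assigned seed genes
#'
#' @param modules named character partition (gene -> label, `"0"` =
#'   unassigned), e.g. [moduleLabels()] of a [CoexpressionModel-class].
#' @param seedGenes character vector of GWAS-assigned gene ids.
#' @return character vector of selected module labels (possibly empty,
#'   with a warning); seeds absent from the partition are reported in a
#'   message.
#' @export
selectSeededModules <- function(modules, seedGenes) {
  absent <- setdiff(seedGenes, names(modules))
  if (length(absent))
    message("seed gene(s) absent from expression: ",
            paste(absent, collapse = ", "))
  present <- intersect(seedGenes, names(modules))
  sel <- setdiff(unique(modules[present]), "0")
  if (length(sel) == 0) warning("no seed gene falls in any module")
  sort(sel)
}

#' Build the GWAS-seeded coexpression subnetwork with HITS hub scores
#'
#' Nodes are the union of the seed genes, the snpsLD-associated genes and
#' every gene of a selected module. Edges connect node pairs with
#' `|Pearson r| >= minAbsR` (pairwise-complete observations; pairs with
#' fewer than 3 shared samples never form an edge), carrying the signed
#' `r` as attribute `r` and `|r|` as `weight`. Hub scores are the
#' Kleinberg HITS hub vector of the `|r|`-weighted adjacency (hub =
#' authority on an undirected graph), normalized to a maximum of 1.
#'
#' @param X [ExpressionMatrix-class] or normalized gene x sample matrix.
#' @param modules named character partition of the genes of `X`.
#' @param selected module labels to include (from
#'   [selectSeededModules()]).
#' @param seedGenes,extraGenes GWAS-assigned genes and snpsLD genes; node
#'   candidates absent from `X` are dropped with a warning.
#' @param minAbsR edge threshold on |r| (default 0.5).
#' @return A [SeededSubnetwork-class] object.
#' @export
buildSeededSubnetwork <- function(X, modules, selected,
                                  seedGenes = character(),
                                  extraGenes = character(),
                                  minAbsR = 0.5) {
  X <- .exprMatrix(X)
  nodes <- union(union(seedGenes, extraGenes),
                 names(modules)[modules %in% selected])
  absent <- setdiff(nodes, rownames(X))
  if (length(absent)) {
    warning("node(s) absent from expression dropped: ",
            paste(absent, collapse = ", "))
    nodes <- intersect(nodes, rownames(X))
  }
  if (length(nodes) == 0) stop("empty node set")
  sub <- X[nodes, , drop = FALSE]
  r <- cor(t(sub), use = "pairwise.complete.obs")
  shared <- crossprod(t(!is.na(sub)) * 1)  # shared sample counts
  r[shared < 3] <- 0
  diag(r) <- 0
  adj <- which(abs(r) >= minAbsR & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(from = nodes[adj[, 1]], to = nodes[adj[, 2]],
                      r = r[adj], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  scores <- setNames(rep(0, length(nodes)), nodes)
  if (nrow(edges)) {
    igraph::E(g)$weight <- abs(edges$r)
    igraph::E(g)$r <- edges$r
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    scores[rownames(A)] <- .hitsHub(A)
  }
  new("SeededSubnetwork", graph = g, hubScores = scores,
      seedGenes = as.character(seedGenes),
      extraGenes = as.character(extraGenes))
}

#' Top hub genes of a seeded subnetwork
#'
#' @param subnet [SeededSubnetwork-class].
#' @param k number of hubs to report (default 10).
#' @return data.frame (`gene`, `hub.score`, `degree`), sorted by score.
#' @export
topHubs <- function(subnet, k = 10) {
  sc <- sort(subnet@hubScores, decreasing = TRUE)
  sc <- sc[seq_len(min(k, length(sc)))]
  data.frame(gene = names(sc), hub.score = unname(sc),
             degree = unname(igraph::degree(subnet@graph)[names(sc)]),
             stringsAsFactors = FALSE)
}
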