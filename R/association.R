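## FarmCPU-style association mapping on BLUPs. The scan alternates a
## fixed-effect step (per-marker OLS with intercept, principal components
## and the current pseudo-QTNs as covariates) with a random-effect step
## that re-selects pseudo-QTNs from genome bins by the REML likelihood of
## the phenotype under a pseudo-QTN kinship, iterating until the
## pseudo-QTN set is stable. Significance comes from a permutation
## threshold; signals are expanded genome-wide through LD.

## Fast per-marker OLS after projecting covariates out of y and dosages.
## Returns effect, t and p per column of d; columns collinear with C get
## p = 1 and effect NA (a marker identical to a covariate/pseudo-QTN is
## excluded from its own test).
.fixedScan <- function(d, y, C) {
  n <- length(y)
  qrC <- qr(C)
  My <- qr.resid(qrC, y)
  Md <- qr.resid(qrC, d)
  num <- colSums(Md * My)
  den <- colSums(Md^2)
  df <- n - qrC$rank - 1
  if (df < 1) stop("more covariates and pseudo-QTNs than samples")
  beta <- num / den
  rss <- sum(My^2) - beta^2 * den
  se <- sqrt(pmax(rss, 0) / df / den)
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  aliased <- den < 1e-8 * n
  p[aliased] <- 1
  beta[aliased] <- NA_real_
  list(effect = beta, p = p)
}

## EMMA-style REML log-likelihood of y ~ X fixed + u, u ~ N(0, K sigmaU2),
## maximized over the variance ratio. Used to score pseudo-QTN sets.
.remlLoglikKinship <- function(y, X, K) {
  n <- length(y)
  q <- qr(X)$rank
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  ev <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- ev$values[seq_len(n - q)]
  xi[xi < 1e-10] <- 1e-10
  eta <- crossprod(ev$vectors[, seq_len(n - q), drop = FALSE], y)[, 1]
  ll <- function(logDelta) {
    delta <- exp(logDelta)
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 -
                        log(sum(eta^2 / (xi + delta)))) -
             sum(log(xi + delta)))
  }
  grid <- seq(log(1e-5), log(1e5), length.out = 20)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE)
  max(opt$objective, vals[i])
}

.vanRaden <- function(d) {
  p <- colMeans(d) / 2
  W <- sweep(d, 2, 2 * p)
  den <- 2 * sum(p * (1 - p))
  if (den <= 0) return(NULL)
  W %*% t(W) / den
}

#' Iterative pseudo-QTN (FarmCPU-style) association scan
#'
#' Each iteration tests every marker by OLS of the phenotype on
#' `[intercept, PCs, pseudo-QTNs, marker]` (fixed-effect step), then
#' re-selects pseudo-QTNs (random-effect step): the best marker per genome
#' bin among those with `p <= entryP`, with the bin size and pseudo-QTN
#' count chosen from grids by the REML likelihood of the phenotype under
#' the pseudo-QTN VanRaden kinship. Iteration stops when the pseudo-QTN
#' set is stable or after `maxIter` rounds. Markers in the final
#' pseudo-QTN set are re-tested with themselves removed from the
#' covariates; a marker collinear with the remaining covariates is
#' excluded from its own test and reported with p = 1. Monomorphic
#' markers are excluded with a warning.
#'
#' @param G imputed [GenotypeMatrix-class].
#' @param y named numeric of genotype BLUPs (names = sample ids of `G`).
#' @param covariates list with `scores` (samples x PCs matrix; may have 0
#'   columns) as produced by [populationStructure()]; the kinship enters
#'   only through pseudo-QTN selection.
#' @param maxIter maximum pseudo-QTN iterations (default 10).
#' @param binSizes bin-size grid in bp (default `c(5e5, 5e6, 5e7)`).
#' @param qtnCounts pseudo-QTN count grid (default `c(5, 10, 15)`).
#' @param entryP maximum p-value from the previous fixed-effect step for a
#'   marker to be eligible as a pseudo-QTN (default 0.01).
#' @param stopP first-iteration stopping threshold: when no marker of the
#'   initial scan reaches `stopP`, the procedure returns that scan without
#'   selecting pseudo-QTNs (default `0.01 / m`, the published method's
#'   default, which keeps the procedure's null behaviour at the
#'   single-scan level).
#' @return An [AssociationResult-class] object.
#' @export
farmcpuScan <- function(G, y, covariates, maxIter = 10,
                        binSizes = c(5e5, 5e6, 5e7),
                        qtnCounts = c(5, 10, 15), entryP = 0.01,
                        stopP = NULL) {
  d <- dosage(G)
  if (anyNA(d)) stop("impute the panel before the association scan")
  if (!is.null(names(y))) {
    if (!all(rownames(d) %in% names(y)))
      stop("samples of G and y are not aligned")
    y <- y[rownames(d)]
  }
  mk <- markerInfo(G)
  mono <- apply(d, 2, function(x) stats::sd(x) == 0)
  if (any(mono)) {
    warning(sprintf("%d monomorphic marker(s) excluded", sum(mono)))
    d <- d[, !mono, drop = FALSE]
    mk <- mk[!mono, , drop = FALSE]
  }
  scores <- covariates$scores
  if (is.null(scores)) scores <- matrix(0, length(y), 0)
  Cbase <- cbind(`(Intercept)` = 1, scores)

  if (is.null(stopP)) stopP <- 0.01 / ncol(d)
  pseudo <- character()
  scan <- NULL
  for (iter in seq_len(maxIter)) {
    C <- cbind(Cbase, d[, pseudo, drop = FALSE])
    if (ncol(C) + 1 >= length(y))
      stop("more covariates and pseudo-QTNs than samples")
    scan <- .fixedScan(d, y, C)
    if (iter == 1 && min(scan$p, na.rm = TRUE) > stopP) break
    ## candidate pseudo-QTNs: best marker per bin among p <= entryP
    elig <- which(scan$p <= entryP & !is.na(scan$p))
    if (length(elig) == 0) { pseudo <- character(); break }
    bestSet <- NULL; bestLL <- -Inf
    for (bs in binSizes) {
      ord <- elig[order(scan$p[elig])]
      binOrd <- paste0(mk$chrom, ":", mk$pos %/% bs)[ord]
      perBin <- ord[!duplicated(binOrd)]        # best marker per bin
      for (t in qtnCounts) {
        set <- perBin[seq_len(min(t, length(perBin)))]
        K <- .vanRaden(d[, set, drop = FALSE])
        if (is.null(K)) next
        ll <- tryCatch(.remlLoglikKinship(y, Cbase, K),
                       error = function(e) -Inf)
        if (ll > bestLL) { bestLL <- ll; bestSet <- set }
      }
    }
    newPseudo <- mk$id[sort(bestSet)]
    ## drop later-entering collinear pseudo-QTNs
    if (length(newPseudo) > 1) {
      Cp <- cbind(Cbase, d[, newPseudo, drop = FALSE])
      qrp <- qr(Cp)
      if (qrp$rank < ncol(Cp)) {
        bad <- qrp$pivot[(qrp$rank + 1):ncol(Cp)]
        bad <- bad[bad > ncol(Cbase)] - ncol(Cbase)
        if (length(bad)) newPseudo <- newPseudo[-bad]
      }
    }
    if (setequal(newPseudo, pseudo)) { pseudo <- newPseudo; break }
    pseudo <- newPseudo
  }
  ## final fixed-effect step
  C <- cbind(Cbase, d[, pseudo, drop = FALSE])
  scan <- .fixedScan(d, y, C)
  ## pseudo-QTN markers: re-test leaving themselves out of the covariates
  for (q in pseudo) {
    Cq <- cbind(Cbase, d[, setdiff(pseudo, q), drop = FALSE])
    res <- .fixedScan(d[, q, drop = FALSE], y, Cq)
    j <- match(q, mk$id)
    scan$p[j] <- res$p
    scan$effect[j] <- res$effect
  }
  maf <- apply(d, 2, .mafOf)
  new("AssociationResult",
      table = data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                         p = scan$p, effect = scan$effect, maf = maf,
                         stringsAsFactors = FALSE),
      covariates = c("intercept",
                     if (ncol(scores)) paste0("PC", seq_len(ncol(scores)))),
      pseudoQTNs = pseudo, threshold = NA_real_)
}

#' Permutation-based genome-wide significance threshold
#'
#' The phenotype vector is permuted `nPerm` times (covariates held fixed);
#' each permutation records the genome-wide minimum p-value of a single
#' fixed-effect scan. The threshold is the empirical `(1 - quantile)`
#' quantile of those minima (equivalently the `quantile` quantile of the
#' maximal -log10 p), using linear interpolation of order statistics
#' (quantile type 7 — stated because small `nPerm` makes the rule visible).
#'
#' @param G imputed [GenotypeMatrix-class].
#' @param y named numeric phenotype (BLUPs).
#' @param covariates as in [farmcpuScan()].
#' @param nPerm number of permutations (default 30, >= 2).
#' @param quantile confidence quantile (default 0.95).
#' @param seed RNG seed (logged in the output).
#' @return list: `threshold` (p-value scale), `minima` (per-permutation
#'   minimum p), `seed`.
#' @export
permutationThreshold <- function(G, y, covariates, nPerm = 30,
                                 quantile = 0.95, seed = 1) {
  if (nPerm < 2) stop("nPerm must be >= 2")
  d <- dosage(G)
  if (anyNA(d)) stop("impute the panel first")
  if (!is.null(names(y))) y <- y[rownames(d)]
  keep <- apply(d, 2, function(x) stats::sd(x) > 0)
  d <- d[, keep, drop = FALSE]
  scores <- covariates$scores
  if (is.null(scores)) scores <- matrix(0, length(y), 0)
  C <- cbind(1, scores)
  set.seed(seed)
  minima <- vapply(seq_len(nPerm), function(i) {
    yp <- y[sample.int(length(y))]
    min(.fixedScan(d, yp, C)$p, na.rm = TRUE)
  }, numeric(1))
  list(threshold = unname(stats::quantile(minima, 1 - quantile, type = 7)),
       minima = minima, seed = seed)
}

#' Per-SNP additive variance and variance explained
#'
#' Adds `va = 2 p (1 - p) effect^2` (additive variance of the locus, trait
#' units squared) and `pve = va / var(y)` to the association table.
#' Values are stored at full precision; round only when reporting.
#'
#' @param result [AssociationResult-class] with `maf` and `effect` columns.
#' @param y the phenotype (BLUP) vector defining the PVE denominator.
#' @return The [AssociationResult-class] with `va` and `pve` columns.
#' @export
snpStatistics <- function(result, y) {
  tab <- result@table
  tab$va <- 2 * tab$maf * (1 - tab$maf) * tab$effect^2
  tab$pve <- tab$va / stats::var(y)
  result@table <- tab
  result
}

#' Expand significant markers through genome-wide LD
#'
#' snpsLD are all markers (any chromosome) with r-squared at least
#' `minR2` to at least one significant marker, excluding the significant
#' set itself; every qualifying pair is recorded as an LD edge (pairs
#' among the significant markers included).
#'
#' @param G imputed [GenotypeMatrix-class].
#' @param snpsGWAS non-empty character vector of significant marker ids.
#' @param minR2 LD threshold (default 0.7).
#' @return A [MarkerSets-class] object.
#' @export
expandLdSet <- function(G, snpsGWAS, minR2 = 0.7) {
  if (length(snpsGWAS) == 0) stop("snpsGWAS must be non-empty")
  d <- dosage(G)
  mk <- markerInfo(G)
  if (!all(snpsGWAS %in% mk$id))
    stop("snpsGWAS absent from the panel: ",
         paste(setdiff(snpsGWAS, mk$id), collapse = ", "))
  hits <- d[, snpsGWAS, drop = FALSE]
  sdH <- apply(hits, 2, stats::sd)
  sdA <- apply(d, 2, stats::sd)
  r <- suppressWarnings(cor(hits, d))
  r2 <- r^2
  r2[sdH == 0, ] <- NA
  r2[, sdA == 0] <- NA
  edges <- which(r2 >= minR2, arr.ind = TRUE)
  ldEdges <- data.frame(markerA = snpsGWAS[edges[, 1]],
                        markerB = mk$id[edges[, 2]],
                        r2 = r2[edges], stringsAsFactors = FALSE)
  ldEdges <- ldEdges[ldEdges$markerA != ldEdges$markerB, , drop = FALSE]
  ## de-duplicate unordered pairs
  key <- apply(cbind(ldEdges$markerA, ldEdges$markerB), 1,
               function(z) paste(sort(z), collapse = "|"))
  ldEdges <- ldEdges[!duplicated(key), , drop = FALSE]
  rownames(ldEdges) <- NULL
  snpsLD <- setdiff(unique(ldEdges$markerB), snpsGWAS)
  new("MarkerSets", snpsGWAS = snpsGWAS, snpsLD = snpsLD, ldEdges = ldEdges)
}

#' Build the LD network of significant and linked markers
#'
#' Undirected graph on snpsGWAS and snpsLD, edges weighted by r-squared.
#'
#' @param sets [MarkerSets-class].
#' @return list: `graph` (igraph) and `components` (named membership
#'   vector).
#' @export
buildLdNetwork <- function(sets) {
  nodes <- union(sets@snpsGWAS, sets@snpsLD)
  g <- igraph::graph_from_data_frame(
    sets@ldEdges[, c("markerA", "markerB")], directed = FALSE,
    vertices = data.frame(name = nodes))
  if (nrow(sets@ldEdges))
    igraph::E(g)$weight <- sets@ldEdges$r2
  comp <- igraph::components(g)
  list(graph = g, components = comp$membership)
}
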