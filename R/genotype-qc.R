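## Marker QC, kNN imputation, population structure and LD: the substrate
## preparation between raw VCF and the association scan.

#' Retention percentage of a filtering step
#'
#' @param discovered,retained marker counts before and after filtering.
#' @return percentage retained, rounded to 2 decimals.
#' @export
retentionPercent <- function(discovered, retained) {
  if (discovered <= 0) stop("discovered count must be positive")
  round(100 * retained / discovered, 2)
}

.mafOf <- function(col) {
  f <- mean(col, na.rm = TRUE) / 2
  min(f, 1 - f)
}

#' Filter markers on missing rate and minor allele frequency
#'
#' Markers with missing rate strictly above `maxMissing` or MAF strictly
#' below `minMaf` (computed on non-missing calls) are removed; the
#' boundaries themselves are retained. Removing every marker is a warning
#' with an empty panel, not an error.
#'
#' @param G [GenotypeMatrix-class].
#' @param maxMissing maximum tolerated missing proportion (default 0.20).
#' @param minMaf minimum MAF (default 0.05).
#' @return list: `genotypes` (filtered [GenotypeMatrix-class]) and `report`
#'   (list `discovered`, `retained`, `pctRetained` to 2 decimals,
#'   `removedMissing`, `removedMaf`).
#' @export
filterMarkers <- function(G, maxMissing = 0.20, minMaf = 0.05) {
  d <- dosage(G)
  missRate <- colMeans(is.na(d))
  okMiss <- missRate <= maxMissing
  maf <- apply(d, 2, .mafOf)
  okMaf <- !is.na(maf) & maf >= minMaf
  keep <- okMiss & okMaf
  if (!any(keep)) warning("all markers removed by filtering")
  out <- GenotypeMatrix(d[, keep, drop = FALSE],
                        markerInfo(G)[keep, , drop = FALSE])
  rownames(out@dosage) <- rownames(d)
  list(genotypes = out,
       report = list(discovered = ncol(d), retained = sum(keep),
                     pctRetained = retentionPercent(ncol(d), sum(keep)),
                     removedMissing = sum(!okMiss),
                     removedMaf = sum(okMiss & !okMaf)))
}

#' k-nearest-neighbour genotype imputation
#'
#' Each missing entry is replaced by the mean dosage of the `k` nearest
#' samples with an observed call at that marker (Euclidean distance per
#' shared non-missing marker), rounded half-up to the nearest dosage in
#' \{0, 1, 2\}. Neighbour ties are broken by sample order.
#'
#' @param G [GenotypeMatrix-class].
#' @param k neighbour count (default 5); every marker needs >= `k`
#'   observed calls.
#' @return list: `genotypes` (complete panel) and `imputationRate`
#'   (imputed entries / total entries).
#' @export
imputeKNN <- function(G, k = 5) {
  d <- dosage(G)
  nm <- colSums(!is.na(d))
  if (any(nm == 0))
    stop("marker(s) fully missing: ",
         paste(markerInfo(G)$id[nm == 0], collapse = ", "))
  if (any(nm < k))
    stop("marker(s) with fewer than k observed calls: ",
         paste(markerInfo(G)$id[nm < k], collapse = ", "))
  nMissTotal <- sum(is.na(d))
  if (nMissTotal == 0)
    return(list(genotypes = G, imputationRate = 0))

  M <- !is.na(d)
  A0 <- d; A0[!M] <- 0
  ## squared distance per shared marker, all sample pairs at once
  S <- (A0^2) %*% t(M) + M %*% t(A0^2) - 2 * A0 %*% t(A0)
  C <- M %*% t(M)
  D2 <- S / pmax(C, 1)
  D2[C == 0] <- Inf
  diag(D2) <- Inf

  out <- d
  for (j in which(colSums(!M) > 0)) {
    obs <- which(M[, j])
    for (i in which(!M[, j])) {
      dd <- D2[i, obs]
      nn <- obs[order(dd, seq_along(dd))][seq_len(k)]
      out[i, j] <- min(2, max(0, floor(mean(d[nn, j]) + 0.5)))
    }
  }
  Gout <- GenotypeMatrix(out, markerInfo(G))
  rownames(Gout@dosage) <- rownames(d)
  list(genotypes = Gout, imputationRate = nMissTotal / length(d))
}

#' Population structure: PCA and VanRaden kinship
#'
#' PCA on the column-centered dosage matrix, plus the VanRaden genomic
#' relationship matrix `K = W W' / (2 * sum(p (1 - p)))` with
#' `W = dosage - 2p`.
#'
#' @param G imputed [GenotypeMatrix-class] (no missing entries).
#' @param nComponents number of principal components to return (default 2).
#' @return list: `scores` (samples x `nComponents`), `varExplained`
#'   (per-component proportion of total variance), `kinship` (symmetric
#'   samples x samples matrix).
#' @export
populationStructure <- function(G, nComponents = 2) {
  d <- dosage(G)
  if (anyNA(d)) stop("impute the panel before population structure")
  vv <- apply(d, 2, stats::var)
  if (all(vv == 0)) stop("zero-variance panel: no polymorphic markers")
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nComponents <- min(nComponents, ncol(pc$x))
  p <- colMeans(d) / 2
  W <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero-variance panel: kinship undefined")
  K <- W %*% t(W) / denom
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       varExplained = ve[seq_len(nComponents)], kinship = K)
}

#' Pairwise linkage disequilibrium as squared Pearson correlation
#'
#' r-squared between dosage columns; a monomorphic marker yields `NA`
#' (undefined), never 0.
#'
#' @param G imputed [GenotypeMatrix-class].
#' @param pairs optional data.frame/matrix with two columns of marker ids;
#'   when omitted, all pairs within `window` bp on the same chromosome
#'   (or all pairs if `window` is `NULL`) are computed.
#' @param window optional maximum pair distance in bp.
#' @return data.frame (`markerA`, `markerB`, `dist`, `r2`); `dist` is `NA`
#'   across chromosomes.
#' @export
ldR2 <- function(G, pairs = NULL, window = NULL) {
  d <- dosage(G)
  mk <- markerInfo(G)
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(ncol(d))), arr.ind = TRUE)
    a <- idx[, 1]; b <- idx[, 2]
    sameChr <- mk$chrom[a] == mk$chrom[b]
    dist <- ifelse(sameChr, abs(mk$pos[b] - mk$pos[a]), NA)
    if (!is.null(window)) {
      keep <- sameChr & dist <= window
      a <- a[keep]; b <- b[keep]; dist <- dist[keep]
    }
  } else {
    pairs <- as.data.frame(pairs)
    a <- match(pairs[[1]], mk$id); b <- match(pairs[[2]], mk$id)
    if (anyNA(a) || anyNA(b))
      stop("unknown marker id in pairs: ",
           paste(unique(c(pairs[[1]][is.na(a)], pairs[[2]][is.na(b)])),
                 collapse = ", "))
    dist <- ifelse(mk$chrom[a] == mk$chrom[b],
                   abs(mk$pos[b] - mk$pos[a]), NA)
  }
  r2 <- vapply(seq_along(a), function(i) {
    x <- d[, a[i]]; y <- d[, b[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }, numeric(1))
  data.frame(markerA = mk$id[a], markerB = mk$id[b], dist = dist, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Fit the exponential LD decay curve
#'
#' Nonlinear least squares for `r2(x) = a + b * exp(-c * x)` (`x` in bp).
#' Initialization is a multi-start grid over the decay rate `c` (log-spaced
#' `1e-6`..`1e-2` plus a flat candidate); `a` and `b` are conditionally
#' linear and solved exactly per candidate, then the best start is polished
#' with Levenberg-Marquardt under `c >= 0`.
#'
#' @param points data.frame with columns `dist` (bp) and `r2`; at least 4
#'   points spanning more than one distance value.
#' @return An [LdDecayFit-class] object (smallest SSE found; never worse
#'   than the flat model).
#' @export
fitLdDecay <- function(points) {
  x <- points$dist; y <- points$r2
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 finite (dist, r2) points")
  if (length(unique(x)) < 2) stop("degenerate input: all distances equal")

  solveLin <- function(cc) {
    e <- exp(-cc * x)
    fit <- stats::lm.fit(cbind(1, e), y)
    list(a = fit$coefficients[1], b = fit$coefficients[2],
         sse = sum(fit$residuals^2))
  }
  grid <- c(10^seq(-6, -2, length.out = 12))
  cand <- lapply(grid, solveLin)
  sses <- vapply(cand, `[[`, numeric(1), "sse")
  best <- cand[[which.min(sses)]]
  cBest <- grid[which.min(sses)]
  ## flat candidate: b = 0
  flat <- list(a = mean(y), b = 0, c = 0, sse = sum((y - mean(y))^2))

  res <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ a + b * exp(-c * x),
                             start = list(a = unname(best$a),
                                          b = unname(best$b), c = cBest),
                             lower = c(-Inf, -Inf, 0),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, ftol = 1e-14, ptol = 1e-14))
    co <- coef(fit)
    list(a = co[["a"]], b = co[["b"]], c = co[["c"]],
         sse = sum(resid(fit)^2))
  }, error = function(e) NULL)

  pickBest <- flat
  for (cd in list(c(best, list(c = cBest)), res))
    if (!is.null(cd) && cd$sse <= pickBest$sse) pickBest <- cd
  new("LdDecayFit", a = unname(pickBest$a), b = unname(pickBest$b),
      c = unname(pickBest$c), sse = unname(pickBest$sse))
}

#' Evaluate an LD decay fit
#'
#' @param fit [LdDecayFit-class].
#' @param x distances in bp.
#' @return predicted r-squared values.
#' @export
predictLdDecay <- function(fit, x) fit@a + fit@b * exp(-fit@c * x)
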