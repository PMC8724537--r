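## Multi-environment mixed model for the growth trait:
##   y = mu + block + replicate + water + month + g + gw + e
## with g (genotype) and gw (genotype x water level) random. Variance
## components by REML, genotype values by BLUP, random-effect tests by a
## boundary-corrected LRT, and broad-sense heritability on a
## genotype-mean basis.

.phenoFixed <- c("block", "replicate", "water", "month")

.checkPhenotypeTable <- function(pheno) {
  need <- c("genotype", .phenoFixed, "value")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(pheno$value))) stop("trait values must be finite")
  if (length(unique(pheno$genotype)) < 2)
    stop("need >= 2 genotypes to separate g from e")
  invisible(pheno)
}

#' Fit the growth-trait mixed model by REML
#'
#' Fits `value ~ block + replicate + water + month + (1|genotype) +
#' (1|genotype:water)` by REML and extracts the variance components
#' (genotype, genotype-by-water interaction, residual), the genotype BLUPs
#' and the interaction BLUPs. Fixed factors observed at a single level are
#' dropped with a warning; a rank-deficient fixed design is an error that
#' names the aliased columns. A noiseless response (zero residual variance
#' after the fixed effects) short-circuits to an all-zero variance fit.
#' Non-convergence is flagged in the result, never silently returned.
#'
#' @param pheno data.frame with columns `genotype`, `block`, `replicate`,
#'   `water`, `month`, `value` (one row per phenotypic record).
#' @return A [VarianceComponents-class] object.
#' @export
fitMixedModel <- function(pheno) {
  .checkPhenotypeTable(pheno)
  pheno$genotype <- factor(pheno$genotype)
  keep <- character()
  for (f in .phenoFixed) {
    pheno[[f]] <- factor(pheno[[f]])
    if (nlevels(pheno[[f]]) >= 2) keep <- c(keep, f) else
      warning(sprintf("fixed factor '%s' has a single level; dropped", f))
  }
  fixedForm <- if (length(keep))
    paste("value ~", paste(keep, collapse = " + ")) else "value ~ 1"

  ## aliased fixed-effect columns are a design error, reported by name
  X <- stats::model.matrix(stats::as.formula(fixedForm), pheno)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  ## degenerate noiseless case: residuals of the fixed-effect fit vanish
  lmFit <- stats::lm(stats::as.formula(fixedForm), data = pheno)
  if (stats::var(resid(lmFit)) < 1e-12 * max(stats::var(pheno$value), 1)) {
    gl <- levels(pheno$genotype)
    return(new("VarianceComponents", sigmaG2 = 0, sigmaGW2 = 0, sigmaE2 = 0,
               mu = mean(stats::fitted(lmFit)),
               blups = setNames(rep(0, length(gl)), gl),
               gwBlups = data.frame(genotype = character(),
                                    water = character(), blup = numeric()),
               logLik = as.numeric(stats::logLik(lmFit)), converged = TRUE))
  }

  hasWater <- "water" %in% keep
  form <- paste(fixedForm, "+ (1 | genotype)",
                if (hasWater) "+ (1 | genotype:water)" else "")
  converged <- TRUE
  fit <- withCallingHandlers(
    suppressMessages(
      lme4::lmer(stats::as.formula(form), data = pheno, REML = TRUE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  re <- lme4::ranef(fit)
  gB <- re$genotype
  blups <- setNames(gB[["(Intercept)"]], rownames(gB))
  gwB <- data.frame(genotype = character(), water = character(),
                    blup = numeric())
  if (hasWater && !is.null(re[["genotype:water"]])) {
    keyParts <- strsplit(rownames(re[["genotype:water"]]), ":", fixed = TRUE)
    gwB <- data.frame(genotype = vapply(keyParts, `[`, "", 1),
                      water = vapply(keyParts, `[`, "", 2),
                      blup = re[["genotype:water"]][["(Intercept)"]],
                      stringsAsFactors = FALSE)
  }
  new("VarianceComponents",
      sigmaG2 = pick("genotype"), sigmaGW2 = pick("genotype:water"),
      sigmaE2 = pick("Residual"),
      mu = mean(X %*% lme4::fixef(fit)),
      blups = blups, gwBlups = gwB,
      logLik = as.numeric(stats::logLik(fit)), converged = converged)
}

#' Likelihood-ratio test for a random effect
#'
#' `statistic = 2 * (logLik(full) - logLik(reduced))`, floored at zero.
#' Because a variance component sits on the boundary of its parameter
#' space under the null, the default reference distribution is the 50:50
#' mixture of a point mass at zero and chi-squared with `df` degrees of
#' freedom, so `p = 0.5 * P(chisq_df >= statistic)` (0.5 at statistic 0);
#' `mixture = FALSE` gives the plain chi-squared tail (1 at statistic 0).
#'
#' @param full,reduced [VarianceComponents-class] fits of nested models
#'   (reduced within full), both by REML with identical fixed effects.
#' @param df degrees of freedom of the chi-squared part (default 1, one
#'   variance tested).
#' @param mixture use the boundary mixture null (default TRUE).
#' @return list with `statistic` and `p`.
#' @export
lrtRandomEffect <- function(full, reduced, df = 1, mixture = TRUE) {
  stat <- 2 * (full@logLik - reduced@logLik)
  if (stat < -1e-6)
    stop("full model log-likelihood below the reduced model's: ",
         "models not nested or a fit failed")
  stat <- max(0, stat)
  p <- if (mixture) 0.5 * pchisq(stat, df, lower.tail = FALSE)
       else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Broad-sense heritability on a genotype-mean basis
#'
#' `H2 = sigmaG2 / (sigmaG2 + sigmaGW2 / s + sigmaE2 / a)`, where `s` is
#' the number of environments (water levels) and `a` the number of blocks.
#'
#' @param v [VarianceComponents-class] or a named numeric with `sigmaG2`,
#'   `sigmaGW2`, `sigmaE2`.
#' @param s environment count (>= 1).
#' @param a block count (>= 1).
#' @return H2 in [0, 1].
#' @export
heritability <- function(v, s, a) {
  if (s < 1 || a < 1) stop("s and a must be >= 1")
  if (is(v, "VarianceComponents"))
    v <- c(sigmaG2 = v@sigmaG2, sigmaGW2 = v@sigmaGW2, sigmaE2 = v@sigmaE2)
  den <- v[["sigmaG2"]] + v[["sigmaGW2"]] / s + v[["sigmaE2"]] / a
  if (den <= 0) stop("zero total variance: H2 undefined")
  unname(v[["sigmaG2"]] / den)
}
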