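---
title: "Dissecting a quantitative growth trait with GrowthOmics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a quantitative growth trait with GrowthOmics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrowthOmics)
```

GrowthOmics implements, as one tested pipeline, the multiomics dissection of
a quantitative growth trait in a perennial tree crop (the motivating case is
stem diameter in rubber tree, measured in cm): mixed-model BLUP phenotypes,
genotype QC and linkage disequilibrium (LD), an iterative pseudo-QTN
genome-wide association scan with permutation thresholds, LD expansion of
the hits, flanking-gene annotation, GWAS-seeded coexpression modules with
hub scoring, and an Enzyme Commission (EC) metabolic network with
centrality and community structure. This vignette explains each model, the
parameters that matter, and the choices made where the design was open.

## The phenotype model

Phenotypic records follow the multi-environment linear mixed model

$$ y = \mu + X_B b + X_R r + X_W w + X_M m + Z_G g + Z\,gw + \varepsilon, $$

with fixed effects for block ($b$), replicate ($r$), water level ($w$, the
contrasting-rainfall environment) and measurement month ($m$), and random
genotype effects $g \sim N(0, \sigma_g^2)$, genotype-by-water interactions
$gw \sim N(0, \sigma_{gw}^2)$ and residuals
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$. `fitMixedModel()` estimates
the three variance components by REML and extracts the genotype BLUPs that
feed the association scan. Fitting is delegated to `lme4::lmer` — mixed
model fitting is a solved problem and the original analysis likewise used a
packaged fitter — behind a surface that adds the contracts the pipeline
needs: factors observed at a single level are dropped with a warning,
aliased fixed-effect columns are an error that names the columns, a
noiseless response short-circuits to a zero-variance fit, and
non-convergence is flagged in the result object rather than silently
returned.

Random effects are tested by a likelihood-ratio test. Because a variance
component lies on the boundary of its parameter space under the null, the
default null distribution is the 50:50 mixture $\tfrac12\chi^2_0 +
\tfrac12\chi^2_q$, so `lrtRandomEffect()` returns
$p = \tfrac12 P(\chi^2_q \ge \Lambda)$ (0.5 at $\Lambda = 0$); the plain
$\chi^2$ tail is available with `mixture = FALSE`. Broad-sense heritability
on a genotype-mean basis is

$$ H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_{gw}^2/s +
\sigma_\varepsilon^2/a}, $$

with $s$ environments and $a$ blocks (`heritability()`). With the REML
estimates that motivated this package (4.56, 0.0001, 26.69) and $s = 2$,
$a = 4$ the formula gives 0.4060; note that no choice of small integer
$(s, a)$ reproduces the originally reported population-level value, so the
formula, not any printed number, is the contract here.

## Genotype QC and LD

`filterMarkers()` removes markers with more than 20% missing calls or MAF
below 0.05 (both defaults; boundaries retained), reporting counts and the
retention percentage to two decimals. `imputeKNN()` fills missing calls
with the rounded mean dosage of the `k = 5` nearest samples (Euclidean
distance per shared non-missing marker, ties broken by sample order,
half-up rounding into {0, 1, 2}) — the k-nearest-neighbour scheme used for
this class of GBS panels. `populationStructure()` provides PCA scores and
the VanRaden kinship. LD is the squared Pearson correlation of dosage
columns (`ldR2()`), the composite genotype-level estimator appropriate for
unphased data; monomorphic markers yield `NA`, never 0.

LD decay is fitted by nonlinear least squares to
$r^2(x) = a + b e^{-cx}$ ($x$ in bp; $a+b$ is the expected $r^2$ at zero
distance, $c \ge 0$ the per-bp decay rate). Because the objective is
multimodal in $c$, `fitLdDecay()` solves $a, b$ exactly on a log-spaced
grid of $c \in [10^{-6}, 10^{-2}]$ (conditionally linear least squares),
polishes the best start with Levenberg–Marquardt, and keeps a flat-model
fallback so the reported SSE never exceeds the flat-model SSE.

## The association scan

`farmcpuScan()` follows the fixed-and-random iterative design of the
FarmCPU method. The fixed-effect step tests every marker by OLS of the
BLUP phenotype on intercept, the first two principal components, the
current pseudo-QTNs and the marker, with a t-test on the marker
coefficient. The random-effect step re-selects pseudo-QTNs: among markers
with $p \le$ `entryP` (0.01), the best marker per genome bin is taken, and
the bin size ({5e5, 5e6, 5e7} bp) and pseudo-QTN count ({5, 10, 15}) are
chosen by the REML likelihood of the phenotype under the VanRaden kinship
of the candidate set (an EMMA-style profiled likelihood). Iteration stops
when the pseudo-QTN set stabilises. Markers in the final pseudo-QTN set
are re-tested with themselves removed from the covariates; a marker
collinear with the remaining covariates is excluded from its own test and
reported at $p = 1$.

Two guards keep the simplified procedure honest under the null. First,
when no marker of the initial scan reaches `stopP` $= 0.01/m$ (the
published method's default), the scan returns the plain single-marker
results without selecting pseudo-QTNs: covariates chosen for their
association with a null phenotype otherwise overfit it and inflate every
subsequent t-statistic. Second, pseudo-QTN candidacy itself requires
$p \le 0.01$. With both rules the familywise error at the permutation
threshold, measured over 50 simulated null datasets in the test suite,
stays below the 0.10 bound.

The significance threshold is empirical: `permutationThreshold()` permutes
the phenotype (30 times by default), records the genome-wide minimum
p-value of a single fixed-effect scan per permutation, and returns the 5%
quantile of the minima using linear interpolation of order statistics
(quantile type 7 — stated explicitly because with 30 permutations the
quantile rule is visible in the result). Per-SNP summaries follow the
standard single-locus decomposition: additive variance
$V_a = 2p(1-p)\alpha^2$ and PVE $= V_a / \mathrm{var}(y)$, with the BLUP
variance as denominator (the original report's PVE definition is not
stated; this one is reproducible and documented).

Hits are expanded genome-wide: `expandLdSet()` collects every marker with
$r^2 \ge 0.7$ to at least one significant marker (the snpsLD set,
excluding the hits themselves), and `buildLdNetwork()` returns the
$r^2$-weighted LD graph and its connected components.

## Marker annotation

`assignFlankingGenes()` assigns each marker its containing transcript
(distance 0) or the nearest transcripts up- and downstream in genome
coordinates, strand-agnostic; distance is the bp gap between the marker
position and the nearest transcript boundary, and equidistant ties go to
the smaller start coordinate. Both mean-distance conventions (contained
markers counted as zero, or excluded) are reported, since the field's
"average distance" summaries rarely state which is meant. QTL overlap
(`qtlOverlap()`) is closed-interval coordinate containment — external QTL
intervals are supplied directly as coordinates, replacing any
sequence-alignment lift-over, so the package needs no aligner.

## Coexpression

`preprocessCounts()` retains genes with mean CPM ≥ 10 (a flag switches to
the "at least one sample" rule), log2(CPM+1)-transforms and
quantile-normalizes. Quantile normalization is implemented in-package
(`quantileNormalize()`) with ties broken by row order, which makes the
transform exactly idempotent — a property the test suite asserts.

The network is unsigned WGCNA-style: adjacency $|r|^\beta$, with $\beta$
chosen by `pickSoftThreshold()` as the smallest power whose connectivity
distribution fits a scale-free law at $R^2 \ge 0.85$ (signed negative when
the fitted slope is positive; argmax with a warning when no power
qualifies). `tomMatrix()` computes the topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
with zero adjacency diagonal and unit TOM diagonal; the suite checks it
against a literal triple-loop oracle.

Modules come from UPGMA clustering of $1 - \mathrm{TOM}$ with an adaptive
variable-height branch cut (`cutModules()`): a branch qualifies as a
module when, after pruning at most 15% of its members (those farthest
from the rest) plus any individual stragglers, its mean within-branch
dissimilarity is below `coreScatterFrac` (0.75) of the overall mean
dissimilarity and at least `minModuleSize` (30) genes remain; otherwise
the branch splits at its top merge and the rule recurses. This is a
deliberately simple, reproducible stand-in for the cited variable-height
pruning heuristic: its published parameterisation is not stated in the
motivating work, so the package trades fidelity to an under-specified
algorithm for a rule whose planted-module recovery (ARI > 0.9 at
within-module correlation 0.95) and null behaviour (no modules on white
noise) are both asserted by tests.

`selectSeededModules()` picks the modules containing GWAS-assigned genes;
`buildSeededSubnetwork()` adds the snpsLD-associated genes, connects node
pairs with $|r| \ge 0.5$ (pairwise-complete observations, never with
fewer than 3 shared samples) and scores hubs. Hub scores are Kleinberg
HITS scores on the $|r|$-weighted adjacency, computed as the Perron
eigenvector of the adjacency by shifted power iteration and normalized to
a maximum of 1. For a symmetric matrix this equals the principal
eigenvector of $A^\top A$ whenever that eigenvalue is simple; on bipartite
subnetworks (a star, the canonical hub pattern) $A^\top A$ is degenerate
at the top and generic eigensolvers return an arbitrary vector from the
leading eigenspace, so the package computes the well-defined non-negative
vector directly.

## The enzyme network

`extractEC()` collects syntactically valid EC numbers (partial ECs with a
trailing `-` retained but flagged) with gene provenance. From a KEGG-like
pathway flat file, `buildEnzymeNetwork()` retrieves every pathway
containing a query EC and includes *all* enzymes of the retrieved pathways
as nodes — the published network grew from 19 query enzymes to hundreds of
nodes precisely because pathway members are included. A directed edge
$a \to b$ is drawn when a product compound of a reaction of $a$ is a
substrate of a reaction of $b$ within the same pathway. Currency cofactors
(ATP, ADP, NAD(H), NADP(H), H2O, H+, CO2, Pi, PPi, CoA, O2;
`currencyCompounds()`) never create edges — without this exclusion nearly
every enzyme pair connects. Reversibility is not assumed.

`networkTopology()` reports the five per-node measures: degree (in, out,
total, on the directed graph), normalized betweenness, stress (the raw
count of shortest paths through the node), eccentricity and mean shortest
path within the node's component, and neighborhood connectivity (mean
total degree of neighbors), plus graph-level statistics. Betweenness comes
from igraph; stress is computed in-package from BFS shortest-path counts
(no installed package provides it) and is checked exactly — integer for
integer — against an exhaustive path-enumeration oracle on all connected
5-vertex graphs and random 8- and 12-node graphs. The graph-level mean
neighbor count is reported both as distinct neighbors on the simple graph
(2E/N) and as mean total directed degree, because the two conventions
genuinely differ on directed multi-pathway data and published summaries
rarely say which was used.

Hubs are degree outliers under the Tukey rule (total degree above
$Q_3 + 1.5\,\mathrm{IQR}$, strict, hence scale-invariant and empty on
uniform-degree graphs). `detectCommunities()` approximates pan-resolution
community detection in the HiDeF spirit: Louvain modularity partitions at
20 log-spaced resolutions in $[0.1, 10]$, matched across consecutive
resolutions by Jaccard similarity $\ge 0.75$; communities persisting
through at least `persistenceMin` resolutions with at least 4 members are
reported, with containment edges across levels. Full containment-graph
reconstruction of the original algorithm is out of scope; persistence
across resolutions is the idea being kept.

## What the synthetic data emulate — and what they do not

`simulateGenotypes()` builds LD blocks by copying a latent biallelic
haplotype per block and flipping each marker's allele independently at a
rate solved analytically so the expected pairwise dosage $r^2$ equals the
block target (the symmetric closed form $f = (1 - r_2^{1/4})/2$ holds at
allele frequency 0.5; the implementation solves the general case).
TE-dense blocks are generated with the target $r^2$ multiplied by 0.25,
reflecting only the qualitative observation that transposon-rich regions
show lower LD. Missingness is injected uniformly (default 5% where
exercised). `simulatePhenotypes()` draws from exactly the mixed model
above, with planted additive QTLs entering the genotypic value as
$\sum \alpha \cdot \mathrm{dosage}$.

`simulateExpression()` uses a Gaussian latent factor model with a
log-link into negative binomial counts (dispersion 0.1 — the motivating
study gives no expression-noise model, so a standard bulk-RNA-seq value is
used). Module genes load on their module eigengene with
$\sqrt{\rho_\mathrm{within}}$; baseline log-means are drawn in a
moderately-to-highly expressed range (200–2000 expected counts),
consistent with genes that survive a CPM ≥ 10 filter. A stable,
highly expressed housekeeping background (default equal in number to the
module genes) anchors the library size: in a small synthetic panel the
planted modules otherwise dominate the library, and CPM plus quantile
normalization would strip the very signal being planted — a compositional
artifact that a 30,000-gene transcriptome does not exhibit. The
generators are fully seed-deterministic.

What passing tests therefore show: the pipeline recovers planted signals
of the published magnitudes under Gaussian traits, block-structured LD
and factor-structured expression. What they do not show: robustness to
non-Gaussian traits, selection or family structure in the panel,
isoform-level expression complexity, or batch effects — none of which the
generators emulate.

## Problem sizes and numerical choices

The test and acceptance simulations run at deliberately chosen desk
scales: variance-component recovery at 437 genotypes × 8 records × 20
replicates; association power and familywise error at n = 300 samples ×
m = 2,000 markers (20 power seeds, 50 null datasets, 30 permutations
each); module recovery at 900-gene panels over 10 seeds; topology oracles
over all 728 connected labeled 5-vertex graphs plus random 8- and
12-node graphs. These sizes preserve the statistical geometry of the
original design (effect sizes, MAF, per-locus variance shares) while
keeping the whole suite in minutes.

Other numerical choices: variance components floored at zero by the
fitter; REML profile likelihood for pseudo-QTN selection maximized on a
log-grid of the variance ratio refined by golden-section search;
imputation rounds half-up; dosage r² on pairwise-complete data;
correlation-based edges never formed from fewer than 3 shared samples;
all coordinates 1-based inclusive (VCF/GFF3 convention) with interval
overlap closed on both ends.

## Known limitations

The branch cut is a documented simplification, not the published
dynamic-tree-cut heuristic, so module counts on real data will differ in
detail. The FarmCPU-style scan tests markers by OLS in the fixed step
(kinship enters only pseudo-QTN selection), faithful to the cited
method's structure but not a per-marker mixed model. HiDeF is
approximated by resolution-sweep persistence. The LD decay fit assumes a
single exponential regime. PVE uses the BLUP-variance denominator stated
above. These are the places to look first when numbers differ from other
implementations.
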