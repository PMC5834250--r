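---
title: "Discovering condition-specific co-expression modules"
author: "coexmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering condition-specific co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The problem

A gene expression matrix (GEM) assembled from samples of several
biological conditions — say five tumor types plus normal tissue — mixes
regulatory programs. A gene pair that is tightly co-expressed in one
condition and independent everywhere else shows only a mediocre global
correlation, so conventional co-expression networks built from
whole-matrix correlations either miss such pairs or admit them only as
noise. `coexmod` implements the opposite strategy: deconvolute every
gene pair's 2-D expression scatter into sample clusters *first*, then
correlate within clusters, so that an edge can be supported by the
samples of a single condition and annotated as such.

The pipeline is, in order:

1. **Preprocessing** — Kolmogorov–Smirnov outlier removal, log2
   transform of non-zero values, quantile normalization.
2. **Pairwise mixture deconvolution** — a full-covariance bivariate
   Gaussian mixture per gene pair; clusters of ≥ 30 samples are
   retained and scored with Spearman correlation.
3. **RMT thresholding** — the correlation significance cutoff is
   placed at the Poisson → Wigner–Dyson transition of the thresholded
   matrix's nearest-neighbour eigenvalue spacing distribution (NNSD).
4. **Link communities** — the network's *edges* are clustered by
   single-linkage over the linkcomm edge-similarity and cut at maximum
   partition density; a module is a community of edges plus its induced
   gene set.
5. **Enrichment** — per-module condition labels via the strict
   "> 95 % of edges" sample rule and a one-sided Fisher exact test
   (p < 0.001), plus generic term enrichment against a user-supplied
   annotation map.
6. **Cross-network validation** — gene-ID mapping, mini-GEM
   extraction, edge rediscovery against an alternate sample set, and
   Student *t*-tests on expression and DNA-methylation beta values.

## The statistical core

**Why 30 samples?** The Fisher-z power analysis for detecting a
correlation of magnitude $r$ at false-positive rate $\alpha$ and
false-negative rate $\beta$ requires

$$ n \;\ge\; \left(\frac{z_{1-\alpha/2} + z_{1-\beta}}{\operatorname{artanh}(r)}\right)^{\!2} + 3 .$$

At the conventional $\alpha = 0.05$, $\beta = 0.2$ and effect size
$r = 0.5$ this gives $n = 30$ — the floor applied to every mixture
cluster before a Spearman correlation is computed
(`pearson_min_sample_size(0.05, 0.2, 0.5)`).

**Mixture deconvolution.** For each unordered gene pair, samples where
either gene is exactly 0 (the missing-data sentinel that survives the
log2 step) are excluded. Full-covariance 2-D Gaussian mixtures are fit
for $k = 1 \dots 5$ by EM (relative log-likelihood tolerance $10^{-6}$,
at most 200 iterations) and the order is selected by ICL — BIC plus
twice the assignment entropy. ICL rather than plain BIC matters on
continuous data: on a single elongated cloud, EM can carve a thin
high-likelihood "slice" component whose within-slice correlation is
spuriously high; such components have heavily overlapping
responsibilities, which the entropy term penalizes, while genuinely
separated condition clusters have near-zero entropy and are selected
exactly as BIC would. Initialization is a deterministic k-means seeded
from contiguous quantile slices along the data's principal axis, so
every fit is bit-reproducible with no RNG involvement; samples are
hard-assigned to their maximum-responsibility component. A short-EM
screen (a 10-iteration $k = 2$ fit) skips the full $k \ge 2$ search
when even the screen cannot beat the closed-form $k = 1$ fit — on
unimodal pairs, the overwhelming majority in any GEM, this changes
nothing about model selection and makes the exhaustive
$\binom{n}{2}$-pair scan tractable on one CPU. The per-pair kernel is
compiled code (C++), as is usual for exhaustive pairwise network
construction.

**RMT thresholding.** Candidate cutoffs are scanned from 0.99 downward
in steps of 0.001. At each cutoff the gene × gene matrix of maximal
absolute per-cluster Spearman correlations (entries below the cutoff
zeroed, diagonal 1, restricted to genes with a surviving edge) is
eigendecomposed; the eigenvalues are unfolded by mapping through a
cubic smoothing spline (smoothness by GCV) fitted to the empirical
cumulative spectral density, duplicates collapsed at $10^{-10}$, and
the spacings rescaled to mean 1. A Pearson chi-square against the
Poisson density $e^{-s}$ (60 bins over $[0,3]$, $\alpha = 0.001$)
classifies the NNSD; the returned threshold is the last scanned value
whose NNSD still accepts Poisson. Two boundary rules are explicit
because small networks hit them: if no edge ever reaches the scan
floor (0.50) the scan errors ("matrix never dense enough"), and if the
floor is reached without a detected transition — including the case
where the spectrum never holds the required 100 distinct eigenvalues —
the floor is returned with a warning flag. The second rule is what a
desk-scale network with one planted module exercises: its spectrum
never reaches 100 genes, the floor (0.50) is returned, and that value
does sit strictly between the background correlation ceiling
(≈ 0.3–0.45 at 160–240 samples) and the planted correlation mass
(≈ 0.7–0.9), so it thresholds correctly even though no spacing
transition was observable.

**Link communities.** Adjacent edges $(i,k)$ and $(j,k)$ are compared
by the Jaccard similarity of the inclusive neighbourhoods
$n^+(i), n^+(j)$ of their non-shared endpoints; similarities are
unweighted (every GCN edge already passed a high threshold).
Single-linkage clusters of edges at a cut height are exactly the
connected components of the edge-similarity graph thresholded at that
height, which is how the implementation computes them — this makes the
result provably independent of input ordering, with no tie-break
needed. The cut maximizes the partition density

$$ D = \frac{2}{M} \sum_c m_c\,\frac{m_c - n_c + 1}{(n_c - 2)(n_c - 1)} ,$$

preferring the highest-similarity height on plateaus (smaller, tighter
modules). Communities with fewer than 3 edges — the smallest size with
non-zero density — are dropped by default (`min_module_edges`).

One property deserves honesty: the single-linkage cut family does not
contain every edge-connected partition. On every connected subgraph of
$K_5$ with ≤ 6 edges the chosen cut attains the global maximum of $D$
(verified exhaustively in the test suite), but on sparser 6-node
graphs a counterexample exists — a 5-cycle with a pendant edge whose
attachment similarity exceeds the cycle's weakest internal similarity —
where the global optimum is unreachable by any single cut height. The
implementation follows the standard algorithm; the suite tests both
the global-optimum equivalence where it holds and the within-family
optimality everywhere.

**Enrichment.** A sample supports a module if its in-cluster code
appears in strictly more than 95 % of the module's edges. For each
condition the 2 × 2 table (module-sample membership × condition
membership over all samples) is tested with the one-sided
(over-representation) hypergeometric tail; raw p < 0.001 is the
significance rule, with a Benjamini–Hochberg column reported alongside
for transparency but deliberately not used for the flag. Term
enrichment follows the same test against a declared gene background.

**Validation.** A module edge is *rediscovered* in an alternate sample
set when its gene pair reappears among the mini-GEM's edge candidates
(any cluster; cluster indices are not comparable across runs), and
*above threshold* when any such cluster exceeds the reference
network's cutoff. "Student's *t*-test" is interpreted as the classic
pooled-variance two-sided test with a Welch option exposed
(`welch = TRUE`) to document the ambiguity; module-level significance
pools all (gene, sample) values into one test — mirroring a single
published p per comparison — with per-gene results always emitted
alongside. Per-condition global-median normalization
(`median_condition_normalize`) rescales one condition's samples so
their global median is 1, the standard correction when conditions come
from different quantification pipelines.

## What the synthetic generator emulates — and what it does not

`generate_multicondition_gem` simulates log2-scale expression and
returns $2^x$, so the pipeline's log2 step restores the simulated
values exactly. Each gene draws a baseline
$b_g \sim N(\mu_0, \sigma_b^2)$ with $\mu_0 = 5$ (≈ 32 FPKM) and
$\sigma_b = 3$: the several-orders-of-magnitude spread of real
transcriptomes is not decoration — quantile normalization is
rank-based, and only a dispersed background gives it the resolution to
preserve between-gene correlation (with a flat background, a module's
genes occupy a contiguous rank block and their shared factor becomes
rank-invisible, destroying the very signal under study).

A planted module's genes follow $b_g + \delta + a z_s + \varepsilon$
within the active condition's samples, with one latent factor $z_s$
per sample, so every within-module pair has correlation
$a^2/(a^2 + \sigma_\varepsilon^2)$ (default target 0.9). Outside the
active condition they are ordinary noise around a low, tight baseline
($\mu_0 - 3$, sd 0.5): condition-specific modules in tumor data are
near-silent elsewhere, and the compact inactive blob plus the
activation shift $\delta = 6$ log2 units is what makes the active
samples a separable mixture component. The residual noise within the
module ($\sigma_\varepsilon = 0.45$) is tighter than the background
noise (sd 1): genes under strong common regulation scatter less about
their shared factor, and this keeps the module's active dynamic range
(≈ 7 log2 units) inside the span the background can rank-resolve.
Dropout zeros (default 5 % of entries) are injected only into
background entries so planted correlations are undiluted, and are
treated as missing end-to-end: excluded from the KS statistic, left at
0 by the log2 step, excluded from quantile-normalization ranks and
restored as 0, and coded `'9'` in pairwise masks.

What passing tests on this generator do **not** show: robustness to
batch effects, isoform-level structure, count noise (the generator is
Gaussian on the log scale), overlapping modules, or modules without
differential expression — a module co-expressed in one condition at an
unchanged mean level is genuinely hard for mixture deconvolution and
is not claimed.

The KS outlier filter interacts with module size at small gene counts:
a planted module occupying ≥ ~10 % of a sample's transcriptome shifts
that sample's whole distribution enough to be flagged
($D_N > 0.15$) in the active condition. Real modules are a vanishing
fraction of the transcriptome; synthetic runs therefore keep the
module below ~7 % of genes (e.g. 10 of 150, 20 of 500).

## Problem sizes and numerical choices

The shipped simulations use 150-gene GEMs (10-gene module, 3 × 80
samples) for unit-level checks and 500-gene GEMs (20-gene module) for
the five-seed end-to-end recovery study — large enough that the module
is a realistic minority of the transcriptome and that the exhaustive
124,750-pair scan still completes in about a minute per seed on one
CPU. Other defaults: EM ridge $10^{-6}$ × total variance on covariance
diagonals; eigenvalue duplicate collapse at $10^{-10}$; NNSD histogram
60 bins on $[0,3]$; scan grid 0.99 → 0.50 by 0.001; strict `>` in the
95 %-of-edges rule (a sample in exactly 95 % of edges is excluded);
module IDs `M0001…` ordered by descending edge count with ties broken
by the lexicographically smallest gene.

## A worked run

```{r example, eval = FALSE}
params <- gem_sim_params(
  500,
  conditions = list(condition_spec("A", 80), condition_spec("B", 80),
                    condition_spec("C", 80)),
  planted = list(planted_module_spec(1:20, "A", target_correlation = 0.9)),
  seed = 1)
g <- generate_multicondition_gem(params)
res <- run_discovery(pipeline_config(gem = g, seed = 1))
res$gcn
res$modules[[1]]
subset(res$condition_enrichment, significant)
```

On seed 1 this recovers one module of 190 edges over exactly the 20
planted genes (Jaccard 1.0 against the planted set), enriched for
condition A at p ≈ 10⁻⁶¹ and for no other condition; rediscovering its
edges with only inactive-condition samples yields an above-threshold
fraction of 0.

## Known limitations

- The RMT transition itself is only observable on networks with ≥ 100
  well-connected genes; below that the scan returns its floor with a
  warning flag, which is adequate for thresholding but is not an RMT
  measurement.
- Mixture deconvolution assumes condition clusters differ in location
  or shape in each pair's 2-D scatter; purely correlational condition
  specificity (no expression shift) is not reliably separable.
- The link-community cut is optimal within the single-linkage
  dendrogram family; the global partition-density optimum can differ
  on sparse graphs (see above).
- Exhaustive pair enumeration is quadratic in genes; above 2,000 genes
  the build warns, and grid-scale runs are out of scope.
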