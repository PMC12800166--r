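---
title: "Imputing HLA carriership from T cell receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing HLA carriership from T cell receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Conventional T cells recognise peptides only when presented by a specific
HLA protein. Because of this restriction, carriers of an HLA allele share
*public clonotypes* — identical (V gene, J gene, CDR3 amino-acid sequence)
rearrangements observed in many individuals — that are rare or absent in
non-carriers. Given a cohort of paired bulk TCR-Seq repertoires and HLA
allotypes, `hlaimpute` discovers these allele-restricted clonotypes and
turns them into per-allele classifiers that impute HLA carriership from a
single TRA or TRB repertoire. Such imputation removes the need for
laboratory HLA typing in repertoire studies, and the discovered
clonotype–allele table is itself a resource for interpreting
disease-associated clonotypes.

## Units of analysis

A **clonotype** is the triple (V gene, J gene, CDR3 amino-acid sequence)
after collapsing synonymous rearrangements; its **expansion** $C(c, R)$ in
repertoire $R$ is the summed template/read count of its member
rearrangements, and the **depth** $C(R)$ is the number of distinct
clonotypes. Because some export dialects report presence more reliably than
abundance, `collapse_repertoire()` offers `expansion_mode = "binary"`; the
default is the summed count.

Carriership is defined over HLA **functional units**: class-I alleles and
DRB1 alleles directly (the DR alpha chain is invariant), and
alpha-beta heterodimers for DQ and DP (e.g. `DQA1*01:02-DQB1*06:02`),
because both chains are polymorphic there and only the assembled dimer
presents peptide. Without phased genotypes, cis and trans dimers cannot be
told apart, so `enumerate_complexes()` treats every alpha x beta pairing of
a sample's alleles as a candidate carried complex. Zygosity is discarded:
carriership is binary. Samples without genotype information at a locus are
excluded from that locus's statistics rather than counted as non-carriers.

## The association scan

For each unit, samples are binned into carriers and non-carriers and the
*presence* (not expansion) of every public clonotype — one detected in at
least two individuals — is cross-tabulated against carriership. Enrichment
in carriers is tested with a one-sided Fisher exact test: the
hypergeometric upper tail $P(X \ge n_{\text{carrier,with}})$ under fixed
margins, accumulated in log space so that cohorts of thousands of samples
do not underflow. The one-sided direction is enrichment only; depletion of
a clonotype in carriers has no interpretation under HLA restriction.

Pairs with $p < 10^{-4}$ are kept. The cutoff is fixed rather than
optimised per allele, and no multiple-testing correction is applied: the
cutoff acts as a selection rule whose false positives are controlled
downstream by the weighting and classification stages. The scan iterates
over a sparse clonotype-to-samples index, so its cost is proportional to
the total number of presence entries rather than clonotypes x samples.

## Resolving linkage disequilibrium

HLA alleles travel on strongly linked haplotypes, so one clonotype often
associates with several units. For each such clonotype $c$ with $L(c) \ge 2$
candidate units, the package fits an L1-regularised logistic regression
predicting the clonotype's presence $Y_i$ from
$X_i = [\text{carrier}_{i,1}, \dots, \text{carrier}_{i,L(c)}, \sqrt{C(R_i)}]$,
minimising

$$\frac{1}{n}\sum_i \mathrm{CE}(y_i, \hat y_i) \;+\; \lambda \sum_{j=1}^{L(c)} |w_j|,$$

where the sqrt-depth coefficient and the intercept are unpenalised — depth
is a nuisance covariate, not a candidate cause. Ten penalties, log-spaced
from 0.01 to 10, are tried in increasing order (the spacing is the natural
choice for a penalty sweep); each fit runs exactly 1000 full-batch epochs
from scratch with zero initialisation. If after some penalty exactly one
carriership weight has magnitude $\ge 10^{-4}$, the clonotype is assigned
to that unit; if no penalty achieves this the clonotype is **unsolvable** —
its association is locked inside a haplotype this cohort cannot split —
and it is excluded from all downstream analyses. Perfectly collinear
carriership columns stay exactly symmetric under these deterministic
updates, so they can never reach the one-survivor state: collinearity is
unsolvable by construction, which is the intended behaviour.

### Numerical choices

The optimiser is proximal gradient descent (ISTA): a gradient step on the
cross-entropy followed by soft-thresholding of the penalised weights,
which produces exact zeros and makes the sparsity check unambiguous. The
step size defaults to $1/L$ with $L = \sigma_{\max}([\mathbf{1}\,X])^2/(4n)$,
the Lipschitz bound of the logistic gradient. A fixed step of, say, 0.1
oscillates on these designs because the unscaled $\sqrt{C(R)}$ column is
large and nearly constant, putting most of its energy along the intercept
direction; the $1/L$ step is stable for any feature scaling while changing
no optimum. An explicit `lr` override is available. The feature columns are
deliberately left unscaled (binary indicators plus sqrt-depth) so that the
penalty acts on comparable carrier-indicator coefficients.

## Clonotype weights and allele classifiers

Each assigned clonotype gets a weight measuring the strength of its
association: a logistic regression of carriership on the column-wise
Z-scored features $[C(c, R_i), \sqrt{C(R_i)}]$, whose expansion
coefficient's absolute value $|\beta_1|$ is the weight. Clonotypes resolved
from multi-candidate sets are re-fit the same way as single-candidate ones,
so all weights are on one scale. A zero-variance expansion column yields
weight 0.

An allele's weighted clonotype set $A = \{(a_j, c_j)\}$ then drives a
two-feature carriership classifier over

$$X_i = \Big[\sum_j |a_j| \cdot C(c_j, R_i),\; C(R_i)\Big],$$

an ordinary logistic regression. Both features are Z-scored with training
statistics stored in the model (`scale_features = FALSE` disables this; the
scaling changes nothing in exact arithmetic and keeps the optimiser
well-conditioned on deep repertoires). Imputation scores a repertoire under
every model and calls units with carriership probability $\ge 0.5$ — the
threshold is inclusive. Models are only trained for units with training
carriership frequency above 0.01; evaluation by default considers units
with truth-side frequency of at least 0.05, mirroring the release and
reporting filters appropriate for cohort sizes in the thousands.

Both unpenalised fits use an in-package IRLS with a small ridge term
($10^{-6}$) and an iteration cap. On real cohorts with thousands of samples
these fits rarely separate, but synthetic tests routinely do; the ridge
keeps coefficients finite and the whole pipeline deterministic. Away from
separation the fit agrees with `stats::glm` to six decimals (this is
asserted in the test suite).

## Evaluation

Per unit: balanced accuracy $(\mathrm{TPR} + \mathrm{TNR})/2$, precision
and recall, computed over the samples typed at the unit's locus. Precision
with no positive calls is *undefined* and reported as `NA`, not 0, and is
excluded from medians — an all-negative model should score 0.5 balanced
accuracy, not be rewarded or punished by an arbitrary precision
convention. `summarize_evaluation()` aggregates medians and means per
locus.

## The synthetic cohort generator

Restricted cohort data cannot be redistributed, so `simulate_cohort()`
generates cohorts with the structure the framework assumes: per-unit
carriership at configurable frequencies; planted clonotypes detected with
probability `penetrance` (default 0.8) in carriers versus
`background_prevalence` (default 0.02) in non-carriers; a pool of public
background clonotypes (default 2000, each in ~10% of samples) plus private
clonotypes (default 50 per sample) that dominate depth; geometric
expansion counts (mean 2) for present clonotypes; and a +/-30% uniform
per-sample depth factor scaling all detection probabilities, emulating
deep DNA-based versus shallower RNA-based assays. Pairwise linkage between
two units is induced by sampling two haplotypes per individual from a
four-category haplotype table whose joint frequency realises the requested
haplotype correlation $r$; infeasible joint frequencies are rejected
before any sampling. `downsample_repertoire()` thins expansions
binomially, reproducing the recall loss (at stable precision) seen when
models trained on deep repertoires score shallow ones.

The defaults — 300 samples, six units spanning carriership frequencies
0.05–0.5 with 30 planted clonotypes each — describe a mid-sized,
single-population cohort and are the conditions under which the test suite
and the acceptance script measure the pipeline. What passing these tests
shows is that the machinery recovers planted structure under its own
generative assumptions; it does not certify performance on real
repertoires, where effect sizes are smaller and heterogeneous, publicity
is power-law distributed, sequencing artefacts survive filtering, and
population structure induces LD patterns richer than pairwise haplotype
correlation. Generation-probability-based V(D)J models are deliberately
out of scope.

## Degenerate inputs and conventions

* Degenerate 2x2 margins (zero row or column) give $p = 1$.
* Empty repertoires are permitted (with a warning at collapse time); they
  score at each model's baseline probability at zero features.
* Counts of 0 or missing counts in input tables are read as 1 — presence
  was observed.
* Multi-gene V/J calls keep the first listed gene; allele suffixes
  (`*01`) are stripped, since clonotype identity is at gene level.
* CDR3s containing `*`, `X` or other non-canonical letters are removed
  with the non-productive filter.
* Similarity edges in the clonotype graph require equal CDR3 length;
  Hamming distance is undefined across lengths, so length-discordant
  pairs get no edge.
* The train/validation split is simple random; stratification by a
  focal allele is possible upstream but not built in.

## Problem sizes

The test suite and `scripts/acceptance.R` run, among others: the exact
test against a brute-force tail sum on 1000 random tables ($N \le 200$);
a $10^4$-test null calibration; planted-clonotype recovery at $n = 200$
samples with 2000 background clonotypes; 50 replicates of two-unit LD
resolution at $r = 0.8$ ($n = 300$); and the full
simulate–split–fit–impute–evaluate loop at $n = 300$ with an 80/20 split.
These sizes keep any single check under a few minutes on one CPU while
leaving the binomial noise on the measured rates well inside the asserted
margins.

## Known limitations

* Accuracy is strongly frequency-dependent: rare alleles yield few
  associated clonotypes and unreliable classifiers, which is why the
  0.01/0.05 frequency filters exist.
* DQ/DP units conflate cis and trans dimers; unstable trans complexes
  dilute carriership signal.
* TRA- and TRB-based predictions are not combined, and per-allele cutoff
  optimisation is intentionally not implemented.
* The annotation join against VDJdb/McPAS-like tables is an exact CDR3
  (optionally V/J) match on a user-supplied local file; no database
  curation or download is provided.
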