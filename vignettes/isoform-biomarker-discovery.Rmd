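---
title: "Discovering isoform-level drug-response biomarkers with isopharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering isoform-level drug-response biomarkers with isopharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopharm)
```

## The problem

High-throughput drug screens expose panels of cancer cell lines to graded
drug concentrations and record viability; paired RNA-seq quantifies
expression of both genes and their alternatively spliced transcript
isoforms. Because splicing is pervasive in cancer, an individual isoform
can track drug sensitivity even when the gene's aggregate expression does
not: summing a signal-carrying isoform's FPKM with those of uninformative
sibling isoforms dilutes the association. `isopharm` implements a
meta-analytical pipeline that discovers such isoform-level expression
biomarkers across two training studies, and validates them in independent
datasets under a sign-consistency rule.

## From plates to AAC

Raw plates are summarized per (cell line, drug) by a three-parameter Hill
(log-logistic) curve,

$$ v(d) = E_\infty + \frac{1 - E_\infty}{1 + (d/\mathrm{EC}_{50})^h}, $$

with $E_\infty \in [0,1]$ the lower viability asymptote, $\mathrm{EC}_{50}$
the half-effect concentration and $h > 0$ the Hill slope. Before fitting,
sulforhodamine-B (SRB) plates are preprocessed: the mean cell-free (PBS)
blank signal is subtracted from all wells, treated wells are divided by the
mean untreated control, and any dose whose replicate viabilities have a
standard deviation *or* coefficient of variation above 0.2 is discarded.
Both statistics are thresholded because replicate dispersion can be large
in absolute or in relative terms depending on the viability level; the
filter is idempotent. Viabilities are clipped to $[0, 1.2]$ before fitting
to tolerate modest over-growth.

The sensitivity summary is the **area above the curve**:
$\mathrm{AAC} = 1 - \mathrm{AUC}$, where AUC is the mean fitted viability
over the tested dose range on the log10-dose axis (a 1001-point composite
trapezoidal rule; the round-trip against adaptive quadrature is exercised
in the test suite at $10^{-4}$). AAC lies in $[0,1]$ and increases with
sensitivity, combining potency and efficacy in one number. The integration
domain and its normalization by the log-range width are our choice; raw
concentration-axis integration would weight the top doses almost
exclusively.

Numerical choices: the Hill fit is bounded least squares (L-BFGS-B) on
$(\log_{10}\mathrm{EC}_{50}, \log h, E_\infty)$, with
$\log_{10}\mathrm{EC}_{50}$ allowed three decades beyond the tested range,
$h \in [0.05, 20]$, and a fixed 18-point multi-start grid
($\mathrm{EC}_{50}$ at the lowest/middle/highest dose, $h \in \{0.5,1,2\}$,
$E_\infty \in \{0, 0.5\}$). The best residual sum of squares wins and ties
go to the smallest slope, making the fit deterministic. Flat plates are
handled by the parameter bounds themselves: all-viable data pin
$E_\infty \approx 1$ (AAC $\to$ 0), all-dead data push
$\mathrm{EC}_{50}$ below the range (AAC $\to$ 1).

## The nested association models

For each drug and each candidate feature, three linear models are fitted
across cell lines:

$$ M_0: Y = \beta_0 + \beta_T T, \qquad
   M_1: Y = \beta_0 + \beta_T T + \beta_G X_G, \qquad
   M_2: Y = \beta_0 + \beta_T T + \beta_I I_G, $$

where $Y$ is the AAC vector, $T$ the tissue of origin (one-hot encoded;
drug sensitivity in vitro is strongly tissue specific, so every model
adjusts for it), $X_G$ the gene's log2(FPKM+1) expression and $I_G$ one
isoform's expression. $Y$, $X_G$ and $I_G$ are standardized (mean 0,
SD 1) over exactly the cell lines entering each fit, so $\beta_G$ and
$\beta_I$ are standardized effect sizes; the p-value is the usual
two-sided t-test on the expression coefficient. Design choices where the
procedure was open:

* the reference tissue is the most frequent one, and tissues represented
  by a single cell line are merged into an `other` level;
* fits require at least 20 cell lines (`n_min`), which keeps the ~1/3
  out-of-bag test sets used below at a workable size;
* constant features are reported as non-evaluable with a reason, never
  silently dropped.

Per gene, every isoform is fitted under $M_2$ and the most significant one
is selected after Bonferroni correction by the number of isoforms of that
gene actually tested; ties go to the larger $|\beta|$, then the
lexicographically smallest identifier, so selection is invariant to input
order.

## Predictive value and model comparison

Statistical association is not predictive value, so each retained model is
scored by the **concordance index** (CI): the probability that the model
orders a random pair of cell lines correctly by sensitivity. Observation
ties are excluded from the denominator and prediction ties score 0.5
(Harrell's convention); the implementation is checked against brute-force
pair enumeration in the tests. CI is evaluated **out-of-bag**: 100
bootstrap resamples of the cell lines are drawn with replacement (shared
across all features of a drug, and re-drawn until at least two cell lines
are out of bag), models are refitted in-bag — standardization included —
and predictions scored on the omitted ~1/3. The CI uses the model's full
linear prediction (tissue plus expression terms), so $M_1$ and $M_2$ are
compared with $M_0$ on the same footing; with tissue-structured
sensitivity even the null model therefore scores above 0.5, and the
chance-level reference is what the paired comparison below captures. The
expression-only "no-signal" behaviour (CI $\approx 0.5$) is exercised in
single-tissue tests.

Each model's CI vector is compared with the paired null-model vector by a
one-sided Wilcoxon signed-rank test, and gene versus isoform models by the
two-sided version. Zero differences are dropped; with up to twelve
informative pairs the null distribution (midranks for tied magnitudes) is
enumerated exactly, otherwise the standard large-sample approximation is
used. Bootstrap CI vectors are mutually dependent, which can make these
p-values optimistic; the bias is shared by the gene and isoform branches,
so their comparison remains fair, and the calling rule never relies on the
signed-rank p-value alone.

## Meta-combination and calling

Coefficients and p-values from the two training studies are combined as
sample-size-weighted arithmetic means,
$\bar\beta = (n_1\beta_1 + n_2\beta_2)/(n_1+n_2)$ and likewise for $p$.
Averaging p-values is deliberately literal — it is the procedure this
pipeline defines — even though inverse-normal combination would be the
textbook alternative; the operation is symmetric, idempotent on identical
studies, and reduces to pass-through (flagged `single_study`) when one
study is not evaluable. Sign disagreements between studies are flagged,
not errored. The best isoform is chosen once per gene, by the
sample-size-weighted mean of the per-study Bonferroni-corrected p-values,
so that the same transcript is combined across studies; its corrected
p-value is what enters meta-combination and the FDR step.

Benjamini–Hochberg FDR is then applied per drug, separately across the
family of all genes and the family of all selected best isoforms. A level
is called significant when FDR < 1%, median out-of-bag CI > 0.55, and the
signed-rank test against the null model passes at 0.05. The conjunction
defines the category: `gene_specific`, `isoform_specific`, `common`, or
`none`. Because the gates are conjunctive, `discover_biomarkers()` by
default evaluates the (expensive) bootstrap only for features that already
pass the FDR gate — the calls are identical to bootstrapping everything,
which remains available via `bootstrap = "all"`.

Two open points were resolved as follows and are surfaced in the
documentation rather than hidden: the CI > 0.55 filter is applied to the
median of the bootstrap CI vectors pooled (concatenated) across studies,
not per study; and the signed-rank test versus null is run on the pooled
paired vectors.

## Validation

Candidates exported from discovery carry the sign of their meta-combined
coefficient. Pan-cancer validation refits the association on the
independent dataset with the tissue covariate; a candidate validates when
the unadjusted p-value is below 0.05 *and* the coefficient has the
training sign — under a null validation set the expected validation rate
is therefore $\alpha/2$, which the test suite verifies by simulation.
Tissue-restricted pre-selection refits on one tissue's cell lines without
the tissue covariate (it would be constant), and keeps candidates whose
tissue-restricted out-of-bag median CI exceeds 0.55 and whose weighted
p-value is below 0.05; out-of-bag rather than in-sample CI is used, the
more conservative reading. Missing features are reported explicitly
(`missing_feature`), and a drug absent from the validation screen is a
hard "not testable" error. The display effect size for validated
associations is $(\mathrm{CI} - 0.5)\cdot\mathrm{sign}(\beta)$.

## The synthetic-data generator

Every stage is testable without external downloads through a generator
whose defaults define the study conditions used throughout the tests:

* expression on the log2(FPKM+1) scale, clamped at zero, with per-isoform
  baselines uniform on [2, 6] log2 units, tissue-structured baselines
  (i.i.d. standard normal per gene and tissue) shared by a gene's
  isoforms, a within-gene shared factor giving sibling isoforms a default
  correlation of 0.3, and unit-scale idiosyncratic variation;
* gene matrices always recomputed from isoforms by FPKM summation,
  $\mathrm{gene} = \log_2(1 + \sum_i (2^{\mathrm{iso}_i} - 1))$;
* per-gene isoform counts drawn from a configurable distribution
  (default 45/35/20% for 1/2/3 isoforms — the empirical distribution in
  real annotation is a free parameter here);
* AAC generated as a clamped affine map $0.5 + 0.15 \cdot L$ of the linear
  predictor $L$ = tissue effect (i.i.d. N(0,1) per tissue, shared between
  study replicates) + $\sum \beta \cdot$ standardized feature + per-study
  N(0, `noise_sd`) noise, keeping planted $\beta$ interpretable in
  standardized units while rarely clipping;
* planted `isoform_specific` effects place the signal on one isoform
  generated independently of at least two high-baseline siblings (mean
  log2 expression 3 versus 6), so gene-level aggregation demonstrably
  dilutes the signal;
* when a target inter-study Spearman correlation is requested, the
  per-study noise SD is calibrated through the Gaussian rank-correlation
  inversion $r = 2\sin(\pi\rho/6)$, $\sigma = s_L\sqrt{(1-r)/r}$;
* all randomness flows from one seed through labelled, platform-stable
  substreams (expression, per-drug signal, per-study noise, bootstrap
  draws), so identical configurations give bit-identical studies.

What the generator does **not** emulate: count-based sampling noise and
mean–variance coupling of real RNA-seq, shared quantification uncertainty
between isoforms of one gene, batch effects, non-linear dose–response
heterogeneity across cell lines, and missingness patterns of real screens.
Passing tests therefore demonstrate that the machinery recovers planted
linear associations under realistic noise and tissue structure — not that
any particular real drug–transcript association replicates.

## Problem sizes and thresholds used in the checks

The packaged checks run discovery on 100 cell lines in 4 tissues with
1,000 genes (three isoforms each) for the null-calibration study and 200
genes for planted-signal recovery, planted standardized effects of 0.8
against sensitivity noise of 0.3, 100 bootstrap resamples, FDR < 1%,
CI > 0.55, and validation panels of 70 cell lines — sizes chosen to
mirror the scale of a single-drug slice of a real pan-cancer screen while
keeping a full run in seconds. `scripts/acceptance.R` re-runs exactly
these computations from scratch and writes the resulting rates and errors
as JSON.

## Limitations

Associations are univariate and linear by design (a guard against
overfitting, at the price of missing non-linear or multivariate signal);
p-value averaging across studies is heuristic; bootstrap dependence
inflates signed-rank significance as noted above; and the identity filter
consumes a precomputed cross-study concordance table rather than
performing fingerprinting itself.
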