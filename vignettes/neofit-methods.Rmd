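---
title: "Methods: tumor-fitness scoring and prediction-error evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-fitness scoring and prediction-error evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofit)
```

`neofit` implements a neoantigen-based tumor-fitness score and the
statistical machinery needed to test whether that score predicts patient
survival beyond mutation burden and cytolytic immune activity. This
vignette documents the model, the design decisions behind each stage, the
synthetic data the package uses for validation, and the limits of what the
validation shows.

## The fitness model

Immune anti-tumoral response is driven in part by T-cell receptor (TCR)
recognition of mutant peptides (neoepitopes) presented by MHC class I.
The model scores each candidate neoepitope along two axes:

**Recognition potential.** The likelihood that a neoepitope is recognized
by a TCR is assumed to scale with its sequence similarity to known
infectious viral epitopes. Each neoepitope is aligned against a viral
epitope database by Smith–Waterman local alignment (BLOSUM62, affine gap
penalties 11/1 — the protein-BLAST defaults, since no alignment parameters
are standard for this model). With alignment scores $|s,e|$, the
recognition potential is the saturating logistic
$$R = \frac{Z}{1+Z}, \qquad Z = \sum_{e} e^{-k(\alpha - |s,e|)},$$
where $\alpha$ (binding-curve displacement, default 26) positions the
transition and $k$ (steepness, default 4.87) controls how sharply
similarity converts to recognition. These defaults are the constants fitted
for melanoma in the original formulation of the model; they are exposed in
`fitness_params()` and printed with every cohort-level fit, because the
score is known to be sensitive to them. A single hit scoring exactly
$\alpha$ gives $R = 1/2$; $R$ is strictly increasing in every hit score,
never reaches 1, and is 0 for an epitope with no retained hits. In
floating-point arithmetic the logistic saturates once $Z$ exceeds
$2/\epsilon$; the implementation caps $R$ at the largest double below 1 so
the documented invariant $R < 1$ holds for all inputs.

Rather than a heuristic search followed by rescoring, the package aligns
each neoepitope against *every* database entry with an exact
dynamic-programming kernel (written in C++ for speed). At the scale of
short-peptide databases (up to ~10^5 entries) this is both exact and fast,
and it removes an external alignment tool from the pipeline. E-values are
computed analytically from the Karlin–Altschul statistics
$\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ and
$E = mn\,2^{-\mathrm{bits}}$ with the gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$ (configurable in `align_params()`), where
$m$ is the query length and $n$ the total residue count of the database.
Hits with $E \le 10$ are retained by default. Whether the sum in $Z$
should run over all retained hits or only the best hit per neoepitope is
genuinely ambiguous in the model's usual description; both are
implemented (`best_only`), and the default sums all retained hits, which
matches the summation form of the definition.

**Amplitude.** Differential MHC-I presentation of the mutant relative to
its wild-type counterpart is captured by the affinity ratio
$\mathrm{ic50}_{WT}/\mathrm{ic50}_{MT}$ (smaller ic50 = stronger binding,
so a mutant that gains binding has amplitude above 1). The published
description of the dissociation-constant bias correction — multiplication
"by the reciprocal max among all wild type epitopes" — is ambiguous about
scope and direction. The package's default reading is
$$A = \frac{\mathrm{ic50}_{WT}}{\mathrm{ic50}_{MT}} \cdot
      \frac{\mathrm{ic50}_{WT}}{\max_{\text{patient}} \mathrm{ic50}_{WT}},$$
i.e. the ratio is damped for epitopes whose wild type is already a strong
binder, with the maximum taken per patient. The uncorrected ratio is
available via `amplitude_normalization = "none"`; both modes are
unit-tested, and the choice is a parameter rather than a buried constant.

**Immunogenicity and fitness.** The patient-level score is the maximal
product over qualifying neoepitopes, $\ddot I = \max_j R_j A_j$, taken
after a strict 500 nM affinity admission threshold. Tumor fitness is
$1/\ddot I$. Patients with no qualifying epitope receive the sentinel
$\ddot I = 0$, an undefined (NA) fitness, and a `flagged` marker so that
survival-grouping code can exclude them explicitly; silently assigning
them an extreme fitness would distort quantile-based grouping. Clone
labels are carried as metadata only: the maximum runs over all of a
patient's epitopes and no clone-frequency weighting is applied.

## Epitope admission rules

Three strict (`<`) affinity thresholds are used, in decreasing order:
10,000 nM to remove predictor noise, 500 nM for fitness qualification, and
200 nM to define strong binders for burden counts. Mutations confined to
MHC anchor residues are invisible to the TCR while leaving presentation
intact, so records whose mutated positions all fall in the anchor set are
excluded. The canonical anchors are positions 2 and 9 of a 9-mer; because
the epitopes here span 8–11 residues, the package generalizes this to
"position 2 plus the C-terminal position" for every length, with an
explicit position set available for allele-specific work. A record with at
least one non-anchor mutation is kept. The affinity and anchor filters
commute, which the test suite asserts as a set identity.

## Immune measures

CYT is the geometric mean of GZMA and PRF1 expression (RPKM) with a
pseudocount (default 0.01) guarding zero expression:
$\sqrt{(g+\epsilon)(p+\epsilon)}$. TMB is the number of distinct somatic
variants per patient — distinct on (chrom, pos, ref, alt), so MAF files
that repeat a variant per transcript are not over-counted; whether silent
variants count is exposed as a flag (default: they do). Associations among
{Ϊ, CYT, TMB, TIL burden, TIL clonality} use Spearman rank correlations
(robust to the heavy right tails of expression and burden measures) with
pairwise-complete observations; cells with two-sided $p > 0.05$ are masked.
No multiple-testing correction is applied by default — the mask reproduces
the conventional correlogram display — but a Benjamini–Hochberg mode is
available.

## Comparing affinity distributions

Whether neoepitopes or viral epitopes bind MHC-I better is tested on the
ic50 scale with a one-sided two-sample Kolmogorov–Smirnov statistic
$D^+ = \sup_x[F_{neo}(x) - F_{viral}(x)]$: the neoepitope ECDF lying above
the viral ECDF means neoepitopes concentrate at smaller ic50, i.e. bind
more strongly. The asymptotic one-sided p-value
$\exp(-2mnD^{+2}/(m+n))$ is used by default — at the sample sizes this
comparison is designed for (10^4 subsamples) exact small-sample
corrections are irrelevant — and a permutation p-value is available for
samples below ~50. To guard against unequal population sizes, the
comparison is repeated on equal-size subsamples (the full-scale protocol
is m = 10,000 with 1,000 replicates) and the fraction of replicates
rejecting at 0.05 is reported. The package's own calibration checks run
the same machinery at m = 500 with 200 replicates, which keeps the suite
fast while leaving Monte-Carlo error (±0.03 on the null rejection rate)
well inside the asserted bands.

## Viral antigen calling

Contigs assembled from non-human reads enter as FASTA with read support in
the header. Three retention rules apply conjunctively, all inclusive
("at least"): length ≥ 100 bp, support ≥ 20 reads, and base-composition
entropy above a threshold that removes homopolymer-like assemblies. No
entropy value is standard; the default of 1.0 bits sits far above a
homopolymer (0 bits) and far below real viral sequence (~1.9 bits), and is
configurable. ORFs are extracted from all six frames as ATG-to-stop spans
(stop excluded from the protein, included in the nucleotide span), with
nested starts sharing a stop reporting only the longest product, and
reverse-strand coordinates mapped to the forward strand. The minimum
protein length defaults to 100 residues. A stricter excision of products
under 300 residues is sometimes quoted for this kind of pipeline, but that
conflicts with retaining 100 bp contigs (which cannot host 300-residue
products); the package keeps 100 as the default and leaves 300 as an
explicit preset rather than silently reconciling the two.

## Survival evaluation

Patients are grouped by the bottom and top 15% quantiles of a score using
nearest-rank percentiles, with boundary ties falling into the extreme
group — a convention chosen so that groups are never empty for n ≥ 7 and
permutation of input order cannot change labels. Group survival is
compared by the standard log-rank test. Multivariable Cox models are
specified by name: `Reference` (intercept only; its predicted survival is
the training Kaplan–Meier curve), `TMB`, `TMB_I`, and `CYT_TMB`, all
non-reference models including ordinal tumor stage. Skewed positive
covariates enter on the log scale (log for CYT, log1p for TMB,
immunogenicity and TIL burden), stage as integer codes, and all columns
are z-scored with population (not sample) standard deviations — a detail
that makes estimates exactly invariant under patient replication, as is
tie handling by Breslow's method. The proportional-hazards assumption is
checked by the correlation of scaled Schoenfeld residuals with time
(reported per covariate with the score-test p-value).

Prediction error is the time-dependent Brier score with
inverse-probability-of-censoring weights:
$$BS(t) = \frac1n \sum_i \left[
  \frac{\hat S(t|x_i)^2\,\mathbf 1(t_i \le t, \delta_i = 1)}{\hat G(t_i^-)}
+ \frac{(1-\hat S(t|x_i))^2\,\mathbf 1(t_i > t)}{\hat G(t)} \right],$$
with $\hat G$ the Kaplan–Meier estimator of the censoring distribution and
the left limit $\hat G(t_i^-)$ used for event terms (the standard IPCW
convention). Without censoring $\hat G \equiv 1$ and the curve reduces
exactly to the mean squared error, which the tests assert to machine
precision. The default grid is all distinct event times up to the horizon.
The integrated Brier score is the time-normalized trapezoidal integral
over $[0, t_{80}]$, where $t_{80}$ is the time by which 80% of patients
have left the risk set.

Out-of-sample error uses the 0.632+ bootstrap: for each resample, models
are fitted on the bootstrap sample and evaluated on the out-of-bag
patients (with $\hat G$ re-estimated on the evaluation set); the apparent
and averaged out-of-bag curves are combined with weight
$w = 0.632/(1 - 0.368\hat R)$, where the relative overfitting rate
$\hat R$ compares the out-of-bag excess over apparent error to the
no-information error (computed by averaging the loss over all
patient × prediction pairs) and is clipped to $[0,1]$. Degenerate
resamples — too few events to fit, or an out-of-bag set too small to
evaluate — are redrawn and logged. Error curves are compared by one-sided
Wilcoxon tests; the default pairs the per-timepoint 0.632+ values
(signed-rank across the grid), and pairing per-bootstrap out-of-bag IBS
values across replicates is available (`comparison = "ibs"`) since either
reading of "comparing error curves" is defensible. A cross-validation
variant repeatedly splits the cohort in half, fits on one half, scores IBS
on the other, and compares the two models' IBS samples by the one-sided KS
test above.

## The synthetic cohort generator

`generate_cohort()` fabricates every input the pipeline consumes, with the
statistical structure the analysis assumes, so all stages are testable
offline. Its defaults define the package's reference study conditions:

* **Cohort size** 300 patients — the scale of the melanoma and lung
  treatment-naive cohorts this kind of analysis targets.
* **Binding affinities** log-normal on ln(nM): neoepitopes
  $\mathcal{LN}(6.0, 1.5)$ (median ≈ 400 nM) and viral epitopes
  $\mathcal{LN}(7.0, 1.5)$, a one-sigma-unit location advantage for
  neoepitopes that reproduces the direction in which neoepitopes dominate
  viral epitopes in binding strength.
* **Database homology** a fraction (0.3) of neoepitopes are
  single-substitution copies of database entries, which drives the
  recognition potential and viral-likeness calls; 20% of neoepitopes are
  mutated only at an anchor position.
* **Survival** exponential baseline hazard 1/1095 per day (median ≈ 2
  years), proportional-hazards effects on the same z-scored design the Cox
  stage uses — protective CYT ($\beta = -0.8$), modest protective TMB
  ($-0.3$), null immunogenicity (0), adverse stage (+0.3) — and
  independent uniform censoring whose horizon is solved numerically to hit
  a 35% censoring rate. Generating the hazard on the fitted design scale
  is deliberate: planted coefficients are then recoverable by `fit_cox()`
  without unit conversions.
* **Immune copula** CYT and TIL burden share a Gaussian copula whose
  Pearson parameter $2\sin(\pi\rho_s/6)$ hits the planted Spearman
  correlation (0.6) exactly in distribution; GZMA and PRF1 are generated
  so their geometric mean reproduces CYT exactly.
* **Contigs** three viral-like contigs with planted 150-residue ORFs, plus
  decoys each failing exactly one retention rule (a homopolymer, a short
  contig, a low-support contig).

Everything is deterministic given the configuration seed, and
`write_cohort()` emits the on-disk formats plus a metadata JSON recording
all parameters.

What the generator does *not* emulate: realistic mutation signatures and
their trinucleotide context, HLA allele frequencies and allele-specific
binding preferences, correlation between a patient's epitope count and
survival, non-proportional hazards, or informative censoring. Passing
tests on these cohorts therefore demonstrates the correctness and
calibration of the machinery — not that the fitness score predicts
survival in real patients, which is precisely the substantive question the
pipeline exists to examine.

## Numerical choices and degenerate inputs

* Alignment tie-breaks: equal-scoring hits rank by ascending database id;
  optimal-alignment span ties resolve toward the smallest end coordinate.
* An empty alignment (no positive-scoring cell) returns score 0 with NA
  spans; empty sequences are accepted and score 0.
* Brier grid times where $\hat G = 0$ are truncated with a warning; event
  weights with $\hat G(t_i^-) = 0$ contribute nothing rather than
  dividing by zero.
* IBS integration extends the first and last grid values constantly to the
  horizon ends, so a constant curve integrates to the constant.
* Constant features in the association matrix yield NA correlations,
  masked, with a warning; constant scores make quantile groups undefined
  and raise an error.
* The test suite sets problem sizes to keep the full run around two
  minutes (alignment oracle at 1,000 pairs, KS calibration at m = 500 with
  200 replicates, bootstrap at n = 300 with B = 100); all are the
  package's chosen validation scales and are stated in the relevant tests.

## Known limitations

The amplitude correction and the all-hits-versus-best-hit question are
resolved by documented defaults, not by authority; results should be
checked under the alternate settings where they matter. The fitness
constants α and k are inherited, not refitted, and the score's behavior is
known to depend on them. Anchor positions are a length-generalized
heuristic, not allele-specific maps. The e-value model ignores edge-effect
corrections, which is conservative for very short peptides. Proteasomal
cleavage and TAP transport are not modeled, and ic50 values are consumed
as given — the package deliberately starts downstream of MHC-binding
prediction.
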