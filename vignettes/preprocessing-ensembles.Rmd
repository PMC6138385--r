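---
title: "Preprocessing ensembles for prognostic gene signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing ensembles for prognostic gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A prognostic gene signature is scored on a gene-abundance matrix, and that
matrix is not a fact of nature: it depends on the normalization algorithm,
the probe annotation, and whether multiple cohorts were preprocessed
separately or pooled.  Each complete configuration — a *pipeline* — can
flip individual patients between high- and low-risk calls.  prepvote
treats the pipeline as an explicit experimental factor: it scores a
signature under every pipeline, records the binary poor-prognosis *vote*
each pipeline casts per patient, and studies how the votes combine — by
unanimity, by learned tree ensembles over the votes and engineered
vote-summary counts, and by a meta-ensemble over per-pipeline de novo
signatures.

## The scoring scheme

For one matrix and one signature with genes $g_1,\dots,g_k$:

1. per gene, patients are dichotomized at the cohort median of that gene's
   abundance ($1$ if strictly greater, else $0$);
2. the patient score is $s_j=\sum_i \mathbf{1}[x_{g_i j} > \mathrm{med}_j(x_{g_i\cdot})]$;
3. patients with $s_j$ strictly greater than the median score are called
   high risk.

Ties at the median go to the low group.  This makes the rule deterministic
and the high-risk call conservative: with the strict inequality at most
half a stratum can ever be called high risk.  Even-length medians are the
mean of the central order statistics.  For separate-handling pipelines
both dichotomizations run independently within each dataset; for merged
pipelines all patients are pooled.  Whether the original study's merged
pipelines still stratified the score split per dataset is not documented;
we treat merged as fully pooled and expose the choice through the
`handling` argument.

Because every step depends only on within-stratum ranks, scores are
invariant under any strictly monotone per-gene transform of the matrix —
the property that makes votes comparable across pipelines operating on
very different intensity scales (and the property the test suite checks
directly).

## Ensemble classifiers

The unanimous classifier calls a patient only when all pipelines agree
(vote total $0$ or $p$) and otherwise leaves them unclassified; its
coverage is monotonically non-increasing in the number of pipelines.

The learned ensembles are random forests over four feature sets: the raw
votes; votes plus twelve engineered counts (vote totals overall, by
handling, by algorithm, the RMA-and-MAS5 union, and by annotation — the
union is read literally as the 8 pipelines whose algorithm is RMA or
MAS5, log2 variants counting as their own algorithms); engineered counts
alone; and the Boruta-confirmed subset.  The forest is implemented in
C++: `ntree` Gini-split CART trees, `mtry` features sampled per node, and
a class-balanced bootstrap drawing an equal number per class equal to the
minority (event) count, so a 25% event rate does not swamp the trees.
The ensemble probability is the fraction of trees voting poor prognosis,
and labels use a 0.5 cut (ties to good).

Tuning crosses the mtry grid (1, 2, 4, ..., 24 by default) with the ntree
grid (500, 1000, 2000, 5000) and selects by accuracy; the accuracy is
evaluated on the held-out test half by default, which reproduces the
original protocol faithfully at the cost of selection leakage — an
out-of-bag mode (`eval_on = "oob"`) is available but off by default.
Ties go to the smaller `mtry`, then the smaller `ntree`, and every grid
point trains from a seed derived from the combination itself, so the
result is invariant to grid ordering.

### Boruta

Each iteration appends shuffled shadow copies of all not-yet-rejected
features (padded to at least five), trains a forest with out-of-bag
permutation importance, and counts a hit for every undecided feature
whose importance Z-score beats the best shadow.  Hits are tested against
Binomial(iterations, 1/2) two-sided at `alpha`, Bonferroni-adjusted over
the feature count.  Two choices deserve a note.  First, the Bonferroni
adjustment and the shadow-all-kept policy are not forced by the procedure
sketch but match the reference implementation's defaults; without them we
observed pure-noise features with chance in-sample correlation being
confirmed.  Second, the exact binomial test cannot decide anything before
iteration $\lceil\log_2(2p/\alpha)\rceil$, however strong a feature is —
a structural floor worth knowing when setting `max_iter`.  Features still
undecided at the end are resolved by comparing their median importance
history to the median of the per-iteration best-shadow importance.

## Survival statistics

All evaluation statistics are implemented directly against their
definitions and cross-checked in the tests against the `survival` package
and hand tabulations: the Kaplan-Meier product-limit estimator with
Greenwood variance; the two-group log-rank chi-square; the unadjusted Cox
model for a binary group, maximizing the Breslow-ties partial likelihood
by damped Newton-Raphson with Wald 95% intervals on the log scale
(Breslow because the paper's stack defaults to simple tie handling and
because it admits a transparent closed-form score for a binary
covariate); Benjamini-Hochberg step-up adjustment; rank-based AUC with
ties counted one half; and the paired t-test on log2 hazard ratios.
Complete separation makes the Cox partial likelihood monotone and is
raised as an error rather than reported as a huge finite hazard ratio.
Patients the unanimous classifier leaves unclassified are excluded from
that classifier's evaluation.

The per-gene Cox scan for signature discovery precomputes the risk-set
layout once per cohort, so scanning a thousand genes takes well under a
second; genes whose median dichotomy is constant are skipped with a
warning, as are the rare non-convergent fits.

## Novel-signature workflow

Per merged-handling pipeline (12 under the default enumeration): median
dichotomize every gene, fit the univariate Cox model, BH-adjust the Wald
p-values, and keep the 100 top-ranked genes with adjusted $p<0.05$ (all
passing genes, with a warning, if fewer pass).  Each signature is then
validated by a stratified 10-fold cross-validated forest on the
signature genes' dichotomized abundances — every patient receives exactly
one out-of-fold prediction — and the 12 binary out-of-fold
classifications feed a tuned meta-forest.  Two under-specified points
were resolved as follows: discovery should be run on the training half
only when honest held-out evaluation is wanted (`patient_subset`), and
the meta-forest consumes the binary out-of-fold classifications rather
than probabilities or refit predictions, the most literal reading of
"combining the 12 classifications".

## The synthetic cohort: what it is and is not

The generator states one world and the tests live in it.  On the log2
scale, background genes are i.i.d. $N(0,1)$; signature genes add
$\lambda h_j$ where $h_j\sim N(0,1)$ is a per-patient hypoxia-activity
factor; event times are exponential with rate
$\lambda_0 e^{\gamma h_j}$ and censoring is independent exponential.
Defaults: $\gamma=\log 2$ per unit of activity, $\lambda_0=0.05$/year and
censoring rate $0.08$/year, chosen so that roughly a quarter of patients
have an event by five years — the event/censor balance of a large early
breast-cancer cohort (371 events among 1,564 patients) — with the
remainder mostly censored.  Exponential forms are a deliberate
simplification: they give closed-form medians, survivor functions and a
numerically integrable population limit for the marginal hazard ratio,
which the acceptance tests exploit as independent oracles.

Pipeline variants are monotone distortions of the latent matrix:
$g(a x + b + \text{batch} + \epsilon)$ with positive slope, Gaussian
noise (sd 0.4 by default), $g(x)=2^x$ for the native-scale MAS5/MBEI
variants and the identity otherwise.  Per-(gene, dataset) batch offsets
(sd 0.5) are added only to separate-handling variants — emulating
independently normalized datasets sitting on different scales, which the
within-dataset stratification of separate scoring then neutralizes — and
alternative-annotation variants may drop a fraction of genes.  At zero
noise every variant preserves per-gene patient rankings exactly, so all
vote columns coincide (within a handling mode; across modes only when
there is a single dataset, since separate scoring stratifies by
construction).

What the generator does *not* emulate: probe-level microarray noise,
heavy-tailed intensity distributions, correlated gene modules beyond the
single activity factor, informative censoring, or any real cohort's
effect sizes.  A green test therefore establishes that the machinery is
correct and that the qualitative phenomena (pipeline disagreement,
unanimous-subset enrichment, meta-ensemble gains) follow from the stated
structure — not that the original study's numerical hazard ratios are
reproduced, which its unavailable cohorts preclude.

## Numerical choices and degenerate inputs

Seeds: every randomized stage takes an explicit seed, and one master seed
spawns per-stage sub-streams via a hash (`derive_seed`), so adding a
stage never perturbs another stage's stream.  Newton steps in the Cox
fit are damped to $\pm 5$ and $|\beta|>15$ is treated as separation.
Vote-count features are small integers; CART thresholds fall at midpoints
between observed values, so exact ties are handled deterministically.
The unanimous classifier on an empty vote matrix, a single-class outcome,
an all-constant feature matrix, a signature with no genes in the matrix,
and a cohort with no events are all explicit errors or warnings rather
than silent misbehavior.

## Known limitations

The forest is binary-response only and grows unpruned trees; there is no
probability calibration, no survival forest, and no Efron tie handling —
all outside the workflow's needs.  Tuning on the test half leaks
selection information by design fidelity.  The discovery workflow's
cross-validation folds are drawn within the cohort passed to it; when
honest evaluation against a held-out half is wanted, restrict discovery
to the training half and evaluate on the rest.
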