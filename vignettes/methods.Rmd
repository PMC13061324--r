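---
title: "Copy-number-aware differential expression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-aware differential expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid tumors are pervasively aneuploid: genes sit on gained, amplified or
deleted segments, and their transcript counts move with the DNA dose
regardless of any change in transcriptional regulation. A conventional
differential expression (DE) test between tumor and normal samples conflates
these two mechanisms — a gene on a 4-copy amplicon looks "upregulated" even
when its per-copy transcription is unchanged, and a gene whose transcription
is actively buffered against an amplification looks "unchanged" even though
its regulation has shifted substantially. dosageDE separates the two by
fitting the same negative-binomial GLM twice, once ignoring copy number
(CN-naive) and once with the CN dose absorbed into a known offset (CN-aware),
and by classifying genes from the joint pattern of the two tests.

## The model

Counts for gene $g$ are modeled as $y_g \sim \mathrm{NB}(\mu_g, \theta_g)$
with variance $\mu + \theta\mu^2$. The CN-aware mean for sample $n$ is

$$\mu_{g,n} = s_n \, \frac{CN_{g,n}}{2} \, \exp(x_n^\top \beta_g),$$

where $s_n$ is the median-of-ratios size factor, $CN_{g,n}$ the absolute
copy number (2 in every normal diploid sample), and $x_n$ the design row
(intercept and tumor/normal indicator, plus optional numeric covariates).
The factor $CN/2$ is 1 at diploidy, so the CN-aware model reduces exactly to
the CN-naive one when no alteration is present; a 4-copy gene has its
expected count doubled by dose alone, and any remaining difference is
attributed to the condition coefficient. The known factor $s_n \cdot CN/2$
enters the log-link GLM as an offset, so both modes share one fitting code
path; this makes the diploid equivalence of the two modes exact by
construction, which the test suite asserts at $10^{-10}$.

Fitting follows the empirical-Bayes strategy standard for bulk RNA-seq:

1. **Size factors** — median-of-ratios over genes with positive counts in
   every sample; an explicit pseudo-count fallback exists for degenerate
   matrices. The estimator is invariant under global rescaling of the count
   matrix and agrees exactly with DESeq2's implementation (asserted in
   tests).
2. **Dispersions** — per-gene maximum likelihood given preliminary fitted
   means, a parametric trend $\alpha(\bar\mu) = a_0 + a_1/\bar\mu$ fitted by
   a gamma GLM with iterative outlier exclusion, then MAP shrinkage of
   $\log\theta$ toward the trend. The prior variance is the residual spread
   (squared MAD) of gene-wise estimates around the trend minus the expected
   sampling variance $\psi'((N - f)/2)$, floored at 0.25. Gene-wise
   estimates more than two residual SDs above the trend are kept as-is
   (dispersion outliers). The search range is $[10^{-8}, 30]$; one-dimensional
   optimizations run as vectorized golden-section searches in
   $\log\theta$ across all genes simultaneously.
3. **Coefficients** — per-gene IRLS on the natural-log scale (ridge
   $10^{-6}$ on the normal equations, tolerance $10^{-8}$, 100-iteration
   cap, linear predictor clamped to $\pm 30$); non-converged genes are
   flagged and their p-values withheld. Reported log2 fold changes are
   $\beta/\ln 2$.
4. **Shrinkage** — the condition coefficient gets a MAP estimate under a
   zero-centred Cauchy prior (damped Newton on the log-posterior). The prior
   scale is adaptive, $S = \sqrt{\overline{\max(\hat\beta^2 - se^2, 0)}}$
   floored at 0.5 natural-log units: a method-of-moments match of the prior
   spread to the signal variance in the MLEs. We do not claim
   bit-compatibility with any particular shrinkage implementation; the
   relevant behavior — near-MLE estimates for well-measured genes, strong
   pull to zero at low information — is what the tests pin down.
5. **Wald test** — $z = c^\top\hat\beta / se$ with the SE from the observed
   Fisher information of the *unpenalized* fit. Shrunken coefficients are
   used for the reported fold change and the effect-size gate, not for the
   test statistic: the standard Wald construction requires the unpenalized
   SE, and mixing a shrunken numerator with it changes the null distribution.
   A `wald_on = "map"` switch exposes the alternative for sensitivity
   analyses.

CN values below 0.1 are floored before forming $CN/2$ so homozygous
deletions cannot produce a $-\infty$ offset; the floor is a visible argument
(`cn_floor`).

## Stage-wise testing across the two models

The naive and aware p-values for a gene test two strongly correlated
hypotheses; correcting each family separately neither controls the joint
error nor treats the gene as the unit of discovery. We instead screen on the
Simes combination

$$p^{(S)} = \min\{2\min(p^{(N)}, p^{(A)}),\ \max(p^{(N)}, p^{(A)})\},$$

apply a single Benjamini–Hochberg pass to $\{p^{(S)}\}$ at level
$\alpha = 0.05$, and, for screened genes only, confirm the two component
hypotheses with a per-gene Holm step-down. The confirmation level is the
BH-adjusted level implied by screening, $t = \alpha\,|R|/G$ (the stage-wise
testing default), with $t = \alpha$ available via `stage2 = "alpha"`; the
package does not hard-code one choice because the literature uses both.
Genes with missing p-values (failed fits) are excluded from the BH family
rather than silently counted. An independent per-model BH mode
(`mt_mode = "per_model"`) is kept as the legacy comparator.

## Gene-dosage classification

A gene is DE under a model when its confirmed decision is positive *and*
its shrunken $|\log_2 FC|$ strictly exceeds 1 (the gate is applied after
confirmation, each model gated by its own fold change). The joint bits map
to: (naive, aware) = (1,0) dosage-sensitive (DSG; the signal disappears once
dose is accounted for), (1,1) dosage-insensitive (DIG; regulation
independent of dose), (0,1) dosage-compensated (DCG; buffered expression
that only the CN-aware model sees as regulation), (0,0) non-DE. With
diploid CN everywhere the two arms are numerically identical, so DSGs and
DCGs cannot occur — a useful end-to-end invariant that the tests exercise.

The expression filter drops genes with mean count below 10 in *normal*
samples. Descriptions of this filter vary between "across samples" and "in
normal tissue"; we adopt the normal-tissue reading — the reference tissue
defines what is quantifiable — and expose the sample set as a parameter
(`filter_samples`).

Per-gene CN states are annotated from tumor means (neutral $\le 2.5$ <
gain $\le 3.5$ < amplification), with a loss call taking precedence whenever
CN $\le 1$ in at least 25% of tumor samples: frequently deleted genes can
keep a near-diploid mean, and the precedence rule keeps them visible.

## The simulator

`simulate_dataset()` generates matched counts, CN and design with per-gene
ground truth. Baseline means are log-normal (natural-log mean 5, sd 1.5 —
median ≈ 150 counts, a realistic bulk library after low-expression
filtering); dispersions follow $0.05 + 5/\mu_0$ with log-normal jitter
(sd 0.3), the usual decreasing mean–dispersion trend. Class mechanisms:

- **non-DE** — tumor mean $\mu_0$, diploid CN;
- **DIG** — tumor mean $\mu_0 2^{\beta}$ with $|\beta| \sim U(1.2, 3)$ and
  random sign, diploid CN;
- **DSG** — $\beta = 0$, tumor mean $\mu_0 \cdot CN/2$ (pure dosage);
- **DCG** — tumor mean buffered at $\mu_0 (CN/2)^{b}$ with $b = 0$ by
  default (full compensation; a partial-buffering exponent is available),
  CN altered as for DSGs.

Strong CN signal places CN 4–5 (gains) or 1 (losses) in every tumor sample;
weak signal places CN 3 (or 1) in 60% of tumor samples. Gains outnumber
losses 80/20, reflecting the dominance of gains and amplifications among
dose-affected genes in aneuploid carcinomas. Class counts follow
largest-remainder rounding, so configured proportions are hit exactly.
`inject_cn_noise()` perturbs a chosen fraction of entries with additive
discrete noise in $\{-2,\dots,2\}$ weighted 5/30/30/30/5%, mimicking
CN-caller errors where moderate deviations dominate; the robustness harness
applies it to tumor columns only, because normal-sample CN = 2 is an
assumption of the model, not an estimate that could be wrong.

What the simulator does *not* emulate: subclonal CN mixtures and tumor
purity, saturation/diminishing-returns dosage response at high ploidy,
correlated genes (co-amplified segments), outlier counts, and batch
structure. Passing benchmarks therefore demonstrate correctness of the
statistical machinery under the assumed generative model, not performance
on any particular cohort; on real data the dosage-linear assumption is the
main caveat.

Because the generator is parametric and self-contained (nothing is fitted
to external cohorts), its signal is cleaner than simulations calibrated to
real tumor data, and benchmark metrics on it are correspondingly high. All
generator defaults were fixed before the benchmarks were run and are not
tuned to them.

## Benchmarks and problem sizes

`de_benchmark()` scores final DE calls (stage-wise, effect-size-gated)
against truth with DIGs as positives and DSGs/non-DEGs as negatives — DSGs
are exactly the structured false positives a CN-naive analysis makes — and
DCGs excluded and assessed separately by `classification_benchmark()`
(DCG-vs-DSG and DCG-vs-DIG one-vs-one contrasts, plus one-vs-rest).
Effect-size accuracy is MSE and squared Pearson correlation of estimated vs
true log2 fold changes. `robustness_suite()` compares clean and
CN-perturbed runs per dosage class via Jaccard membership overlap, Pearson
$R^2$ of the CN-aware fold changes, and squared Spearman correlation of
screening-adjusted p-values (rank stability of the FDR ordering). Genes
with failed fits in either run are dropped pairwise.

Default problem sizes: 5000-gene grids at $n \in \{10, 20, 40, 60\}$ per
condition with 5 replicates for the DE and classification benchmarks, and
2000-gene grids with 3 replicates for robustness — sizes at which replicate
means are stable while a full grid stays desk-scale. The classification
benchmark needs all four classes present; its default mix is 10% DSG / 30%
DIG / 10% DCG / 50% non-DE (no canonical mix exists for this task; this one
keeps the DCG contrasts balanced against both alternatives).

## Numerical notes and edge cases

- All-zero genes are excluded from fitting and testing and flagged
  (`status = "zero"`); their dispersion is undefined.
- Degenerate metric denominators (e.g. no positive calls) yield `NA`, never
  0-by-convention; the Jaccard of two empty sets is 1 (identical
  membership).
- Simes ties need no special-casing: the formula itself handles
  $p^{(N)} = p^{(A)}$ (the combination equals the common value).
- The engine is deterministic; all simulation randomness flows from a
  single integer seed, and replicate grids derive pairwise-distinct seeds
  from it reproducibly.
- IRLS non-convergence (flat likelihoods, separation-like patterns) is
  flagged rather than fatal; such genes are excluded from the testing
  family and from classification.

## Limitations

The dosage term is linear in $CN/2$ on the mean scale; high-ploidy
saturation and RNA-level buffering that attenuates with dose are not
modeled. CN enters as a point value per gene and sample — subclonal
heterogeneity is averaged out. Indirect effects (a CNV in a transcription
factor moving a diploid target) are attributed to regulation, which is the
intended reading but worth remembering when interpreting DIG calls.
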