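# dosageDE

Copy-number-aware differential gene expression for aneuploid samples, with
gene-dosage classification.

## The problem

In solid tumors, copy-number alterations (CNAs) move transcript counts up
and down by gene dose alone: a gene on a 4-copy amplicon yields roughly
twice the reads of its diploid counterpart even when nothing about its
regulation has changed. Conventional RNA-seq differential expression (DE)
tools (DESeq2, edgeR, limma) implicitly assume diploidy, so tumor-vs-normal
contrasts conflate dose-driven and regulation-driven expression changes —
inflating false positives on gained segments and hiding genes whose
transcription is actively buffered against an amplification.

dosageDE fits the same negative-binomial GLM twice. The CN-naive model is
the standard one,

```
y_gn ~ NB(mu_gn, theta_g),    mu_gn = s_n * exp(x_n' beta_g)
```

and the CN-aware model scales the mean by the per-gene, per-sample dose:

```
mu_gn = s_n * (CN_gn / 2) * exp(x_n' beta_g)
```

with `s_n` the median-of-ratios size factor and `CN_gn` the absolute copy
number (2 in every normal diploid sample). The known factor `s_n * CN/2`
enters the log-link GLM as an offset; dispersions are estimated by the
usual empirical-Bayes three-stage scheme, condition log2 fold changes are
shrunk under an adaptive Cauchy prior, and each model yields a Wald
p-value per gene.

The two correlated tests are combined by **stage-wise multiple testing**:
per gene, a Simes omnibus p-value
`pS = min(2*min(pN, pA), max(pN, pA))` is screened with a single
Benjamini–Hochberg pass at level alpha, and screened genes have both
component hypotheses confirmed by a per-gene Holm step-down. Confirmed
decisions, gated by `|log2FC| > 1`, classify every gene:

| (naive, aware) | class | meaning |
|---|---|---|
| (1, 0) | DSG | dosage-sensitive: signal vanishes once dose is modeled |
| (1, 1) | DIG | dosage-insensitive: regulation independent of CN |
| (0, 1) | DCG | dosage-compensated: buffered expression, visible only CN-aware |
| (0, 0) | nonDEG | no change under either model |

The package also ships a ground-truth simulator (NB counts with
class-specific CN/regulation coupling), a CN-noise injector, and a
benchmarking harness (precision/recall/F1/MCC, effect-size accuracy,
Jaccard stability under CN noise).

## Worked example

```r
library(dosageDE)

cfg <- sim_config(n_genes = 2000, n_per_condition = 20,
                  class_proportions = c(DSG = 0.10, DIG = 0.40,
                                        DCG = 0.10, nonDEG = 0.40),
                  cn_signal = "strong", seed = 7)
sim <- simulate_dataset(cfg)
fit <- dosage_analysis(sim$counts, sim$cn, sim$design)
fit
#> Copy-number-aware differential expression analysis
#>   genes analyzed: 1931 (filtered out: 69)
#>   testing: stagewise, alpha = 0.05, |log2FC| > 1
#>   dosage classes:
#>   dosage_class   n   percent
#> 1          DSG 117  6.059037
#> 2          DIG 770 39.875712
#> 3          DCG 151  7.819782
#> 4       nonDEG 893 46.245469
```

69 genes fell below the mean-expression-10 filter in normal samples. Among
the remaining 1931, the classifier recovers the simulated structure: DIGs
(truth 40%) at 39.9%, and the CN-coupled classes slightly conservatively
(DSG 6.1% vs 10% truth, DCG 7.8% vs 10%), the shortfall being genes whose
dosage signal is too weak to confirm at n = 20. Individual DSG calls show
the expected signature — a strong CN-naive fold change that collapses once
dose is modeled:

```r
head(subset(fit$results, dosage_class == "DSG"), 3)
#>       gene_id lfc_naive   lfc_aware      p_naive   p_aware dosage_class      cn_state
#> 12 gene_00014 -1.167807 -0.19647600 3.861370e-07 0.3741969          DSG          loss
#> 24 gene_00026 -1.263985 -0.27920693 3.974051e-12 0.1158046          DSG          loss
#> 50 gene_00052  1.087212  0.09465304 3.299400e-22 0.3982671          DSG amplification
```

For real data, read the inputs from delimited text and proceed the same
way:

```r
counts <- read_matrix("counts.tsv", "counts")   # genes x samples, integers
cn     <- read_matrix("cn.tsv", "cn")           # absolute CN, tumor columns
design <- read_design("design.csv")             # sample_id, condition (0/1)
fit <- dosage_analysis(counts, cn, design)
write_results(fit$results, "results.tsv")
```

Normal samples missing from the CN file are filled with diploid CN = 2. A
thin command-line wrapper with `fit` / `simulate` / `classify` /
`benchmark` subcommands is installed at
`system.file("scripts/dosagede.R", package = "dosageDE")`.

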