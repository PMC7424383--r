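---
title: "ceRNA network discovery and risk-score prognosis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network discovery and risk-score prognosis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAprog)
options(ceRNAprog.quiet = TRUE)
```

## The problem

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNA
response elements: a long non-coding RNA (lncRNA) that sponges a set of
miRNAs indirectly de-represses the mRNAs those miRNAs would otherwise
silence. In tumor cohorts this motivates a screen for lncRNA–mRNA pairs
that (i) share more targeting miRNAs than chance, (ii) are positively
co-expressed, and (iii) relate to their shared miRNAs in a similar way —
followed by the question of whether the resulting lncRNA–miRNA–mRNA
triplets stratify patient survival.

`ceRNAprog` implements that screen end to end for tumor/normal expression
cohorts (bulk RNA-seq and miRNA-seq counts), together with a
synthetic-cohort generator that plants known triplets so every stage can
be validated against ground truth.

## Stage 1: differential expression

Counts are placed on the log2 counts-per-million scale,

$$\mathrm{logCPM}_{gs} = \log_2\!\frac{(c_{gs} + 0.5)\cdot 10^6}{L_s + 1},$$

with library size $L_s$; the half-count offset keeps zeros finite. Per
gene, the tumor-minus-normal mean difference is the log fold change, and
its significance comes from a moderated t-statistic: gene-wise residual
variances $s_g^2$ (with $d$ degrees of freedom) are shrunk toward a prior
fitted by method of moments on $\log s_g^2$. Writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, the prior degrees of freedom
solve $\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ (Newton iteration on
the trigamma inverse) and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$; the posterior
variance is $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and the
moderated t uses $d + d_0$ degrees of freedom. When the observed
variances are *less* dispersed than chi-square sampling predicts (a
degenerate case arising only in constructed data), the common variance is
taken as their geometric mean so identical variances shrink to themselves
and the statistic reduces to the ordinary t. On realistic data the whole
procedure agrees with the limma reference implementation to ~1e-10 (see
the test suite).

Voom-style precision weights are deliberately omitted: the two-group
contrast and thresholds, not the mean–variance weighting, define the
screen. No TMM or other composition normalization is applied.

P-values are Benjamini–Hochberg adjusted (`p.adjust`); a gene is `up`
when adj. P < 0.01 and logFC > 1, `down` when adj. P < 0.01 and
logFC < −1 (tumor minus normal). Both cut-offs are `RunConfig` fields.

## Stage 2: ceRNA pair scoring

Candidate pairs are lncRNA/mRNA targets of the interaction table,
restricted to differentially expressed RNAs, sharing at least one miRNA.
Three gates, all thresholds configurable:

1. **Shared-miRNA test.** With universe size $N$ (by default the DE
   miRNAs present in the interaction table), $K$ miRNAs targeting the
   lncRNA, $n$ targeting the mRNA and $k$ shared, the pair's p-value is
   $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$; gate at raw
   p < 0.05. Pairs with $k = 0$ are not scored.
2. **Co-expression.** Pearson correlation of the pair over tumor samples
   (the sample set is configurable to `all`), two-sided p from the
   t-transform; gate at $r > 0$ and p < 0.05.
3. **Regulation similarity.** For the $M$ shared miRNAs with
   correlations $r_l^{(k)} = \mathrm{corr}(m_k, l)$ and
   $r_g^{(k)} = \mathrm{corr}(m_k, g)$,
   $$\mathrm{regsim} = 1 - \frac{1}{M}\sum_{k=1}^{M}
     \left(\frac{|r_l^{(k)} - r_g^{(k)}|}{|r_l^{(k)}| + |r_g^{(k)}|}\right)^{M},$$
   gated at regsim > 0. Each normalized term lies in $[0,1]$, so the
   score does too: 1 means identical correlation profiles.

Numerical conventions for the score: a $0/0$ term (both correlations
exactly zero) counts as 0 — two null profiles are identical, not
dissimilar; a miRNA with zero expression variance is dropped with a
warning and $M$ reduced; if no miRNA survives, scoring is an error rather
than a silent pass. The exponent $M$ sharpens the penalty as the shared
set grows; because published transcriptions of this score are ambiguous
about the exponent, `regsim_exponent = "1"` switches to the plain mean of
normalized differences for sensitivity analysis. No sign constraint is
placed on the miRNA–target correlations by default (only regsim > 0 is
required); `require_negative_mirna_corr = TRUE` adds the canonical sponge
direction as an extra gate.

Because RNA-seq and miRNA-seq rarely cover identical samples, every
cross-assay correlation uses the intersection of sample identifiers (at
least 3 required). Tumor-only correlation is the default on the view that
ceRNA activity is a property of the tumor state; pooling tumor and normal
would let the group difference itself manufacture correlation.

## Stage 3: network and hubs

Every passing pair contributes miRNA–lncRNA and miRNA–mRNA edges for each
shared miRNA; edges are deduplicated, so the graph is bipartite by
construction (every edge has a miRNA endpoint). Degree is computed on the
undirected graph; hubs are the top `hub_k = 10` nodes by degree with ties
broken lexicographically, a deterministic stand-in for interactive
degree-ranking tools. Triplets are enumerated per (pair, shared miRNA);
the full list is always reported, with a flag marking triplets whose
three members all lie in the hub set.

## Stage 4: prognosis

For a triplet, the three members' tumor logCPM values are standardized
(mean 0, sd 1 over included patients) and a multivariate Cox
proportional-hazards model is fitted by partial-likelihood maximization
with Breslow tie handling (the `survival` package's fitter; ties are
sparse in continuous-time data, so the simplest standard method
suffices). Each patient's risk score is the linear predictor
$\mathrm{RS}_i = \sum_j \beta_j x_{ij}$; standardization makes the
$\beta_j$ comparable across RNAs and gives an all-average patient a score
of exactly 0. Patients are split at the median risk score — ties at the
median go to the low-risk group — and the two groups are compared by the
Mantel–Haenszel log-rank test with Kaplan–Meier curves for display. Hub
RNAs are screened the same way with a median split on the single RNA's
expression, mirroring the risk-score convention. At least 10 observed
events are required for a Cox fit; collinear features and monotone
likelihoods are reported as errors naming the offending feature, not as
huge coefficients. No clinical covariates enter the model: the risk score
is defined over the ceRNA members only.

**Known limitation — same-data reuse.** The risk model is fitted and the
median-split log-rank is evaluated on the *same* patients. Under a null
in which survival is independent of expression, the fitted direction is
chosen to maximize a 3-covariate fit, so the downstream 1-df log-rank is
anti-conservative: heuristically it behaves like a dichotomized
projection of a $\chi^2_3$ maximum rather than a $\chi^2_1$ draw. The
acceptance suite measures this rate directly (the log-rank test itself is
verified nominal in the same suite, isolating data reuse as the cause).
Interpret small triplet p-values as descriptive of this cohort-level
procedure; for confirmatory use, fit and test on disjoint patient sets or
pre-specify the coefficients.

## Stage 5: enrichment

Over-representation of the DE mRNA list against user-supplied GMT sets
uses the identical hypergeometric tail (one code path with the pair
test), BH-adjusted across sets, gated at q < 0.01 with raw p retained.
Set structure is flat; no ontology hierarchy, and no term databases are
bundled. The default universe is every gene in the expression matrix.

## The synthetic cohort

`simulate_cohort()` emulates the structure of a paired tumor/normal
multi-omic study: per-class count matrices, a miRNA→target table, and a
clinical table. Counts are negative binomial with mean $\mu$ and
$\mathrm{Var} = \mu + \phi\mu^2$, $\phi = 0.2$ (typical bulk RNA-seq
overdispersion), baseline means log-uniform on 20–2000. A fraction
(`de_frac = 0.15` per class, of the order seen in tumor/normal contrasts
at these thresholds) receives a ±2 log2-unit tumor shift — the DE truth.

Each planted triplet has a per-tumor-sample latent factor
$A_s \sim N(0, 1)$ added (on the log2 scale, loading 1) to its lncRNA and
mRNA means and subtracted from its miRNA mean, inducing positive
lncRNA–mRNA and negative miRNA–member correlations while approximately
respecting the count marginals — a latent-factor coupling rather than an
explicit copula. Planted members are forced into the DE truth (lncRNA and
mRNA up, miRNA down) so they survive the DE screen by design. Every
planted miRNA targets every planted lncRNA and mRNA, so each planted pair
shares all `n_triplets` miRNAs — mirroring the biology in which one pair
is sponged by several miRNAs, and giving the hypergeometric gate genuine
signal at desk-scale universes. Decoy interactions are drawn uniformly
over DE, non-planted RNAs: interactions on non-DE RNAs would be discarded
before scoring, so DE-restricted decoys are the ones that actually
exercise the filters.

Survival times are exponential with hazard
$h_0 \exp(\beta^\top x)$, where $x$ is the standardized tumor logCPM of
the first planted triplet's members, $\beta = (0.7, -0.5, 0.7)$ and
$h_0 = \log 2 / 600$ per day (median survival ~600 days at baseline);
censoring is independent uniform on $(0, 3.1/h_0)$, which yields roughly
30% censoring. With 100 tumor and 50 normal samples (the defaults — a
scaled-down cohort keeping the tumor-heavy imbalance of public tumor
atlases while retaining enough normals to estimate group variances), the
designated triplet separates median-split risk groups with near-certain
power, and the miRNA coefficient's sampling sd (~0.23) means its *sign*
is only a population-level property, not a per-cohort guarantee.

What the generator does **not** emulate: library-size and GC biases,
batch effects, annotation ambiguity, biotype misclassification,
non-proportional hazards, or informative censoring. Passing tests
demonstrate that the pipeline recovers the signal it is designed to
detect under its own model assumptions; they are not evidence about
behavior under those real-data complications.

```{r example}
co <- simulate_cohort(seed = 7)
res <- run_all(co, run_config(rng_seed = 7))
res$summary$pair_counts
head(res$risk[, c("lncrna_id", "mirna_id", "mrna_id", "logrank_p")], 3)
```

## Determinism and problem sizes

A single integer seed fully determines the simulated cohort, and
`run_all()` is a pure function of (cohort, config): re-running writes
byte-identical outputs, which the test suite asserts. The validation
suite works at desk scale by choice — DE calibration on 30 + 30 samples
with 1000 genes over tens of replicates, log-rank calibration on 1000
two-group cohorts of 50 + 50, Cox recovery at n = 1000 over dozens of
seeds, and end-to-end recovery on the default 100 + 50 cohort across ten
seeds — sizes at which every oracle (exhaustive hypergeometric
enumeration, brute-force product-limit tables, hand-built log-rank risk
tables) can be computed exactly.

## Configuration reference

| parameter | default | meaning |
|---|---|---|
| `de_adj_p`, `de_abs_logfc` | 0.01, 1.0 | DE gates (BH-adjusted p; log2 FC) |
| `pair_p` | 0.05 | hypergeometric overlap gate (raw p) |
| `pcc_p` | 0.05 | co-expression gate (with r > 0) |
| `regsim_min` | 0 | regulation-similarity gate (exclusive) |
| `enrich_q` | 0.01 | ORA significance gate (BH q) |
| `hub_k` | 10 | hubs kept by degree |
| `correlation_sample_set` | `tumor` | samples for all correlations |
| `mirna_universe` | `de` | hypergeometric universe |
| `regsim_exponent` | `M` | exponent in the similarity score |
| `require_negative_mirna_corr` | `FALSE` | canonical sponge-direction gate |

Overlap p-values are used raw at 0.05 by design fidelity to the screen's
published form; BH adjustment across pairs can be applied downstream from
the returned table if desired.
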