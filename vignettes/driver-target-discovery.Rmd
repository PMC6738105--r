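---
title: "Methods: multi-cohort driver target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort driver target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotarget)
```

This vignette explains the statistical machinery in `cotarget`, the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology left genuine choices open.

## The discovery problem

A driver gene (an over-expressed chromatin factor, say) is suspected of
*activating* a transcriptional program in tumours. Direct perturbation data
in patients is unavailable, so the evidence is assembled indirectly:

* genes whose expression tracks the driver across several independent
  cohorts (co-expression screen, replicated by intersection);
* coherent enrichment of those genes in transcription-factor-motif gene
  sets (which partner factor could mediate the activation);
* prognostic impact of the candidate program (survival coupling);
* cross-species confirmation in a knockout model (orthologs should drop
  when the driver is removed);
* physical plausibility (partner-factor ChIP peaks near the candidates).

Each stage is an ordinary, separately testable function; `run_pipeline()`
chains them and records every summary statistic in a JSON manifest.

## Correlation screen

For each non-driver gene, the sample Pearson coefficient against the driver
is computed on pairwise-complete observations, with the two-sided p-value
from the exact-null *t* transform on *n* − 2 degrees of freedom.
Benjamini–Hochberg adjustment is applied **within each cohort**, over the
family of genes that actually yielded a defined coefficient (at least three
complete pairs and non-constant on them); genes failing those preconditions
are reported with missing *r* and kept out of the family size *m*. The
driver is excluded from its own table — self-correlation is degenerate and
would only distort *m*.

Cross-cohort membership requires *q* < threshold in **every** cohort *and*
a consistent sign everywhere; significant genes with mixed signs are
dropped and counted in a diagnostic (`n_mixed_sign`). The testable universe
is the set of genes with a defined coefficient in all cohorts, and it is
this universe that forms the denominator of the activator-vs-repressor
imbalance test: a two-sided Fisher exact test on
`[[n_pos, N − n_pos], [n_neg, N − n_neg]]`. The published screens describe
this comparison only as a difference-in-proportions test, so the package
defaults to the exact test and offers the χ² two-proportion statistic
(without continuity correction) behind `method = "chisq"`.

Defaults: intersection FDR 0.001 (with 0.01 as the conventional relaxed
level), at least 3 complete pairs per gene. Both FDR levels are plain
arguments; the pipeline asserts its defaults in a configuration test.

## Pre-ranked enrichment

The ranking metric is the correlation coefficient (averaged over cohorts by
`rank_by_correlation()`, so that a gene must be testable everywhere to be
ranked). Ties in the metric are broken lexicographically by gene identifier
— an arbitrary but reproducible order that makes reruns bit-identical.

The enrichment score is the weighted Kolmogorov–Smirnov-like statistic:
walking down the ranked list of *N* genes, a member ("hit") increments the
running sum by $|r_i|^w / N_R$ with $N_R = \sum_{hits} |r_i|^w$, a non-member
decrements it by $1/(N - N_{hits})$, and ES is the running-sum value of
maximal absolute deviation from zero. The increments are chosen so the sum
returns exactly to zero at the end — a conservation property the tests check
to 1e-9 on every instance. With *w* = 0 the statistic collapses to the
classical two-sample KS statistic on hit/miss positions, which the tests
verify against `stats::ks.test`. Numerical choices: an exact tie between
the positive maximum and the negative minimum resolves positive; the
leading-edge peak takes the *earliest* maximising prefix for positive ES
and the *latest* minimising one for negative ES. The default *w* = 1 is the
"weighted" scheme that mainstream GSEA implementations use as their
default; it is a plain argument.

Significance uses gene-label permutation (the only option for a pre-ranked
analysis): `n_perm` random same-size member sets drawn from the ranked
universe. The permutation p-value is the tail frequency among same-sign
null scores with a +1 pseudo-count in numerator and denominator — this
keeps the p-value uniform under the null on either side (the tests confirm
~5% rejection at α = 0.05), at the cost that its attainable minimum is
roughly `1/(same-sign permutations + 1)` rather than `1/(n_perm + 1)`.
`NES = ES / mean(|null ES| of the same sign)`, flagged unstable when fewer
than ten same-sign null values support it. The across-sets FDR is the
standard permutation ratio — (fraction of pooled null NES at least as
extreme, same sign) over (fraction of observed NES at least as extreme,
same sign), clipped to [0, 1] — with BH on the permutation p-values behind
`fdr_method = "bh"`.

"Intersecting the leading edges" of the selected sets is read as strict
intersection (present in *all* selected leading edges): with heavily
overlapping motif sets this is the reading that produces a compact core
list, and it is what the synthetic planted-core recovery exercises. A
relaxed "in at least *k*" rule is available via `min_sets`.

## Metagene survival analysis

The default metagene is the per-sample mean of per-gene z-scores
(`mode = "zmean"`). A plain mean of log2 values (`"rawmean"`) is provided,
but z-scoring first is the safer default when cohorts come from different
platforms: it makes the score invariant to per-gene affine rescaling, a
property the tests assert. Zero-variance genes are dropped with a warning
in z-mean mode; missing values among the listed genes are a hard error —
correlation tolerates missingness pairwise, but a mean over different gene
subsets per sample would silently change the score's meaning.

Median dichotomisation sends ties (and the median itself) to "low" — a
deterministic, documented rule. Kaplan–Meier estimation, the log-rank test
and Cox regression are delegated to the `survival` package, the field's
reference implementation, behind tidy interfaces; the test suite
cross-checks them against hand-tabulated product-limit values, the
hand-computed two-group log-rank χ² (49/17 on the four-subject example),
the asymptotic identity between log-rank and the Cox score test, and an
independent Newton–Raphson partial-likelihood maximiser. Ties are handled
by Breslow's approximation by default (Efron behind a flag) — the simplest
consistent choice, and the one matching the hand-derivable score test.
Monotone likelihood (perfect separation) is detected — a diverging
coefficient or a non-convergence warning — and raised as an error rather
than returned as a huge hazard ratio.

## Cross-species nomination and group tests

The knockout DE filter follows the conventional strict inequalities:
FDR < 0.1 and |logFC| > 1.0, so boundary values are excluded — the tests
pin this down. Orthology is case-folded symbol equality (`RRM2` ↔ `Rrm2`):
no orthology database is consulted, which is exactly what name-based
intersection of human and mouse tables does; genes whose symbols diverged
between species are a documented limitation. Which human list feeds the
intersection — the full FDR < 0.001 positive list or the leading-edge core
— is configurable (`human_list`), defaulting to the positive list.

Wilcoxon rank-sum comparisons are exact (full enumeration) when the
smaller group has ≤ 8 observations without ties, and use the
tie-and-continuity-corrected normal approximation otherwise; one-way ANOVA
is the classical pooled-variance F test. Both delegate to base R and are
verified against enumeration and sums-of-squares oracles.

## Peak-to-gene annotation

All interval arithmetic is 0-based half-open internally; GTF input
(1-based closed) is converted at the reader boundary, and a test confirms
the conversion agrees with `rtracklayer`. Overlap requires at least 1 bp:
a peak ending exactly where a window starts does not bind. Two window
anchors are implemented because both conventions are in active use: the
default pads the whole CDS span by ±2 kb; the alternative takes a
strand-aware TSS ± 2 kb. Windows are clipped at coordinate zero. Multiple
models per gene yield a union of windows — a peak in any of them marks the
gene bound. Binding fractions are reported per dataset over the query
genes present among the gene models, with absent genes listed separately
rather than silently shrinking the denominator.

## qPCR quantification

Two small formulas support the validation experiments: ΔΔCt relative
expression, `2^-((Ct_t − Ct_ref) − (Ct_t,ctrl − Ct_ref,ctrl))`, and
ChIP-qPCR percent-of-input with dilution adjustment,
`100 × 2^(Ct_input − log2(1/f) − Ct_IP)` for input fraction *f*. Both
assume 100% amplification efficiency — the ΔΔCt method's own assumption;
efficiency-corrected variants are out of scope. Technical replicates are
averaged on the Ct scale before transformation (averaging after the
exponential transform would weight replicates unequally).

## The synthetic-data generator

`gen_cohorts()` draws, per cohort, a latent activity *z* ~ N(0,1) per
sample; the driver is *z* + σε and each module gene is *a·z* + σε with the
loading *a* solved from the factor model so that the *population*
correlation between gene and driver equals ρ exactly
(*a = ρσ√(1+σ²) / √(1 − ρ²(1+σ²))*). Because the driver itself carries
noise, attainable |ρ| is capped at 1/√(1+σ²); `sim_config()` rejects
configurations beyond the cap rather than silently delivering a smaller
correlation. Anti-correlated genes use −*a* (giving the sign-proportion
test a non-degenerate table), background genes are independent unit
noise, and every gene receives a baseline log2 abundance shared across
cohorts. Defaults — 3 cohorts × 200 samples, 5,000 genes, a 100-gene
module at ρ = 0.6 with 20 anti-correlated genes, σ = 0.5 — describe a
well-powered multi-cohort screen at desk scale: ρ = 0.6 at n = 200 puts
module genes far inside FDR 0.001 while leaving background genes null.

Survival times are exponential with hazard λ·exp(β·score) — proportional
hazards by construction, with the baseline shape irrelevant to log-rank
and Cox contracts. Censoring is independent uniform on (0, c_max) with
c_max solved numerically so the expected censored fraction matches the
requested rate. Defaults λ = 0.02 events/month, β = 0.7 per unit
metagene, 30% censoring — an aggressive-tumour regime where median
survival spans a few years.

Gene sets are "motif-like": five sets sharing a planted 50-gene core, each
padded with further module genes and a few background members (so leading
edges agree on the core but not on the padding), plus fifty decoy sets of
background genes. The knockout table plants module orthologs at
logFC ≤ −1.5 with FDR < 0.05 and keeps background genes null on both
axes. Peak fixtures place significant peaks in bound genes' windows,
*non-significant* peaks in some unbound genes' windows (so skipping the
FDR filter visibly changes the answer), and significant decoys far from
any window.

What the generator does **not** emulate: probe effects, batch structure,
count noise, platform-specific normalisation, correlated background
modules, or partially overlapping gene universes between cohorts (a
dedicated fixture covers name-based intersection instead). Passing the
planted-truth tests therefore demonstrates that the machinery is correct
and well calibrated — not that any particular biological screen will reach
the same recall on real data, where effect sizes vary per gene and the
background is not independent.

## Determinism and problem sizes

Every generator and every permutation routine takes a seed; a single
global seed is expanded into fixed per-stage substreams
(`stage_seed()`), so stages can be rerun independently yet reproducibly,
and reruns of `run_pipeline()` are bit-identical. The test suite runs the
full screen at 3 cohorts × 200 samples × 5,000 genes with 1,000
permutations over 55 gene sets, 2,000 null log-rank simulations at n = 100,
and 200 Cox-recovery simulations at n = 500 — sizes chosen to keep Monte
Carlo error well below the contract margins while completing in a few
minutes; the acceptance script uses the same sizes.

## Known limitations

* Correlation-based screening cannot separate direct targets from
  co-regulated bystanders; the cross-species and binding stages narrow but
  do not eliminate this.
* Name-based orthology misses genes whose symbols diverged.
* The permutation FDR inherits GSEA's known conservatism/instability for
  very small collections; with fewer than two scored sets it falls back to
  the permutation p-value with a warning.
* Proportional-hazards diagnostics, time-varying covariates and competing
  risks are out of scope; the Cox interface reports what it fits and no
  more.
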