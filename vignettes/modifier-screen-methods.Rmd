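---
title: "Methods: statistics of a Drosophila modifier screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics of a Drosophila modifier screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

`modscreen` packages the quantitative machinery of a genetic-modifier
screen: behavioral scoring statistics, exact categorical inference on
penetrance tables, and a simplified count-based differential-expression
stage, together with synthetic-data generators that emulate each assay's
statistical structure. This vignette documents the models, their
assumptions, the defaults, and the design choices made where the design was
genuinely open.

## Countercurrent climbing

In the Benzer countercurrent apparatus, ~20 flies start in tube 0, are
tapped down and given 15 s to climb; climbers are transferred to the next
tube and the cycle is repeated five times. The climbing index is

$$ CI = \frac{\sum_{i=0}^{5} N_i \, i}{5 \sum_i N_i}, $$

with $N_i$ the number of flies counted in tube $i$ at the end.

**Trial semantics.** The protocol wording admits two readings. The default
model gives every fly exactly five independent Bernoulli($p$) climb
opportunities, so its final tube is its number of successes and
$E[CI] = p$: the index is an unbiased estimate of the per-trial climb
probability, and `estimate_climb_prob()` returns it with a Wilson interval
on $5\sum N_i$ trials. The alternative — a fly that fails stays behind and
is not re-tested — is available as `simulate_countercurrent(dropout = TRUE)`;
it stochastically lowers the mean tube and breaks the identity, which is why
it is not the default. Optional Beta-distributed per-fly probabilities
(`kappa`) add over-dispersion for robustness experiments; off by default.

Genotype comparisons (`compare_climbing`) compute one CI per replicate run
(at least three runs per genotype, matching the assay's design) and pass
them to Kruskal–Wallis with Dunn's post hoc against the control — CIs from
~20 flies are bounded, discrete and not plausibly normal.

## Center-occupancy tremor metric

A fly is recorded for 10 min at 30 frames/s in a circular well; the last
5 min are analyzed (`analysis_window`, 0-based frame indices, so a complete
recording contributes exactly 9000 frames). The tremor score is the
fraction of observed frames strictly inside a concentric disc of radius
`inner_ratio * R`, default 0.743 (`center_occupancy`).

Three numerical choices matter:

* **The threshold is a ratio, not a length.** Protocols sometimes print the
  inner circle as an absolute distance in tracker units; that number is
  device-specific (and in our source material arithmetically inconsistent
  with the stated 15-mm well), so the scale-free ratio is the primary
  parameter and `chamber_geometry(inner_radius = )` exists only for literal
  reproduction of a stated absolute threshold.
* **Boundary frames count as outside** — the inequality is strict, as the
  defining formula is printed.
* **Tracking dropouts** (missing coordinates) are removed from numerator
  and denominator: the metric is a fraction of *observed* time.

Occupancy is invariant under rotation about the chamber center and under
joint rescaling of coordinates and geometry (property-tested).

## Seizure time-courses and recovery

Heat-induced seizures are scored as a per-fly binary state at every 5-s
assessment over 2 min (24 bins). The state is instantaneous per-bin status,
not cumulative, so remission is representable in data; the default
generator, however, is onset-only (exponential onset hazard, no remission),
because the assay window is short. `incidence_curve` averages within
replicate groups first and reports mean ± SEM across groups, which is how
such time-courses are plotted.

`compare_incidence` feeds the replicate × bin proportion table into a
classical balanced mixed-design ANOVA (`rm_anova_two_way`): genotype is
between-subjects, the replicate group is the subject, time bin is within.
The genotype $F$ is tested against subjects-within-genotype; time and the
interaction against the residual. Unbalanced designs are rejected rather
than imputed — with three replicate groups per genotype there is no
defensible imputation. Sphericity correction is off by default (the
source analyses give no indication one was applied); Greenhouse–Geisser is
available as `sphericity = "greenhouse-geisser"`. Per-bin pairwise genotype
comparisons use Welch $t$ on the replicate values at that bin, Holm–Šidák
adjusted across all bin × pair comparisons; Welch was chosen over a pooled
model-error term because with 3 subjects per cell the per-cell variance
estimate is fragile and Welch degrades gracefully.

Bang-sensitivity recovery times are right-skewed, so groups are compared
with the Mann–Whitney U test. Flies not recovered by the end of observation
are represented explicitly as censored and enter the ranking at the horizon
as tied maxima — with midranks this is exact for the rank test as long as
the horizon exceeds all observed times, which `recovery_summary` enforces.
The median treats censored flies as larger than any observed time and is
reported as `NA` when it falls in the censored region.

## Penetrance and viability tables

Penetrance is `100 * affected / scored` to 1 decimal. Published tables
print `n` and the percentage; `reconstruct_counts` inverts the rounding
(half away from zero, the convention that reproduces such tables) and flags
any cell whose printed percentage no integer count can produce — one such
typo exists in the bundled screen fixture and the validator catches it.

`screen_report` tests each deficiency against the control row per trait
with Fisher's exact test and calls significance at the Bonferroni-adjusted
threshold $\alpha/m$, $m$ = number of screened deficiencies (0.05/11 here).
The two-sided p-value uses the probability-mass convention — the sum of
hypergeometric probabilities of all margin-preserving tables no more
probable than the observed one — which is the dominant software convention;
conventions differ (tail-doubling is the main alternative), so this is
stated rather than assumed. The two-sided p is invariant to row/column
swaps, so the orientation of the table does not matter (tested). The odds
ratio is reported as the sample cross-product ratio $ad/bc$, $\infty$ when
only the denominator product vanishes, undefined (flagged) when both do.

## Simplified differential expression

The DE stage is deliberately a transparent, minimal reimplementation of the
count-based workflow, intended for simulation studies — *not* a replacement
for a production tool:

* **Normalization**: median-of-ratios size factors over genes with positive
  counts in every sample.
* **Per-gene test**: normalized condition means; log2 fold change with a
  0.5-unit pseudo-count (genes with a zero mean are flagged); a pooled
  method-of-moments dispersion per gene, floored at $10^{-8}$; a Wald
  statistic whose standard error follows from the NB variance function
  $\mathrm{Var}(K/s) = q/s + \alpha q^2$ by the delta method. The statistic
  is referred to a $t$ distribution with $n_A + n_B - 2$ degrees of freedom
  rather than a normal: with four replicates and a moment dispersion
  estimate the normal reference is anti-conservative, and the $t$ reference
  empirically restores type-I error to its nominal level (the null
  simulations in the test suite check raw $p < 0.05$ frequency and BH
  discoveries).
* **Known differences from shrinkage-based tools**: no dispersion shrinkage
  across genes, no fold-change moderation, no independent filtering, and
  the GO stage is a plain one-sided hypergeometric test with BH control —
  transcript-length bias is ignored. Consequently moderate fold changes at
  low counts are under-powered relative to shrinkage-based analyses, and
  the package's claims about this stage are calibration and parameter
  recovery on synthetic data, not reproduction of any published DE table.

## Synthetic-data generators

The generators produce data with the statistical structure each stage
assumes, with defaults set to the study designs: 3 replicate groups of ~20
flies (climbing), 30 fps × 600 s recordings (locomotion), 3 groups of 30
flies × 24 five-second bins (seizures), log-normal recovery times, binomial
penetrance tables, and NB counts with 2000 genes, 4 replicates per
condition, dispersion 0.05, log-normal size factors (sd 0.15, geometric
mean 1) and one "GstS1-like" gene spiked at log2FC = −1 by default.
Baseline means are drawn log-uniformly on [10, 10000], a realistic dynamic
range for detected genes in a bulk experiment.

Trajectory dynamics are invented — the source assay defines only the
metric, not fly motion — and are designed solely to separate the metric's
two regimes with parameters exposed. The wall-follower walks angularly at
radius $\mathcal{N}(0.9R, 0.02R)$ (occupancy of the 0.743 R disc is
effectively 0). The tremor walker is a mean-reverting AR(1) process about
the chamber center, clipped at the wall, rather than the more obvious
reflected random walk: the AR(1) form vectorizes exactly (`stats::filter`),
which keeps 200-simulation studies at full recording length tractable, and
its stationary radial distribution is available in closed form, so the
default reversion (φ = 0.95) and stationary spread (0.35 R) were set
analytically to give disc occupancy $1 - e^{-0.743^2/(2\cdot0.35^2)}
\approx 0.9$. What passing tests show is that the *metric and inference*
behave correctly when the regimes differ; they say nothing about real fly
biomechanics, arena-edge optics, or tracking noise, which the generator
does not model.

All generators are deterministic given a seed and restore the caller's RNG
state.

## Problem sizes and interfaces

The bundled simulation studies use 1000 replicate runs per climb
probability, 200 locomotion simulations of 20 + 20 flies at full recording
length, and 100 + 100 (spiked + null) DE simulations of 2000 genes — sizes
chosen so Monte-Carlo error is comfortably below each property's margin.
The exact-test oracle check enumerates every 2×2 table with total $N \le
40$.

File interfaces are plain UTF-8 TSV/CSV with explicit headers (readers
validate schemas and report offending rows); `run_pipeline()` drives the
tabular stages end to end and writes deterministic outputs. The package is
an R library by design — the exported functions, `run_pipeline()` and the
repository's `scripts/acceptance.R` are the command surface, and no
separate shell executable is shipped.

## Known limitations

* The Fisher two-sided convention and the Dunn adjustment family
  (Bonferroni over control comparisons, SigmaPlot's default) are assumptions
  where the upstream software path is unstated; both are parameterized.
* `rm_anova_two_way` requires balance; real screens with lost replicate
  groups need a mixed-model treatment outside this package's scope.
* The DE stage's power at low counts is below that of shrinkage-based
  tools by construction.
* Censored recovery times are handled by ranking, not survival regression.
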