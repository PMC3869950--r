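---
title: "Methods: rank-product meta-analysis, pattern classification, cohort and growth statistics"
author: "rpmeta maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-product meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmeta)
```

This vignette is the package's own account of its methods: the model behind
each module, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## 1. The rank-product meta-test

### Model

Samples from several independent studies are pooled into ordered biological
groups — normal brain (N), low-grade tumor (L), high-grade tumor (H) — and
analysed pairwise (NL, LH, NH). For a pair (A, B) with group sizes
$n_A, n_B$, every cross-group sample pair contributes one log ratio

$$Y_{i,m} = X_{i,l,B} - X_{i,j,A}, \qquad m = 1,\dots,M,\; M = n_A n_B,$$

where $X_{i,j,k}$ is the log-scale expression of probe $i$ in sample $j$ of
group $k$. Within each of the $M$ comparisons the probes are ranked — rank 1
is the largest $Y$ for the "A &lt; B" alternative, the smallest for
"A &gt; B"; ties receive the average rank — and the statistic is the
geometric mean rank

$$RP_i = \Big(\prod_{m=1}^{M} R_{i,m}\Big)^{1/M} \in [1, p].$$

The geometric mean (rather than the raw product) is used so that the
statistic has a sample-size-free scale: it is bounded by the number of
probes regardless of $M$, which is the scale on which published per-gene
rank products for a 19 273-probe universe (values in the hundreds to
thousands) are interpretable. It is computed in log space to avoid
overflow at realistic $M$.

"Ranking among $M$ comparisons" is read as *for each of the M comparisons,
rank across probes* — the standard rank-product construction; the
alternative reading (ranking a probe's own $M$ ratios against each other)
would make the statistic independent of the other probes and could not
produce probe-universe-scale values.

### Permutation null and empirical p-value

The null distribution is generated by permutation: in each of $N_p$ rounds,
each probe's values across the pair's samples are permuted *independently
per probe* (`scheme = "per_probe"`, as the method describes), $RP^*$ is
recomputed identically, and

$$p_i = \frac{1}{N_p} \sum_{r=1}^{N_p} I\big(RP^{*(r)}_i \le RP_i\big).$$

Ties count as successes (conservative). The resolution is $1/N_p$, and a
probe stronger than every permuted statistic gets $p = 0$; with the study
default $N_p = 5000$ and the DE rule *strict* $p < \alpha = 0.001$, a probe
may have up to 4 exceedances and still be called. Options kept off by
default because they depart from the method as described, but exposed for
sensitivity analysis:

* `plus_one = TRUE` — the $(k+1)/(N_p+1)$ correction, which avoids exact
  zeros;
* `null = "pooled"` — compare $RP_i$ against the permuted statistics of
  *all* probes (the convention of the original rank-product literature);
* `scheme = "sample_label"` — permute whole sample labels (one permutation
  per round shared by all probes), preserving probe–probe correlation.

### Numerical and reproducibility choices

* **Tie comparison tolerance.** $RP^* \le RP$ is evaluated as
  $RP^* \le RP\,(1+10^{-9})$: two geometric means of *equal* rank multisets
  can differ in the last floating-point bit depending on summation order,
  and the tolerance makes such mathematical ties compare equal. $10^{-9}$
  is far below the smallest genuine separation (two rank vectors differing
  in one rank differ relatively by at least $\sim \log(1+1/p)/M$).
* **Random stream.** One seed per test; each round draws one $p \times n$
  uniform key matrix whose row-wise sort yields the per-probe
  permutations. Results are exactly reproducible given the seed and the
  matrix layout, but are not invariant to reordering probe rows (a
  per-probe stream would make them so at the cost of $p \times N_p$
  generator states; row-order dependence is the convention of mainstream
  permutation code). Both one-sided directions are computed from the *same*
  permutation draws, which halves the work and makes the two directions'
  p-values comparable round by round.
* **Down-direction ranks.** With average ties,
  $R^{up}_{i,m} + R^{down}_{i,m} = p + 1$ holds identically, so the down
  ranking is derived from the up ranking rather than re-sorted.

### A caution on per-probe nulls under strong effects

For a probe with a very large true effect, the per-probe permutation null
is *not* a "no-effect" null: permutations that happen to reassemble most of
the shifted values into one group reproduce a small $RP^*$. The probability
of such reconstitution events grows as group sizes shrink (for two groups
of 4 it is $1/70$ per round) and as the effect strengthens relative to
noise, because partial reassemblies then suffice. Consequences verified by
the test suite: sensitivity at strict $p < 0.001$ is high but not 1 even
for 2-log2-unit effects at 15 samples/group, and a *larger* effect (the NH
comparison sees twice the per-step effect) can recover *fewer* probes than
a smaller one. Users wanting a classical no-effect null should use
`null = "pooled"` or `scheme = "sample_label"`.

## 2. Pattern classification

Each pairwise test assigns a probe one of three statuses: `up` (significant
under the "&lt;" alternative), `down` ("&gt;"), `not-DE`. Probes significant
in at least two of NL, LH, NH are classified:

* exactly two significant — the two directions define an ordering chain
  over {N, L, H}; four combinations per test pair × three pairs = 12
  labels (`pattern_labels()`);
* all three significant — labeled by the NL and LH directions; when those
  agree in sign the NH direction must match, otherwise the probe is
  `"unclassified"` (kept, not dropped, so totals remain auditable). When NL
  and LH disagree (e.g. `N<L>H`) the N–H relation is unconstrained by the
  label and any NH direction is consistent.

The map is a pure function of the status triple; flipping all directions
maps every label to its mirrored-inequality partner (verified exhaustively
over all $3^3$ triples). The four at-least-two Venn regions (NL∩LH only,
NL∩NH only, LH∩NH only, all three) are reported with the calls and sum to
the size of the ≥2-tests set.

## 3. The synthetic-data generator

`generate_meta_dataset()` emulates what the meta-analysis assumes about a
multi-study GCRMA-style collection, and nothing more:

$$X_{ij} = \mu + \delta_{\text{pattern}(i),\,\text{group}(j)} +
  s_{\text{study}(j)} + \varepsilon_{ij},$$

with $s \sim \mathcal N(0, \sigma_s^2)$ drawn once per study,
$\varepsilon \sim \mathcal N(0, \sigma^2)$ i.i.d. on the log2 scale, and
planted probes' group offsets spaced by the stated effect size along their
ordering chain. Defaults, chosen once as a desk-scale rendition of a real
grouped GEO collection (normal 53 / low 32 / high 376 across ten studies):

| parameter | default | meaning |
|---|---|---|
| `group_sizes` | N=5, L=3, H=12 per study | mimics the 53/32/376 imbalance scaled down |
| `n_studies` | 3 | several independent baselines |
| `baseline_mean` | 6 log2 units | mid-range GCRMA intensity |
| `noise_sd` | 1.0 log2 units | within-group biological+technical spread of tumor cohorts |
| `study_shift_sd` | 0.5 log2 units | between-study baseline offset surviving normalization |

The within-group variance of the real cohorts is not published, so
`noise_sd` is a free parameter: 1.0 reflects heterogeneous tumor
collections; the planted-pattern recovery example and acceptance scenario
use 0.5, the generator's documented planted-example world. Because only
additive structure on the log scale matters to rank products, the model is
additive Gaussian; it deliberately does **not** emulate probe-level
cross-hybridization, intensity-dependent variance, chip spatial artifacts,
probe–probe correlation, or heavy-tailed outliers. A green recovery test
therefore establishes correctness of the statistics pipeline under the
stated model — not robustness to microarray pathology.

Under a null spec (no planted probes) all samples of a study are
exchangeable across groups by construction, so empirical p-values must be
uniform to resolution $1/N_p$; the acceptance suite checks this at
$p = 2000$ probes, 10+10 samples, $N_p = 1000$ (KS at $\alpha = 0.01$ and
binomial bounds on the DE fraction at $\alpha = 0.001$).

## 4. Biopsy cohort statistics

The packaged cohort (42 surgical samples: log-scale microarray expression
for all, qRT-PCR/β-actin ratio for 20, tumor type and WHO grade) drives
three analyses, with these conventions:

* **Grade groups.** Metastatic samples excluded; grades I–II = low (19),
  III–IV = high (13). For qRT-PCR, absent ratios are dropped but the one
  literal zero ("non-detected") is retained — low n=12, high n=8. The Welch
  test runs on the raw (not log) ratios; this is the only convention under
  which the published t = 2.21 reproduces, and the published P = 0.031 is
  the corresponding one-tailed value.
* **Tissue groups.** meningioma (15); astrocytoma = pilocytic + grade II +
  gemistocytic + anaplastic astrocytoma (4); glioblastoma (11);
  adenocarcinoma = the ten metastatic carcinomas; anaplastic ependymoma and
  haemangioblastoma fit no group and are excluded (40 analysed). This
  membership is the one that reproduces the published astrocytoma mean
  11.30 and every pairwise mean difference.
* **Tukey–Kramer.** Adjusted p from the studentized range with the
  unequal-n standard error $\sqrt{(MSW/2)(1/n_i + 1/n_j)}$; differences
  follow the column-vs-row sign convention; at equal group sizes the
  procedure reduces to classical HSD (tested against `TukeyHSD`).

Three discrepancies in the published tables, found while validating the
fixture, are documented rather than patched:

1. the one-row tissue summary prints the meningioma and adenocarcinoma
   means transposed relative to direct computation from the per-sample
   table (6.58 vs 7.32); the per-sample table is authoritative here, and
   the pairwise differences confirm it;
2. the published astrocytoma–glioblastoma cell (0.56) has the sign opposite
   to the convention obeyed by every other cell; it is treated as an
   absolute difference;
3. the published astrocytoma sd (0.85) does not recompute from the four
   astrocytic samples (which give 0.92); it appears to duplicate the
   glioblastoma sd.

The cohort ANOVA illustrates a precision limit: the per-sample expression
values are printed to 2 decimals, and an $10^{-8}$-scale F-tail is
hyper-sensitive at that precision — the printed values give
F = 22.64, P = 2.06×10⁻⁸ where the publication states 2.20×10⁻⁸
(F = 22.52, a 0.5 % difference well within input rounding). The acceptance
test asserts the published 3-significant-figure value and is expected to
fail by this margin; the discrepancy is an input-precision artifact, not an
implementation defect. Published Tukey tail p-values differ similarly
(order-of-magnitude at the 10⁻⁶ scale), so the significance *pattern* at
the stated 0.01 threshold is asserted instead.

The genome-wide moderated t-statistic context in which the cohort's
low-vs-high microarray test was originally run is not reproducible from a
single gene's values and is out of scope; `bh_fdr()` provides the
Benjamini–Hochberg step-up generically for any p-value vector.

## 5. Growth kinetics

Caliper pairs give the modified-ellipsoid volume $V = \pi L W^2 / 6$;
doubling time is $\ln 2 / b$ with $b$ the OLS slope of $\ln V$ on day.
OLS is the stated estimator; no weighting options are offered. A slope
$\le 10^{-12}$ per day is reported as non-growing (`NA` doubling time)
rather than an error or an absurd number — the threshold only absorbs
floating-point noise on exactly flat series. Group comparison is a pooled
two-sample two-tailed t-test by default (Welch by flag); the estimator
behind the published group comparison is unstated, and pooled is the
conventional default at equal n.

No per-animal series were published, so the growth acceptance criterion is
property-based: exact recovery on noise-free exponentials, and ≥80 % power
to separate groups simulated from the published summaries
(8.12 ± 0.72 vs 6.11 ± 0.98 days, n = 6/group) at the 0.05 level. The
simulated series place between-animal variation on the true doubling time
and small (σ = 0.05) lognormal noise on measured volumes.

## 6. Known limitations

* The per-probe permutation null inflates p-values of extremely strong
  effects (Section 1); this is faithful to the described method, and the
  pooled null is available where a no-effect null is wanted.
* Permutation results depend on probe row order (documented stream design).
* The generator's Gaussian world cannot certify behavior on real arrays
  with correlated probes or outliers.
* Probe-to-gene annotation, normalization (GCRMA), and download clients
  are out of scope by design: the pipeline starts from normalized
  log-scale matrices with group labels.
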