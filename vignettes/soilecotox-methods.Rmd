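---
title: "Methods: soil ecotoxicological indices and dose-response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil ecotoxicological indices and dose-response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilecotox)
```

## The assessment problem

Fungicides applied to cropland accumulate in soil, where they can depress
the microorganisms and extracellular enzymes that drive nutrient cycling.
The standard laboratory assessment treats replicated soil samples with a
dose series of the active ingredient (here 0, 0.075, 2.25, 11.25 and
22.50 mg kg⁻¹ dry soil of azoxystrobin, 0.075 being the recommended field
rate), incubates them for 30–90 days, and tracks three families of
endpoints: culturable microbial counts, community biodiversity indices,
and enzyme activities condensed into stability indices. This package
implements those endpoints and the statistics used to summarize them, on
top of tidy long-format tables (`dose`, `time`, `replicate`, `variable`,
`value`).

## Biodiversity indices from colony emergence

Diluted soil suspensions are plated and newly visible colonies are
counted each day for a 10-day window, giving counts $N_1,\dots,N_{10}$
and fractions $p_d = N_d / \sum_j N_j$. Two indices condense the profile:

$$\mathrm{CD} = 100 \sum_{d=1}^{10} \frac{p_d}{d}, \qquad
  \mathrm{EP} = -\sum_{d} p_d \log_{10} p_d .$$

CD weights early emergence: it is 100 when every colony appears on day 1
(pure fast-growing r-strategists) and $100/10 = 10$ when everything
appears on day 10. EP is a Shannon-type evenness; with base-10 logs and a
10-day window it spans $[0, 1]$, reaching 1 on a uniform profile.

Two formulation details are deliberate. First, the index is computed on
the *fractions* $p_d$, not the raw counts: raw counts would make CD
unbounded and scale-dependent, whereas all reported CD values in this
assessment tradition lie in $[10, 100]$. Second, the EP logarithm base is
an explicit parameter defaulting to 10, the only base for which the
10-day uniform profile scores exactly 1. An all-zero profile raises an
error rather than returning a number: the index is undefined with no
colonies.

## Resistance and resilience of soil parameters

For a parameter measured in control ($C$) and treated ($P$) soil, with
$D_0 = C_0 - P_0$ at the baseline time and $D_x = C_x - P_x$ at a
follow-up time, the Orwin–Wardle indices are

$$\mathrm{RS} = 1 - \frac{2|D_0|}{C_0 + |D_0|}, \qquad
  \mathrm{RL} = \frac{2|D_0|}{|D_0| + |D_x|} - 1 .$$

RS is 1 for an unaffected parameter, 0 when the parameter is fully
suppressed, and approaches −1 for extreme stimulation; it is symmetric in
the sign of the change. RL is 1 on full recovery, 0 when the disturbance
is unchanged, negative when it grew. `index_tables()` applies RS at every
sampling time using that time's own control, and RL between the earliest
and latest times, matching how the fixture tables were produced.

Degenerate RL inputs need a policy: with $D_0 = 0$ the formula returns −1
regardless of $D_x$. When the follow-up is also undisturbed
($D_x = 0$) there was never anything to recover from, so the package
returns a flagged `NA` with a classed warning instead of the misleading
−1; when a disturbance appears only at follow-up ($D_0 = 0$, $D_x \ne 0$)
the limit −1 is returned, with a warning.

## The PEC dissipation model

The predicted environmental concentration table in the source is
consistent with dose-proportional shared first-order decay, which the
package adopts as its model:

$$\mathrm{PEC}(d, t) = f \, d \, e^{-kt}, \qquad DT_{50} = \ln 2 / k,$$

fitted as an ordinary least-squares regression of
$\log \mathrm{PEC} - \log d$ on $t$ (all doses pooled). On the packaged
grid this gives $k = 0.00834\ \mathrm{day}^{-1}$, $DT_{50} = 83.2$ days.
The half-life is sensitive to the lowest-dose row, whose printed cells
carry only two significant figures; excluding or down-weighting that row
gives $k \approx 0.0082$ ($DT_{50} \approx 84.5$ d). The default remains
the plain unweighted fit over all printed cells, with a `weights`
argument for sensitivity analysis.

### Precision-aware consistency checks

`pec_consistency()` verifies dose-linearity (per time column,
`value/dose` against the column median) and shared decay (per dose row,
consecutive-time ratios against the fitted $e^{-k\Delta t}$) at a 0.5 %
relative tolerance. A printed cell, however, only carries its
quantization step, and these tables demonstrably truncate some cells, so
the printed error can reach one full unit in the last place — for the
0.0029 mg kg⁻¹ cell that is 3.4 % of the value, far beyond any 0.5 %
test. Cells whose full-ulp propagated uncertainty exceeds the tolerance
are therefore held to their quantization bound instead, and the report
says which bound applied. On the packaged grid every ≥3-significant-figure
comparison passes at 0.5 % and the two quantization-limited lowest-dose
comparisons pass their printed-precision bound.

## Dose–response statistics

**Correlation.** `dose_correlation()` is plain Pearson correlation on the
raw dose scale with a two-sided t-test flag at p = 0.01, the convention
of this assessment literature. Count and activity tables include the
dose-0 control in the sequence; RS/RL tables cannot (the indices are
undefined at dose 0), so their correlations use the four treated doses.
Both conventions reproduce the printed coefficients (−0.993 for urease
day 90; −0.996 for the dehydrogenase RL row). Note that a 5-point
correlation needs $|r| > 0.959$ to reach p < 0.01; correlations over
replicate-level observations reach significance much more easily, which
is how the source's starred coefficients should be read.

**Variance partition.** `eta_squared()` decomposes a complete dose × time
factorial into dose, time, interaction (and, with replicates, error) sums
of squares and reports $\eta^2 = SS/SS_{total}$ in percent. Run on a
means grid the error stratum is empty and the shares only approximate a
replicate-level partition; the package documents this rather than
pretending otherwise. The dose share for alkaline phosphatase (0.6 %)
reproduces the published figure from the means grid; the time share
differs in the last digit (99.1 % vs 99.0 %), as expected for a
means-level approximation.

**Compact letter display.** `tukey_letters()` builds homogeneous groups
from the Tukey HSD adjusted p-value matrix with the insert-and-absorb
algorithm: one letter initially covers all groups; every significant pair
splits each letter containing both members; letters that become subsets
of others are absorbed. The invariant — two groups share a letter iff
their comparison is non-significant — is tested against an exhaustive
pairwise oracle on randomized layouts of up to 6 groups. The published
letters themselves are not reproduced: they require the unpublished
replicate-level data.

**Clustering and PCA.** `ward_cluster()` z-scores each feature, drops
constant features with a warning, and applies Ward's minimum-variance
linkage; the classic dialect (squared Euclidean distances, `ward.D`) is
the default, with `ward.D2` selectable — both give identical merge
orders. On the packaged count profiles the top split isolates fungi from
the two bacterial groups, matching the published dendrogram.
`pca_variance()` performs correlation-matrix PCA (variables standardized)
and reports explained-variance percentages.

### A known irreproducible figure

The source states that the first two principal components of the
resistance matrix carry 93.78 % of total variance. From the printed
12 × 5 RS matrix this is not reproducible under any standard dialect:
correlation PCA gives 80.42 %, covariance PCA 90.54 %, and transposed or
re-blocked layouts 83–94 % but never 93.78. Like the Tukey letters and
the η² ranges, that figure evidently derives from replicate-level values
that were never published. The package keeps correlation PCA as the
default (the convention of the Statistica software family used in this
literature), and its acceptance test records the discrepancy as a failing
expectation rather than hiding it.

## The synthetic world

`synthetic_config()` pins a generative model whose *structure* mirrors
the real experiment; it emulates signs, orderings and noise scale, not
the exact published values.

- **Layout**: the published design — 5 doses, 3 times, 9 enzyme
  replicates, 3 count replicates.
- **Enzyme activities**: $A = A_0(t)\,(1 - I_{max}\, d/(d + K_{50}))\,
  e^\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. Saturating
  inhibition is used because the published activities decline
  sub-proportionally at high doses. Baselines $A_0(t)$ default to the
  published control row; per-enzyme $I_{max}$ defaults
  (0.07–0.32) are the observed top-dose relative declines;
  $K_{50} = 5$ mg kg⁻¹ puts half-saturation inside the dose range;
  $\sigma = 0.05$ (log scale) gives means-table variation comparable to
  the published inter-dose spread. Replicate dispersion in the real
  experiment is unknown (only the Tukey letters reflect it), so
  $\sigma$ is a convention, not an estimate.
- **Counts**: $\mu(t) + \beta \log_{10}(1 + d/d_{ref}) + N(0,
  \sigma_c^2)$ in log₁₀ CFU, with baselines from the published control
  row and slopes scaled to the observed top-dose deltas (fungi steepest,
  $\beta = -0.3$).
- **Emergence**: multinomial over days 1–10 with day distribution
  $w(d)\,\mathrm{fast} + (1 - w(d))\,\mathrm{slow}$; fast is a
  geometric-decay profile peaking on day 1, slow a late-peaked profile
  centred on day 7, and $w(d) = w_0/(1 + d/5)$ with $w_0 = 0.9$, so
  increasing dose shifts the community toward slow growers and lowers
  the expected CD monotonically.

All generators are pure functions of the configuration (including its
seed); emergence profiles use a dose-indexed sub-seed so profiles at
different doses are independent yet individually reproducible. A green
synthetic test therefore establishes that the pipeline recovers the
structure it assumes — monotone dose responses, significant
replicate-level correlations, parameter recovery within stated bounds —
and nothing about any particular real soil.

## Numerical choices and degenerate inputs

- Printed fixture values are stored as printed and frozen by checksum;
  re-derived report values are compared round-half-even at the printed
  precision, with an explicit annotation when only the truncated
  rendering matches (the source contains such cells, e.g. a mean of
  0.1196 printed as 0.119).
- Parameter recovery profiles the per-time baselines out analytically
  and optimizes only $(I_{max}, \log K_{50})$ with L-BFGS-B from a
  coarse start grid, followed by a Nelder-Mead polish; noiseless data are
  recovered to ≤ 1e-6 relative, and a brute-force grid oracle agrees
  with the optimizer in the tests.
- Ranking ties in `summarize_index()` break by group label order; empty
  groups report `NA`, never 0.
- Validation failures raise classed conditions (`soilecotox_*`) naming
  the offending column, row or key.

## Limitations

- Replicate-level quantities of the source (Tukey letters, starred
  correlation coefficients, η² ranges, the 93.78 % PCA figure, the RS
  table itself) cannot be recomputed from printed means; the package
  serves them as-printed and says so per cell.
- The PEC model is an empirical decay fit, not fungicide chemistry; no
  leaching, sorption or metabolite formation.
- RS/RL are computed at the means level; no uncertainty propagation is
  attempted because the source publishes no replicate dispersion.
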