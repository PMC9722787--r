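---
title: "Methods: estuarine water quality, plankton community and diet electivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estuarine water quality, plankton community and diet electivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodiet)
```

## Scope and data model

The package analyses a seasonal estuarine monitoring programme with three
kinds of input, exchanged as tidy CSV tables: a per-site, per-date panel
of ten physico-chemical parameters (temperature, salinity, DO, pH,
NO~3~-N, NO~2~-N, NH~4~^+^, PO~4~/DIP, dissolved silica, chlorophyll-a);
depth-ordered CTD salinity casts with an along-axis coordinate; and
genus/phylum-resolved phytoplankton counts from water tows and from the
guts of individual fish. Dissolved inorganic nitrogen is derived as
DIN = NO~3~-N + NO~2~-N + NH~4~^+^, with the ammonium fraction tracking
the dominant species of the pool.

Seasons follow the monsoonal flow cycle: December–March is the dry (low
flow) season and July–October the wet (high flow) season. Records from
other months are labelled *transitional* and excluded from seasonal
contrasts — the pre-monsoon (April) and early-monsoon (June) surveys sit
between regimes and assigning them to either season would dilute a paired
test. Missing values are propagated and deleted pairwise; nothing is
imputed.

The `counts.csv` schema carries an optional `date` column (filled by the
generator) so that compositions can be split by season; readers accept
tables without it and then pool across seasons.

## Hydrography

**Stratification.** For each cast, `s_sur` and `s_bot` are the first and
last recorded levels (not fixed depths — monitoring casts rarely hit
exactly the same grid), and

$$n_s = \frac{S_{bot} - S_{sur}}{\tfrac12 (S_{bot} + S_{sur})}$$

classifies the column as well mixed ($n_s < 0.1$), partially mixed
($0.1 \le n_s \le 1$) or stratified ($n_s > 1$). The depth-mean in the
denominator is the standard definition; a difference rather than a sum
there would make $n_s \equiv 2$ for any column and could never produce
the near-zero values a homogeneous 13 PSU column must give. When both
levels are fresh ($S_m = 0$) the ratio is undefined and the cast is
flagged rather than classified. $n_s$ is invariant to relabelling depths
and to rescaling salinity, which the test suite checks as properties.

**Venice zonation.** Salinity classes use half-open intervals closed on
the low side — [0, 0.5) freshwater, [0.5, 5) oligohaline, [5, 18)
mesohaline, [18, 30) polyhaline, [30, ∞) euhaline — because the published
ranges overlap at their endpoints and a total, monotone step function
needs one convention. 0.5 PSU is therefore oligohaline.

**Salt intrusion.** The 2 PSU near-bottom isohaline is located by linear
interpolation of bottom salinity against the axis coordinate at the first
landward crossing; an exact hit returns that cast's position, and a
section entirely on one side (the fresh wet-season estuary) returns
`NA`. Lists of casts supplied by the user must already be sorted seaward;
long-format tables are sorted internally since they carry the coordinate.

**Habitat.** Hilsa habitat windows are nested: spawning requires
< 0.1 PSU, juvenile nursery ≤ 1 PSU, brood fish ≤ 2 PSU, so suitability
only ever shrinks as salinity rises.

## Plankton metrics

Chlorophyll-a uses the trichromatic SCOR-UNESCO form with coefficients
(11.64, −2.16, 0.10) on the 663/645/630 nm bands, each blanked against
750 nm for turbidity, scaled by extract volume (mL) over filtered volume
(L) × path length (cm). The cited method names the equation without
printing it; the coefficients are taken from the standard. Noisy blanks
can push the estimate below zero, in which case it is floored at 0 with a
warning. Sedgwick–Rafter densities are
`cells / (fields × field volume) × 1000 / concentration factor`, with all
chamber geometry configurable since the original counting equation is not
reproduced in the source describing it.

Simpson's index is implemented in the dominance orientation,
$D = \sum n_i(n_i-1) / N(N-1)$ in exact integer arithmetic — the
probability that two individuals drawn *without* replacement are
conspecific — so 1 is a monoculture and values near 0 are diverse; the
reciprocal is always computed from the unrounded $D$. Published tables
that round $D$ to two decimals cannot be inverted to their printed
reciprocals (0.17 vs 5.80), which is why reproduction tests target median
columns only and the package never derives one rounded figure from
another. Whether seasonal indices should be computed on pooled counts or
per sample and then medianed is genuinely ambiguous in field practice;
`diversity_by()` offers both, with pooled as the default.

## Electivity

The odds-ratio index compares the gut share $g_i$ with the environmental
share $a_i$:

$$O_i = \frac{g_i}{1-g_i}\cdot\frac{1-a_i}{a_i}, \qquad
  X_i = \frac{O_i}{1+O_i}.$$

$X$ is 0.5 exactly when $g = a$ (the implementation uses the product form
$g(1-a) / ((1-g)a)$, which cancels exactly in floating point at the null),
1 when the taxon is the only prey, 0 when it is never eaten, strictly
increasing in $g$ and decreasing in $a$, and obeys the reciprocal identity
$X(g,a) = 1 - X(1-g, 1-a)$ on interior points. Degenerate environmental
proportions ($a = 0$ or $1$) are errors by default; the optional
Haldane–Anscombe-style correction adds 0.5 to every taxon count in both
pooled samples before forming proportions, keeping the index defined for
taxa seen in only one source. The taxon universe is the union of water
and gut taxa, and fish are binned by fork length into small [10, 20),
medium [20, 30) and large [30, 35] classes (last bin closed); fish outside
all bins are excluded with a warning.

## Trophic state

Each indicator is summarised by a percentile of its seasonal values —
DIN and DIP at the 80th, dissolved silica at the 10th, chlorophyll-a at
the 90th — using linear interpolation between order statistics (quantile
type 7; the convention is configurable because the classification sources
cite percentiles without one). Class bounds: DIN good < 0.1 ≤ fair < 1
≤ poor (mg/L); DIP good < 0.01 ≤ fair < 0.1 ≤ poor; silica reversed,
good > 5 ≥ fair > 2 ≥ poor (diatom blooms *deplete* silica, so more is
better); chlorophyll-a good ≤ 5 < fair ≤ 20 < poor ≤ 60 < very poor
(µg/L). The published nutrient ranges leave exact boundaries ambiguous
("≥ 0.1 but < 1" next to "> 1" excludes 1.0 itself); boundaries resolve
upward, so DIN = 1.0 is poor. A coarser three-state biomass-only scheme
(`chla_estuary_class()`, boundaries at 5 and 20 closed on the left) is
kept alongside the four-state table because both appear in monitoring
practice.

## Panel statistics

Seasonal contrasts use the paired Wilcoxon signed-rank test with the
*site* as pairing unit: within-season replicates are averaged per site
first, and sites observed in both seasons are matched (12 sites in the
default design). The exact null distribution is used up to 25 pairs,
falling back to the tie-corrected normal approximation when zeros or ties
force it. Spatial contrasts use Kruskal–Wallis across stations.
Correlations are Pearson with two-sided t-tests, starred at 0.05 / 0.01 /
0.001 and deleted pairwise; no multiple-testing correction is applied
across the 45 pairs, matching the starred-matrix presentation convention
(a Holm adjustment can be applied downstream if desired).

PCA operates on the correlation matrix — with parameters in mixed units
(°C, PSU, mg/L, µg/L) covariance PCA would be dominated by scale, so
standardisation is the only defensible choice. The full spectrum is
computed; four components are retained for reporting. Eigenvector signs
are fixed by making each component's largest-magnitude loading positive,
so loadings are reproducible across linear-algebra backends. Components
beyond the numerical rank are zeroed and flagged. Variable contributions
are squared unit loadings × 100, summing to 100 per dimension;
`scores %*% t(loadings)` reconstructs the standardised data exactly at
full rank.

## PUFA attribution

Phylum-level PUFA fractions of total fatty acids come from published
meta-analysis: green algae 60%, diatoms 28%, blue-green algae 26%.
Season-level gut compositions are averaged *unweighted* across dry and
wet (this is the convention that reproduces published headline numbers;
fish-weighted averaging is not reconstructable without per-fish season
labels), sums over phylum subsets are taken on unrounded averages, and
rounding happens last. Reported percentages round half-up at one decimal:
inputs carried at one decimal produce exact halves (45.8 and 61.5 average
to 53.65) that IEEE round-to-even would send down to 53.6, whereas the
field convention rounds up to 53.7; the implementation nudges by 10^-8^ —
far below data resolution — before rounding. The composition-weighted
PUFA score restricts to annotated phyla, renormalises, and reports both
the score and the annotated mass so a low-coverage composition cannot
masquerade as a well-characterised one.

## The synthetic generator: what it does and does not emulate

`scenario_spec()` states the world once: five stations (UE, ME, LE, CK,
HI) at 0/30/60/95/100 km with 2/2/2/3/3 sites, dry months
December–March and wet months July/August/October, per-station seasonal
medians and standard errors for all ten parameters, seasonal percent
compositions for water tows and guts, 90 fish of 18–35 cm, water-sample
totals of 16.2–94.1 ×10³ (dry) and 10.3–215.1 ×10³ (wet) cells/L, and
50–500 prey per gut (per-fish totals are not published anywhere; this
range is a declared stand-in).

Each panel value is drawn from a normal law centred on its seasonal
station median with spread `se × √n_eff` (default n_eff = 6, the
approximate replicate count behind a published standard error), truncated
at zero, at 14 for pH, and below 0.5 PSU for wet-season salinity — the
structural claim that the estuary runs fresh in the monsoon. Setting
`n_eff = 0` degenerates every record to its median, which the descriptive
tests exploit. Dry CTD sections interpolate bottom salinity linearly from
0.15 PSU at the head to exactly 13 PSU at the seaward end and build each
cast with a surface-to-bottom difference below 1% of the depth mean, so
the stratification parameter is below 0.01 *by construction*; wet
sections are uniformly below 0.15 PSU. Counts are multinomial at phylum
level with probabilities equal to the configured percents renormalised to
one (the within-season published percents sum to 92, 85, 84.08 and 98,
not 100; the renormalisation factor is recorded on the output), then
split uniformly across each phylum's genus list — genus identity carries
no signal.

A green test on synthetic data therefore establishes that the analysis
recovers the contrasts the generator encodes (seasonal shifts in
salinity/temperature/DO, the spatial salinity gradient, well-mixed
columns, composition ratios, the electivity null), not that any real
estuary behaves this way. The generator has no tides, no
advection–dispersion, no autocorrelation between months, no
genus-level ecology, and truncated-normal rather than skewed noise —
real nutrient panels are typically right-skewed, so real-data p-values
and PCA variance fractions will differ from synthetic ones. Published
PCA variance percentages and real-panel test p-values depend on the
unreleased raw data and are deliberately not reproduction targets.

## Numerical conventions and edge cases

* Quantiles: type 7 (linear interpolation); medians of even-length
  vectors average the central pair.
* Wilcoxon: all-zero difference vectors return p = 1 directly (the test
  statistic is degenerate); the type-I calibration fixture uses 14 pairs,
  chosen a priori because the exact two-sided attainable level there
  (0.0494) is closest to the nominal 0.05 among small panels.
* Electivity: `g = 1` maps to X = 1 with an infinite odds ratio rather
  than an error; `g = 0` to X = 0.
* Simpson: N < 2 is an error (the formula divides by N−1); zero-count
  rows are dropped and do not affect D.
* PCA: eigenvalues below 10^-10^ of the largest are treated as rank
  deficiency; affected components are zeroed and the rank reported.
* Stratification with an inverted profile (fresher at depth) yields a
  negative `n_s`, which falls below the 0.1 threshold and classifies as
  well mixed; the sign itself surfaces the inversion, which is rare in
  this setting.
* All generators consume a fixed number of RNG draws per record so that
  identical seeds give byte-identical outputs.

## Known limitations

Bootstrap confidence intervals for electivity, alternative indices
(Ivlev, Chesson, Manly), multi-indicator trophic syntheses (ASSETS/TRIX),
varimax rotation, and tidal or hydrodynamic structure in the generator
are out of scope. The gut prey-total range and the genus-level uniform
split are declared conventions, not estimates.
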