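---
title: "A two-stage habitat model for sticky-egg spawners under reservoir drawdown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage habitat model for sticky-egg spawners under reservoir drawdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickyhab)
```

## The problem

Phytophilic spawners such as carp (*Cyprinus carpio*) and crucian carp
(*Carassius auratus*) attach adhesive eggs to submerged vegetation in the
shallow littoral zone of reservoir tributaries. Spawning success depends on
the usual hydraulic preferences — low velocity, shallow depth, warm water —
but hatching success depends on something a conventional habitat suitability
model ignores: the water level must not recede below the eggs before the
larvae can swim. Egg incubation plus the attainment of free-swimming takes
about five days; an egg stranded at any point in that window desiccates and
dies, even if the water later returns. Flood-season drawdown of large
reservoirs therefore decouples *spawning* suitability (where eggs can be
laid) from *hatching* suitability (where they can survive), and `stickyhab`
models the two stages separately.

## The model

### Factor suitability curves

Each environmental factor maps to a suitability index $SI \in [0, 1]$
through a piecewise-linear curve. The three hydraulic factors use
trapezoidal curves: suitability 1 over the empirically optimal range,
falling linearly to 0 at the limits of the observed range, 0 beyond. The
package defaults, from littoral spawning-site surveys of carp and crucian
carp, are:

| factor       | support     | optimum    | units |
|--------------|-------------|------------|-------|
| velocity     | 0 – 0.5     | 0 – 0.2    | m/s   |
| depth        | 0.2 – 0.8   | 0.4 – 0.6  | m     |
| temperature  | 15 – 30     | 20 – 23    | °C    |

The velocity optimum shares its lower edge with the support limit, which
would make the edge rules contradictory (limits get 0, optima get 1). The
package resolves this *degenerate limb* in favour of the optimum: still
water is these species' preference, so $SI_V(0) = 1$ and there is no left
limb. Evaluation outside a curve's knot span clamps to the edge value (1 on
a degenerate-limb side, 0 otherwise).

### The drawdown suitability index $SI_L$

The novel factor is the cumulative water-level drop over the 5-day
incubation window. Deposition depths of 163 field-observed egg clutches
fall into seven bins between 0 and 0.8 m (packaged as
`egg_depth_reference()`; the modal bin 0.4–0.5 m holds 33.1% of
observations). An egg deposited at depth $z$ below the spawning-day surface
survives a drop $d$ iff $z > d$, so

$$ SI_L(d) = 1 - F(d), $$

where $F$ is the cumulative deposition-depth distribution computed from the
raw counts. With eggs uniform within bins, $F$ is piecewise linear between
bin edges, so $SI_L$ has knots at $d = 0$ and every bin upper edge:
$SI_L(0) = 1$, $SI_L(0.2) = 1 - 1/163 \approx 0.994$, and $SI_L(d) = 0$ for
$d \ge 0.8$ m. Raw counts, not the table's rounded percent column, define
the knots: the rounded percents sum to 100.1% and would make the curve
internally inconsistent. Rising water (negative drop) strands nothing, so
$SI_L = 1$ there.

The realized drop on spawning day $t$ is

$$ D(t) = \max\!\big(0,\; L(t) - \min_{k = 1..w} L(t+k)\big), \quad w = 5, $$

the deepest excursion below the spawning-day level during the forward
window, not simply $L(t) - L(t+w)$: stranding is irreversible, so the
window minimum governs even when the level recovers. For monotone declines
— the cases that matter for regulation advice — the two definitions
coincide; `five_day_drop(method = "endpoint")` exposes the endpoint variant
for sensitivity analysis. Days without a full forward window carry no value
and are excluded from period means rather than padded.

Inverting the curve gives regulation advice: the smallest drop with zero
suitability (0.8 m for the reference table) divided by the window length is
the fastest sustainable constant decline,
`max_sustainable_daily_decline()` = 0.16 m/day for a 5-day window.

### Per-cell HSI and weighted usable area

For each mesh cell $i$ with area $A_i$, the factor suitabilities combine
into stage-specific habitat suitability indices:

$$ HSI_i^{spawn} = (SI_V SI_H SI_T)^{1/3}, \qquad
   HSI_i^{hatch} = (SI_V SI_H SI_T SI_L)^{1/4} $$

in the default `geometric_mean` mode. A plain-`product` mode
($HSI = SI_V SI_H SI_T$, $\times SI_L$ for hatching) is also provided, and
the choice is recorded in every output file. The geometric mean is the
conventional combination in habitat suitability modelling, but the two
modes differ materially in one respect: only the product mode guarantees
$WUA_{hatch} \le WUA_{spawn}$ with equality exactly when $SI_L = 1$,
because multiplying by a fourth factor and taking a higher root can raise a
sub-unity score (e.g. $SI$s of $0.5, 0.5, 0.5, 1$ give spawning HSI $0.5$
but hatching HSI $0.5^{3/4} \approx 0.59$). Narratives in which hatching
habitat tracks at-or-below spawning habitat and converges to it when
drawdown pauses are strictly consistent only with the product
interpretation; users comparing stages should prefer `mode = "product"`.
$SI_L$ is a spatially uniform scalar per date, derived from a single stage
gauge; a per-cell hook would be a straightforward extension but is unused.

In either mode a zero factor annihilates the HSI, and HSI is non-decreasing
in every factor. Dry cells (depth 0) get $SI_H = 0$ through the depth
curve's support, hence HSI 0, with no special-casing.

Aggregates per date are the weighted usable area
$WUA = \sum_i A_i \, HSI_i$ (m²), per-stage class-area fractions over the
five conventional classes (very low [0, 0.2), low [0.2, 0.4), medium
[0.4, 0.6), high [0.6, 0.8), very high [0.8, 1]; boundaries go to the upper
class, 1.0 is very high), and the relative spawning-to-hatching change per
class. Note that per-class relative change uses the plain formula
$100(\text{hatch} - \text{spawn})/\text{spawn}$ on the computed fractions;
aggregation schemes that average pre-rounded yearly tables can give
different values.

## The synthetic-data generators

Real bathymetry and multi-decade gauge records for a specific tributary are
not distributable with the package, so `stickyhab` ships generators that
emulate their statistical structure; every module is exercised end-to-end
against them.

**Stage series** (`gen_stage_series()`): the `post_dam` regime draws daily
level changes from a normal distribution around the month's mean decline
(defaults: April −0.22 m/day, May −0.32 m/day, spread 0.08 m/day),
truncated at the regime's largest observed daily drop (−0.61 m/day) and at
a small admissible rise — the minimal distribution consistent with
mean/extreme statistics. The `pre_dam` regime is generally stable:
level = baseline + a rainfall-pulse component + small Gaussian noise, where
pulses arrive with probability 0.2/day, raise the level by 0.4–2.4 m, and
decay by 30% per day, producing the characteristic rise-then-recession
pattern of a monsoon-season natural regime. With these defaults the
pre-dam April–May mean $SI_L$ is about 0.6 and 5-day drops below 0.8 m are
common, whereas the post-dam regimes force mean $SI_L$ near 0 — a starker
contrast than a real record, whose within-month variability (stable spells
inside a drawdown month) the generator deliberately does not model; the
day-to-day spread is exposed as a free parameter instead of guessed.

**Hydraulic fields** (`gen_hydro_field()`): cells scatter over a
longitudinal axis (depth increasing downstream toward the impoundment,
0–14.5 m, with a concave $x^{0.7}$ profile and steep $|y|^4$ banks that
keep the shallow littoral fringe narrow), a cross-channel velocity profile
(~0.3 m/s core, < 0.2 m/s margins, a few fast riffle reaches, all within
0–1.4 m/s), and a longitudinal temperature gradient (upstream mean 22.9 °C
vs reservoir-cooled downstream 20.6 °C). Under the defaults a small but
nonzero fraction of cells falls in the jointly optimal window, high
spawning suitability (HSI > 0.6) covers roughly 2–3% of the area and the
very-low class about 97% — the fragmented-habitat structure typical of an
impounded backwater. No real bathymetry is emulated; spatial *pattern*
conclusions should not be read off these fields, only scale-free
statistical ones.

**Egg depths** (`gen_egg_depths()`) sample bins proportionally to the
reference counts with uniform within-bin placement — exactly the
distribution underlying the $SI_L$ curve, which is what makes the
Monte-Carlo cohort-survival check (`cohort_survival()`) an independent
oracle: survival of $10^5$ sampled eggs under a realized drop $d$ must
match $SI_L(d)$ within binomial error.

**Larvae densities** (`gen_larvae_density()`): captured larvae hatched from
eggs spawned about 5 days earlier, so density is proportional to
$SI_L(t-5)$ with mean-one multiplicative log-normal noise. At zero noise
the lagged Pearson correlation (`lagged_pearson()`, which shifts the
$SI_L$ record 5 days before correlating) is exactly 1; the default noise
(sdlog 0.8) was calibrated by simulation over pre-dam scenarios so the
recovered correlation falls in a moderate 0.4–0.8 band, bracketing the
~0.6 values reported from comparable field monitoring. Passing this check
shows the diagnostic recovers a known lagged signal under realistic noise —
not that any particular field correlation is reproduced.

## Numerical choices and degenerate inputs

- Curve evaluation is exact linear interpolation (`stats::approx`) between
  knots; constant policies apply outside the span; non-finite inputs are an
  explicit error, never a silent 0.
- Displayed suitabilities round half away from zero (`round_half_up()`), so
  $1 - 1/163$ prints as 0.994 at three decimals.
- Curve JSON is written with 17 significant digits, the minimum that
  round-trips IEEE doubles bit-exactly; CSV output uses 6 significant
  digits for cross-platform byte-stable files.
- Stage series reject gaps and duplicate dates, naming the offending dates;
  readers reject missing/non-numeric columns and non-positive cell areas
  rather than coercing.
- A drawdown curve that never reaches 0 has no finite regulation threshold
  and `max_sustainable_daily_decline()` says so; a constant $SI_L$ series
  makes the lagged correlation undefined and is refused (or flagged by the
  larvae generator).
- Truncated-normal draws use rejection sampling; the truncation bounds sit
  several standard deviations out under the default regimes, so the
  acceptance rate is ≈ 1.

## Problem sizes

The shipped tests and examples run the generators at 100–2000 cells,
30–61-day stage series, and $10^5$ egg-depth samples for the Monte-Carlo
checks — sizes at which every distributional property tested is already
stable; the model itself is $O(n)$ in cells and days and scales to full
river meshes.

## Known limitations

- The optimal factor ranges are taken as given (the packaged defaults are
  the field-derived ones); the package does not re-derive optima from raw
  observation sets, nor fit smoothed/spline or multivariate preference
  surfaces.
- Egg survival is a sharp depth threshold; no partial-exposure mortality,
  wave run-up, or substrate drying dynamics.
- $SI_L$ is gauge-uniform across the mesh; differential backwater response
  within a reach is not represented.
- Depth-averaged (2-D) hydraulics only: near-bed velocity refugia and
  vertical temperature structure, which can keep eggs viable where surface
  values look unsuitable, are out of scope.
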