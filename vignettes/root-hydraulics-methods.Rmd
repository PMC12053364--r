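---
title: "Modelling whole-root-system conductance in wheat: methods and design notes"
author: "rootkrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-root-system conductance in wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkrs)
```

# Scope

`rootkrs` links root system architecture of winter wheat to the hydraulic
conductance of the whole root system (Krs): a stochastic root-growth
simulator, an exact network solver for Krs with age-dependent segment
hydraulics, the pressure-chamber estimation chain used to measure Krs on
young plants, the breeding-trend statistics applied to shovelomics trait
panels, and a synthetic-data generator that reproduces the statistical shape
of both kinds of data so the entire pipeline is testable without any
external data.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the problem left genuine
freedom. All quantitative statements about package behaviour below are the
ones computed by the test suite and the `scripts/acceptance.R` /
`scripts/calibrate.R` scripts; nothing is asserted that the code does not
recompute.

# The growth model

A root system is represented as a forest of **segments** — short cylinders
with a length, radius, root type (seminal, crown or lateral), creation time
and a parent link — rooted at the collar. Growth is discretized in steps of
`dt` (default 0.5 d): at each step every active axis appends one segment
whose length is its elongation increment, so the final segment table *is*
the full growth trajectory and `rootSnapshot()` recovers the plant at any
earlier age by filtering on creation time.

Axis elongation follows the negative-exponential rule
$L(t) = L_{max}\,(1 - e^{-r_0 t / L_{max}})$ with age $t$ since axis
emergence, initial rate $r_0$ (cm d$^{-1}$) and asymptote $L_{max}$ (cm).
Axis dynamics:

* **Seminal roots**: the per-plant count is drawn from a normal
  distribution (rounded, at least 1) with the cultivar's mean and the
  across-plant standard deviation; root $i$ emerges at $i \times$ 0.4 d.
* **Crown roots** are tied to tillering: cohorts appear at the first-cohort
  day (default 12 d, the main stem standing for tiller zero) and then every
  phyllochron until the drawn final tiller count; each cohort contributes
  `crown_roots_per_tiller` roots (cumulative rounding, so the long-run total
  is tillers × ratio). The phyllochron is derived per cultivar as a fixed
  50-day tillering window divided by (final tiller count − 1): all cultivars
  finish tillering at about the same age, so fewer-tillering cultivars space
  their cohorts more widely. This matters for conductance dynamics, because
  late cohorts are young — hence short and hydraulically juvenile — at any
  evaluation age.
* **Laterals** initiate on seminal and crown parents at regular spacing
  (1/branching density) between the basal and apical unbranched zones; a
  lateral at distance $x$ emerges once the parent tip has passed
  $x +$ apical zone, plus a one-day lag.

Per-axis diameters are lognormal around the type mean with a default
coefficient of variation of 0.1 (within-type spread exists in scanned data
but its magnitude is not tabulated; 10% is typical of such scans).
Geometry is deliberately topological: the hydraulic model depends only on
topology, lengths, radii and ages. Straight-line 3D coordinates are
fabricated only on RSML export.

Numerical choices: increments below 0.01 cm are not recorded (the geometric
tail of the negative-exponential curve would otherwise generate thousands of
micrometre segments; the truncation loses well under 0.1% of axis length);
identical seeds give bit-identical segment tables; all internal lengths are
SI (m), file and table interfaces use cm/mm as labelled.

## Packaged cultivar parameters

Counts, diameters and branching density for the six packaged cultivars
(released 1895–2002) come from the measured panel (`wheatTraitPanel()`),
with standard deviations recovered from the standard errors at the midpoint
sample size. Elongation rates, maximum lengths and zone widths are not
measurable with shovelomics; the packaged values are **calibrated**, jointly
with the hydraulic defaults, against four documented whole-pipeline
anchors: day-70 total root length above 120 m (oldest cultivar) and 63 m
(most modern), day-10-12 Krs near the measured $1.3$ and
$0.7 \times 10^{-10}$ m$^3$ MPa$^{-1}$ s$^{-1}$, a ~3 orders-of-magnitude
rise of Krs over 70 days, and a ~50% time-averaged Krs deficit of the modern
cultivar. `scripts/calibrate.R` recomputes all four diagnostics from the
shipped defaults.

The release-year scaling of growth acts on the *asymptotic lengths only*
(1895 → 1.0 down to 2002 → 0.70), not on initial elongation rates: young
hydroponic plants of old and modern cultivars are similar in per-axis size
(the measured 10-12 d total lengths differ by ~20% while the 70-d simulated
systems differ two-fold), so the cultivar contrast must build up with age
through asymptotes, axis counts and tillering dynamics rather than through
juvenile growth speed.

# The hydraulic model

Water enters a segment radially across its surface (radial conductivity
$k_r$, m MPa$^{-1}$ s$^{-1}$, per unit area) and flows axially through the
xylem (axial conductance $k_x$, m$^4$ MPa$^{-1}$ s$^{-1}$). For a uniform
segment of length $l$ and radius $r$ terminated by a distal network of
conductance $K_{distal}$, the standing conductance seen from the proximal
end has the exact transmission-line form

$$K = \kappa\,\frac{K_{distal} + \kappa \tanh(\tau l)}
                 {\kappa + K_{distal}\tanh(\tau l)},\qquad
\tau = \sqrt{2\pi r k_r / k_x},\quad
\kappa = \sqrt{2\pi r k_r k_x}.$$

$\tau$ (m$^{-1}$) is the inverse of the characteristic exchange length and
$\kappa$ (m$^3$ MPa$^{-1}$ s$^{-1}$) the saturation conductance of an
infinitely long root. `computeKrs()` folds the segment tree from the tips to
the collar, summing children at junctions (ideal nodes, no junction
resistance) and applying the formula per segment; the collar is an ideal
node and the external medium is at uniform water potential (the hydroponics
assumption — soil resistance is out of scope). With $k_r = 0$ a segment
degenerates to a pure axial resistor and the series formula is used.

Each simulated segment carries a single creation time, so segments are
age-uniform at the growth resolution by construction and the solver needs no
further age subdivision; $k_r$ and $k_x$ are evaluated at the segment's
local age from per-type piecewise-linear functions (linear interpolation
between knots, constant beyond the first and last knot).

**Verification** is by an independent brute-force oracle
(`networkOracle()`): each segment is split into hundreds of sub-edges, the
explicit resistor network (axial resistors along the xylem, radial resistors
to the medium, half-lumped to sub-edge end nodes) is solved sparsely, and
the collar influx under a unit potential difference is the conductance. The
discretization converges at second order; on random trees of up to 100
segments the analytic fold and the oracle agree to a relative error below
$10^{-6}$ at 1000 sub-edges per segment (this is an acceptance test), and
the closed-form limits (saturation to $\kappa$, radial-limited short
segments, exact parallel additivity, linear scaling of $K$ when $k_r$ and
$k_x$ are scaled together) hold to $10^{-8}$.

## Packaged hydraulic parameters

Published segment-scale conductivities for wheat are sparse and span an
order of magnitude, so the packaged knots are on the literature scale
(young $k_r \sim 10^{-7}$ m MPa$^{-1}$ s$^{-1}$ declining several-fold with
suberization; $k_x$ rising with xylem maturation, crown > seminal ≫
lateral) and their absolute level is calibrated against the anchors listed
above. A per-cultivar multiplier on both $k_r$ and $k_x$ (1.0 for the 1895
cultivar down to 0.76 for the 2002 one, linear in release year) encodes the
measured decline in conductance per unit root that root size alone does not
explain. Scaling both properties together moves $\kappa$ linearly while
leaving $\tau$ — and hence the shape of the age dynamics — unchanged.

`sensitivitySweep()` exposes the standard sensitivity analysis: global
multipliers on $k_r$ and/or $k_x$ with Krs recomputed on a fixed
architecture; Krs is monotone in both.

# The pressure-chamber chain

The measurement protocol applies pressures of 0.16, 0.24, 0.10, 0.32 and
0.24 MPa after pre-pressurization; the repeated 0.24 MPa step enters the
fit as two separate points. `fitSweep()` is ordinary least squares of sap
flow on pressure with a free intercept (pre-pressurization can leave a
nonzero flow offset, so proportionality is not forced); the slope is Krs,
and normalizations by scanned root surface area and total length give
Krs_area and Krs_length. Quality control requires $r^2 \geq 0.95$ (the
exclusion rule for non-linear sweeps is qualitative in the underlying
protocol; 0.95 is the package default and is configurable) and a positive
slope.

Outlier screening per cultivar follows the two-stage rule: a plant is
flagged when it falls outside $[Q_1 - 1.5\,\mathrm{IQR},\,
Q_3 + 1.5\,\mathrm{IQR}]$ in **all three** measures (conjunction; a
disjunction variant is available via `rule = "any"`) *and* iterative
two-sided Grubbs' tests (critical value from the t-distribution formula,
$\alpha = 0.05$, at most two removals per group and measure) confirm it in
all three. Flags are annotations; no row is ever dropped silently. Groups
smaller than three fall back to IQR-only flagging with a warning.

# Trend statistics

All dependent variables are log-transformed before modelling and results
are back-transformed for reporting; the percent change per century implied
by a slope $b$ (log-units yr$^{-1}$) is $(e^{100 b} - 1) \times 100$. This
back-transformation is an exact invariant of every fit object. Field traits
are modelled with a season random intercept (REML via nlme; the model
collapses to OLS when only one season is present, and falls back to OLS
with a warning if the mixed fit fails); hydroponic conductance traits use
plain OLS, matching how each kind of data is structured (two field seasons
versus one laboratory cohort). Residual normality is reported via
Shapiro–Wilk. Root-type diameter distributions are compared with two-sample
Kolmogorov–Smirnov tests; cultivar contrasts use one-way ANOVA on logs with
Tukey HSD adjustment (the only multiple-testing adjustment applied — trait
trends are reported with per-trait p-values). The crown-root/tiller link is
a pooled plant-level OLS of crown count on tiller count.

Calibration of the trend machinery is checked by simulation: on synthetic
panels with panel-scale noise and season effects, the 95% CI of the percent
change covers a planted −19.4%/century trend in at least 90% of 200
replicates, and the type-I error under a null with season effects stays at
or below 0.07 at nominal 0.05 over 1000 replicates (both are acceptance
tests).

# The synthetic-data generator

`table1Defaults()` returns the packaged generative configuration: for each
cultivar, trait means equal the measured panel means and plant-level
standard deviations are recovered from the panel standard errors at the
midpoint sample sizes (field n = 29.5, chamber n = 10). Traits are drawn
lognormally around the (possibly year-trended) means with an additive
per-season random intercept on the log scale (default sd 0.05); count
traits are rounded to integers ≥ 0. Trait draws are median-preserving, so a
planted percent change per century is *exactly* the slope the log-linear
model estimates; chamber draws are mean-preserving, so per-cultivar
arithmetic means equal the configured truth.

Chamber sweeps use the measurement protocol with
$J_v = a + K_{rs} P + \varepsilon$ (flow noise sd $5 \times 10^{-13}$
m$^3$ s$^{-1}$, about 2% of a typical mid-range flow). A shared lognormal
plant-size factor drives the geometry and part of the conductance, so the
normalized measures are less variable than raw Krs — the same structure the
measured standard errors show. A configured fraction of sweeps saturates
above 0.15 MPa (their $r^2$ against a line is ~0.55, far below any sane
threshold), and a configured fraction are planted outliers: deliberately
extreme in all three measures, implemented as the cultivar mean times a
factor of 5 so the plant-level draw cannot cancel the defect. Under the
packaged noise the chain rejects ≥ 95% of planted non-linear sweeps and
flags ≥ 90% of planted outliers (acceptance tests).

What the generator does **not** emulate: measurement drift within a sweep,
correlated flow errors, censoring of small flows, non-lognormal trait
families (a rounded-lognormal count is used rather than a negative
binomial), or any soil/weather structure. Passing tests therefore show that
the estimators recover the assumed generative structure at realistic noise,
not that real field data satisfy those assumptions.

# Problem sizes and reproducibility

The shipped tests and scripts use the study-scale problem sizes: 70-day
simulations at `dt` = 0.5 d with 6 replicate seeds per cultivar (a simulated
old-cultivar system reaches roughly 60,000 segments), chamber cohorts of
8–12 plants per cultivar, trait panels of ~30 plants per cultivar over two
seasons, 200-replicate coverage and 1000-replicate type-I simulations.
Every stochastic routine takes an explicit seed and restores the caller's
RNG state. `scripts/acceptance.R --seed N --out FILE` recomputes the
headline simulation quantities from scratch and writes them as JSON;
`scripts/calibrate.R` prints the calibration diagnostics for the packaged
defaults.

# Known limitations

* Absolute simulated Krs depends on the packaged calibration; only the
  anchored quantities (early-age Krs level, dynamic range, cultivar
  contrast, final lengths) are constrained by measurement.
* No soil domain, water-content feedback, shoot simulation, xylem
  cavitation, aquaporin dynamics or osmotic transport decomposition.
* The growth rules are the standard negative-exponential/zone-based family;
  tropisms and 3D placement are not modelled (and do not affect Krs under a
  uniform medium).
* The mixed model uses a single random intercept for season; block/plot
  structure within seasons is not modelled.
* Crown emergence before the first tiller is represented by a tiller-zero
  cohort; wheat can also produce late seminal-like axes that are not
  distinguished here.
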