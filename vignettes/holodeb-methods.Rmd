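---
title: "Model, numerics and design of holodeb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, numerics and design of holodeb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`holodeb` simulates a coral host in symbiosis with one or more algal
symbiont populations using dynamic energy budget (DEB) theory. This
vignette records the model assumptions, the numerical scheme, the design
choices that were genuinely open, and what the package's synthetic
experiments do and do not show about real corals.

## The flux network

Every physiological process is a *synthesizing unit* (SU): a saturating
kinetic operator mapping substrate arrival rates to a production rate,
`su_single(m, x) = (1/m + 1/x)^-1` for one substrate and
`su_parallel(m, x, y) = (1/m + 1/x + 1/y - 1/(x+y))^-1` for two jointly
required substrates. Both are continuous at zero substrate and bounded by
the maximum rate and by each input; these bounds are load-bearing (they
guarantee, for instance, that a symbiont never shares more carbon than it
fixes) and are enforced by property tests.

The host assimilates prey and dissolved inorganic nitrogen by
Michaelis–Menten kinetics and builds biomass from carbon (shared by
symbionts plus prey) and nitrogen in a parallel SU with maximum `j_HGm`.
Surplus nitrogen is shared with the symbionts in proportion to their
biomass — the host cannot favor one partner. Surplus fixed carbon powers a
carbon-concentrating mechanism (CCM) delivering CO₂ back to photosynthesis
at `k_CO2` mol CO₂ per mol C; this is the model's positive feedback and the
source of its bistability. Symbionts absorb skeleton-amplified light
(`A = 1.26 + 1.39 exp(-6.48 ΣS_i/H)`, so amplification falls from 2.65
toward 1.26 as self-shading grows), photosynthesize in a light × CO₂ SU,
and grow from photosynthate and nitrogen. Light absorbed beyond what
photochemistry uses is first dissipated by a saturating nonphotochemical
quenching (NPQ) unit with capacity `k_NPQ`; the unquenched remainder raises
relative reactive-oxygen-species production
`c_ROS = 1 + (j_eL - j_NPQ)_+ / k_ROS`, which multiplies photosynthesis by
`1/c_ROS` and raises symbiont turnover to
`j_ST0 (1 + b (c_ROS - 1))`. Because the NPQ unit is strictly saturating,
`c_ROS = 1` exactly only when no excess light exists at all; any positive
excess leaves a strictly positive unquenched residue.

Two parameterizations ship with the package. They differ in exactly three
numbers: the sensitive symbiont has `k_ROS = 80` mol photons C-mol⁻¹ d⁻¹,
`j_CPm = 2.8` mol C C-mol⁻¹ d⁻¹ and `j_SGm = 0.25` d⁻¹; the tolerant one
`k_ROS = 250`, `j_CPm = 1.0` and `j_SGm = 0.15`. Published listings of this
parameterization disagree on the tolerant maximum growth rate (0.15 versus
0.1 d⁻¹); the package defaults to 0.15, the more consistently printed
value, and exposes it as an ordinary parameter.

## Lagged fluxes and time stepping

The SU network is cyclic in two places: shared carbon → host growth →
shared nitrogen → symbiont growth → shared carbon, and photosynthesis →
excess light → ROS → photosynthesis. Rather than solving the implicit
algebraic system every step, `compute_fluxes()` evaluates the network in
dependency order using the previous step's `rho_C`, `j_SG` and `c_ROS`
where a cycle would otherwise close — the fluxes are treated as lagged fast
variables. Biomasses then take one explicit Euler step,
`S' = S (1 + (j_SG - j_ST) dt)`, with `dt = 0.1` d by default.

Two conventions follow from the lag. The CCM flux `j_eC` and the excess
light `j_eL` are clamped at zero: neither mechanism can run in reverse, and
transiently negative values can only arise from one-step-old inputs. And
with zero total symbiont biomass, the per-C-mol shares of host nitrogen and
CO₂ are defined as zero (there is no recipient), which reduces the host to
a symbiont-free heterotroph.

Internally the integrator carries `log H` and the ratios `s_i = S_i/H`.
Every specific rate in the model depends on the biomasses only through
these ratios, so the update
`s_i' = s_i (1 + (j_SG - j_ST) dt) / (1 + (j_HG - j_HT) dt)`,
`log H' = log H + log1p((j_HG - j_HT) dt)` is *exactly* the multiplicative
Euler step while remaining finite through years of sustained exponential
growth that would overflow raw biomasses. The compiled core (`engine =
"cpp"`) and the pure-R reference evaluator (`engine = "R"`) implement the
identical scheme and agree to the last bit in tests; a separately coded
one-symbiont evaluator in the test suite provides an independent oracle for
the reduction case. Step-size robustness is checked two ways: a Richardson
test that halving `dt` roughly halves the distance to a refined solution,
and a 20-environment panel on which outcome classifications are identical
at `dt = 0.1` and `dt = 0.05`.

## Initializations: choosing the basin

The flux network is bistable at fixed biomasses in many environments, so
initial fluxes select the basin.

*Healthy.* The reference initialization (host 1 C-mol, 0.5 C-mol per
symbiont) sets the fluxes to the self-consistent fixed point of
`compute_fluxes()` at that state under the run's own environment. The
original implementation's default initial fluxes are not printed anywhere,
so the fixed point — reproducible, self-consistent and in the healthy basin
— is this package's definition. The iteration starts from a "generous"
guess (maximal carbon sharing, `c_ROS = 1`) so it approaches the healthy
branch from above; plain iteration to a relative tolerance of 1e-9 (cap
100) is retried once with 0.5 damping before failing.

*Bleached.* The bleached initialization uses slow–fast anchoring: total
symbiont biomass 1e-4 C-mol against 1 C-mol of host, host biomass formation
and symbiont photosynthesis pinned to zero, and every other flux derived in
dependency order from those anchors (so `j_SG = 0`, `rho_C = 0`,
`j_eL = j_L`, `j_eC = j_X`). This places the system in the bleached basin;
whether it escapes to growth within 100 days is the recovery question.

## The three experiments

All experiments draw environments uniformly over light 5–60 mol photons
m⁻² d⁻¹, dissolved inorganic nitrogen 1e-8–1e-5 mol l⁻¹ and prey 0–4e-7
C-mol l⁻¹ — ranges spanning benign reef conditions through light stress
and experimental nutrient enrichment.
Note that nitrogen is uniform on a *linear* scale, so most draws are
nutrient-rich; this matters when comparing transects with aggregate
statistics, because the light level at which competitive dominance switches
rises with nitrogen (from roughly 27 at N = 1e-7 to ~45 at N = 1e-6 mol
l⁻¹).

*Competitive dominance* starts healthy with 0.5 C-mol of each symbiont. A
host whose growth rate is zero or negative at day 100 is dead
(`no_survival`); otherwise the more abundant symbiont at 10 years wins. An
exact tie is an error by design — it never occurs in practice and would
indicate a degenerate configuration.

*Rate of exclusion* starts the eventual winner at 1% against the loser at
99% and measures the first crossing of the 99% share threshold. A 10-year
stopping rule would censor the slowest exclusions, which can exceed 20
years near the dominance switch, so the package caps at a configurable 25
years with explicit censoring.

*Recovery* is two-staged: bleached with the sensitive symbiont alone, and —
if that fails — bleached with both at 5e-5 C-mol each, classified at day
100 and (for survivors) by dominance at 1000 days, yielding the four
outcomes `recovers_with_sensitive`, `recovers_with_tolerant`,
`recovers_with_sensitive_in_presence_of_tolerant` and `no_recovery`.

*Functional symbiosis.* Survival is defined by positive growth only. But a
surviving host can be severely carbon-limited — the model's
dysfunctional-symbiosis state, in which a large symbiont population fixes
little carbon per C-mol. `competition_outcome()` therefore emits the signed
carbon/nitrogen limitation index of the host growth SU
(`log(min(C, j_HGm)/min(N, j_HGm))`; positive = nitrogen-limited =
functional) as a diagnostic column, and the acceptance summaries restrict
exclusion-time minima to nitrogen-limited survivors. Applying the
restriction downstream, rather than folding it into the labels, keeps the
default outcome definitions minimal.

## Discriminant summaries

`fit_lda()` summarizes a survey by linear discriminant analysis of the
outcome labels against the three environmental variables, reporting the
variable loadings and each axis's share of between-class variance
("proportion of trace"). Class priors are the observed class proportions
and the variables enter untransformed — log axes in downstream figures are
display choices, and trace shares are invariant to per-variable affine
rescaling anyway (a property test checks this). The fit delegates to the
standard `MASS::lda` with `tol = 1e-12`, because the default tolerance
misreads genuinely varying molar-scale predictors (~1e-7 mol l⁻¹) as
constant; true degeneracies are still caught by an explicit constant-column
screen and a wrapped error naming the offending variable. Axis signs are
not identifiable, and tests compare axes to a brute-force eigen
decomposition of `W⁻¹B` up to sign and scale.

## Problem sizes

Full-scale analyses of this design run 20,000 (competition) and 150,000
(recovery) random environments. The package's bundled summaries use sizes chosen for
interactive work on a single core: a 6 × 6 × 5 grid (light linear, nitrogen
log-spaced to cover both nutrient regimes, prey linear) for exclusion-time
minima, and 500-draw surveys for the discriminant trace shares. At 500
draws the LD1 shares are stable to well under a percentage point across
seeds for the competition survey and about one point for the recovery
survey, whose two rarest outcome classes hold only a handful of draws each.

## What the synthetic experiments do not show

The environment generator emulates a survey sampling design, not reef
reality: conditions are constant for up to 25 simulated
years, whereas real light, nutrients and prey fluctuate on daily to
seasonal scales — and such fluctuation is precisely what could maintain
symbiont coexistence in nature.
Light is the only stressor; bleaching driven by heat through other
pathways is outside the model. Symbionts interact only through shared
resources and shading, never by direct interference, and grow exponentially
with no density dependence, so competitive exclusion is certain in any
constant environment. Passing surveys therefore validate the flux network,
its integration and its classification logic — not quantitative predictions
for any particular reef.

## Known limitations

- The healthy flux initialization is this package's own (fixed-point)
  definition; earlier implementations used unpublished defaults, so only
  qualitative agreement with their trajectories can be asserted.
- The explicit Euler/lagged-flux scheme is first-order; `dt` well above
  0.1 d will distort the ROS feedback in strongly stressed runs.
- Exact ties in symbiont abundance raise errors instead of being broken
  arbitrarily; with floating-point dynamics they do not occur in practice.
- Dissolved-organic-carbon feeding and temperature-dependent rates are
  not implemented.
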