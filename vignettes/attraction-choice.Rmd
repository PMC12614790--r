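---
title: "Attraction–choice models of pollination facilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attraction–choice models of pollination facilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeshare)
```

## The model and its assumptions

`beeshare` models two co-flowering plant species sharing a pool of
pollinators: a focal crop of amount $c$ and a wildflower of amount $w$.
"Amount" is a dimensionless utility to the pollinators — the quantity in
proportion to which foragers divide themselves, whether that is flower
number, nectar quantity or quality. No unit system is imposed.

Two separable processes determine visitation:

1. **Attraction to the patch.** $N(c, w)$ pollinators arrive, under one
   of the functional families listed by `attraction_forms()`. The
   scientifically central families are *decelerating* in $w$: the
   marginal pollinator attracted per unit of a species falls as that
   species becomes more abundant (an empirically common pattern).
2. **Choice within the patch** by input matching (the ideal free
   distribution): a fraction $D = c/(c+w)$ lands on the crop.

Visits to the crop are $F = N D$; to the wildflowers, $N(1-D)$. The two
always sum to $N$ (conservation, tested to $10^{-12}$ relative
tolerance). Facilitation means $F(c, w) > F(c, 0) = N_c$: the neighbour
attracts more pollinators into the patch than it diverts away from the
crop. Everything is static and deterministic: no pollinator or plant
population dynamics, no movement ecology, no fruit set — "yield" below
is shorthand for pollination-limited, area-linear output.

The imbalance that drives everything is between *how a species attracts*
(decelerating) and *how pollinators choose* (proportional). If the two
behave identically — the purely linear family $N = g(c+w)$ — each plant
attracts exactly the pollinators that choose it and the interaction is
exactly neutral. A fixed local pool $L$ shared by both species produces
pure competition. Deceleration produces facilitation whenever the crop
amount exceeds a threshold.

## Optima

For the saturating family $N = A w/(a+w) + N_c$, maximizing $F$ in $w$
gives the tangent (marginal-value) condition
$\partial N/\partial w = N/(c+w)$, a quadratic in $w$ whose positive
branch is implemented in `optimal_w_analytic()`:

$$w^* = \frac{-2 a N_c + \sqrt{(2 a N_c)^2 - 4 (A+N_c)(N_c a^2 - a A c)}}
             {2 (A+N_c)}.$$

The negative branch is never a maximum of $F$ (the brute-force oracle in
the test suite confirms this on random draws); a nonpositive branch or a
negative discriminant means the maximum sits at $w^* = 0$, which happens
exactly below the facilitation threshold $c_0 = N_c a / A$
(`facilitation_threshold()`).

The fixed-area scenario ("Model B") sets $c = 1-p$, $w = bp$ on a fixed
total area, with $b$ the wildflowers' relative per-area value, and
maximizes the crop yield $f(p) = N_p(p) D_p(p) (1-p)$ numerically. Its
stationarity condition $\mathrm{d}(N_p D_p)/\mathrm{d}p = N_p D_p/(1-p)$
is exposed as `model_b_stationarity_residual()` with a closed-form
derivative for the two-species saturating family.

## Parameters

| Parameter | Meaning | Bound |
|---|---|---|
| $A$ | long-range attractiveness scale of the wildflowers | $\ge 0$ |
| $a$ | half-saturation / deceleration constant (power family: exponent, $0<a<1$) | $> 0$ |
| $N_c$ | pollinators attracted by the crop alone (default 0) | $\ge 0$ |
| $L$ | local pollinator pool | $\ge 0$ |
| $r$, $y$ | rate and exponent of the sigmoid (Holling III) family | $> 0$ |
| $g$ | linear attraction constant | $> 0$ |
| $A_w, A_c, a_w, a_c$ | per-species scales of the two-species family | as $A$, $a$ |
| $b$ | per-area value of wildflowers relative to the crop | $> 0$ |
| total area | pure scaling factor; never moves an optimum | $> 0$ |

The named sweep scenarios (`sweep_spec("fig1")`, …) carry the reference
fixture constants $a = 0.4$, $A = 10$, $L = 10$, $r = 0.02$, $y = 3$,
$g = 1$, and for the fixed-area panels $A_w = A_c = 1$ (or $A_w = 10$),
$a_w = a_c = 0.4$, $b = 1$.

## Design choices where the design was open

* **$D$ at $c = w = 0$** is undefined; the package raises a
  degenerate-patch error rather than returning a convention value, so
  silent misuse is impossible.
* **$N_c$ is a scalar parameter.** The crop amount is held fixed in the
  independent-$w$ scenario, so a constant matches every worked use; users
  wanting cross-model consistency can use the two-species family, whose
  crop term $A_c c/(a_c + c)$ plays the same role as a function of $c$.
* **Fixture constants left open:** the tangent-construction scenario
  needs a crop amount and baseline; the package uses $c = 10$,
  $N_c = 10$, consistent with the worked examples throughout the
  documentation. The comparison-panel scenarios hold $c = 10$ likewise.
  Panel-to-family mapping for the three decelerating panels is power
  (decelerating, unbounded), saturating (Michaelis–Menten), sigmoid;
  these panels are qualitative and every regime test is independent of
  the mapping.
* **Power and exponential-saturating families** are generic decelerating
  and saturating stand-ins ($A w^a + N_c$ with $0<a<1$;
  $A(1-e^{-w/a}) + N_c$): increasing and decelerating/saturating, the
  only constraints stated for them.
* **Sigmoid amplitude.** The Holling III family is implemented exactly
  as printed (amplitude 1), with an optional multiplicative `amplitude`.
* **Allee-effect criterion.** "Intraspecific facilitation over a range
  of $w$" is operationalized as rising per-unit-amount visitation
  $V(w) = N(1-D)/w = N/(c+w)$, the natural per-capita rate under input
  matching. One defensible alternative — visits per flower at fixed
  nectar value — would shift interval edges; `allee_scan()` documents
  the choice prominently. Under this reading a decelerating $N$ alone
  ($c = 0$) never yields an Allee effect, while a crop above $c_0$
  always precipitates one near $w = 0$ (the sign of $V'(0)$ is the sign
  of $(A/a)c - N_c$).
* **Interaction signs at one state.** For any attraction additive in the
  species' contributions, $N = h_c(c) + h_w(w)$, the crop-side and
  wildflower-side differences from their respective absent-neighbour
  baselines are exact negatives:
  $F_{crop} - h_c = [h_w c - h_c w]/(c+w)$. Mutual facilitation at a
  *single shared state* therefore requires a non-additive family (the
  sigmoid, in its accelerating range). Mutual benefit under additive
  attraction is real but lives at each species' own optimum
  ($w^* > 0$ for the crop above threshold, and symmetrically for the
  wildflowers); `interaction_matrix()` documents the constraint, and the
  wildflower-side baseline sets $c = 0$ in the state while leaving
  parameters (including a scalar $N_c$) untouched.

## Numerical choices

* All arithmetic is double precision; package tests compare at relative
  tolerance $10^{-9}$ unless stated.
* **Optimizers** use a dense grid scan (default $10^4$ cells) to bracket
  the *global* maximum — necessary for the non-unimodal sigmoid family —
  followed by golden-section refinement to a location tolerance of
  $10^{-8}$. Search windows default to $w \in [0, 50]$ (a warning fires
  if the maximum sits at the upper bound) and $p \in [0, 1]$ closed.
* **Tie-breaking:** flat objectives (the linear family) report location
  0 with `at_boundary = TRUE` — the smallest competitor amount among the
  maximizers is the conservative recommendation. A maximum at the first
  grid point triggers a refinement of the first cell, so interior optima
  below one grid step are still resolved.
* **Derivatives** are closed-form where registered (the saturating and
  two-species families); otherwise central finite differences with step
  $10^{-6}$ on the natural scale.
* **Neutrality tolerance** $\varepsilon = 10^{-9}$ (relative) in regime
  classification, so the algebraically exact neutral case classifies as
  neutral despite one rounded division.
* **Default grids:** $w$-sweeps use 501 points on $[0, 50]$; $p$-sweeps
  101 points on $[0, 1]$; optimization scans $10^4$ cells. Regime and
  Allee interval edges live on the user's grid — no sub-grid root
  polishing, grid density is the user's control.
* The crop-yield optimum under symmetric fixed-area parameters refines
  to $p^* \approx 0.0528$; at two-decimal reporting precision this is
  $0.05$. Whether a coarser grid or rounding underlies a reported
  two-decimal figure cannot be distinguished at that precision; the
  package reports both the refined location and the rounded value.
* The figure-comparability rescaling (`normalize_attraction()`, $N$
  scaled to 1 at $w = 50$) is applied only to output tables, never
  inside optimization — a positive scalar cannot move an argmax.

## What the tests do and do not show

The suite checks exact hand-derived values (half-saturation points, the
quadratic's root at $w^* = 1.2$, yields at $p \in \{0, 0.5, 1\}$),
property-style invariants over seeded random parameter draws
(conservation, deceleration, monotonicity of $w^*(c)$, oracle agreement
between the closed form and brute-force maximization on 200 draws,
threshold equivalence $w^* > 0 \iff c > c_0$), and the two quantitative
fixed-area results ($p^*$ rounding to 0.05, attraction argmax at 0.5).
All of this validates the mathematics of the model, not the model
itself: real plant–pollinator systems have spatial structure, pollinator
constancy, and dynamic feedbacks that the static attraction–choice
decomposition deliberately omits.

## Known limitations

* Two species only; no joint optimization over $(c, w)$.
* Attraction is a static functional response; pollinator numbers do not
  feed back on plant amounts within the model.
* The wildflower-side baseline convention (parameters untouched at
  $c = 0$) matters when $N_c > 0$ is interpreted as crop-generated; use
  the two-species family when that interpretation is intended.
* Figure rendering is out of scope; the tested surface is the data
  tables emitted by `run_sweep()` and the CLI.
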