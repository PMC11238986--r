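---
title: "Multistable neuroendocrine loop models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistable neuroendocrine loop models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmloop)
```

## The scientific problem

Fibromyalgia presents as chronic widespread pain without a known primary
lesion.  One mechanistic account treats pathogenesis as a *state
transition* in two coupled dynamical systems: a pain-processing
thalamocortical loop that can switch from a monostable, low-firing
regime to a bistable regime with a persistent high-firing state, and a
hormonal control layer — the hypothalamus–pituitary–gonadal (HPG) and
hypothalamus–pituitary–adrenocortical (HPA) axes — whose own multistable
dynamics set the GABA/glutamate balance that decides which regime the
loop is in.  `fmloop` implements both systems, the calibration that
connects neurosteroid levels to synaptic coupling strengths, and the
composition of the pieces into a scenario and a prevalence prediction.

All interactions are modelled with Hill functions,
$x^h/(e^h + x^h)$ and its decreasing counterpart $1/(1 + (x/e)^h)$,
the standard saturating law for neuronal input–output curves, receptor
pharmacology and endocrine dose–response relationships.  The
half-saturation $e$ plays the role of an EC50; the coefficient $h$
measures cooperativity (electrophysiological responses sit near
$h \approx 2.5$, genomic and inter-axis effects higher, $h \approx 4$–$7$).

## The thalamocortical loop

Three mean firing rates — $S$ (somatosensory cortex), $T$ (thalamic
reticular nucleus), $V$ (ventroposterolateral nucleus) — obey

$$\tau \dot S + \theta S = f_1(bV), \qquad
  \tau \dot T + \theta T = f_2(bV + bS), \qquad
  \tau \dot V + \theta V = g(aT)\,\frac{(bS)^h}{f_a(aT)^h + (bS)^h},$$

with $f_1, f_2$ increasing Hill functions (maxima $m_1 = 100$ Hz and
$m_2 = 80$ Hz, half-saturation $e = 20$ Hz, $h = 2.5$), $g$ a
decreasing Hill function of maximum $m_1$, and
$f_a(x) = e_0 + m_2 x^h/(e^h + x^h)$ with $e_0 = 20$ Hz.  The
dimensionless couplings $a$ and $b$ scale GABAergic (TRN→VPL) and
glutamatergic transmission; $\theta$ scales the self-limiting decay;
$\tau = 0.5$ s.  TRN inhibition acts twice on the VPL response to
cortical drive: it depresses the maximum (through $g$) and
desensitises the response (raising the half-saturation through
$f_a$).  The printed equation for the composite term admits more than
one parenthesisation; we implement the reading the accompanying prose
supports — $f_a(aT)$ *is* the half-saturation of the Hill response to
$bS$ — and note that at $T = 0$ this reduces exactly to the basal
half-saturation $e_0$.

The origin is an equilibrium for every admissible parameter set (all
Hill numerators vanish), and the nonnegative octant is forward
invariant.  Steady states are found by a scalar reduction: eliminating
$S^* = f_1(bV^*)/\theta$ and $T^* = f_2(bV^* + bS^*)/\theta$ leaves a
one-dimensional fixed-point problem in $V$ on $[0, m_1/\theta]$, which
is bracketed on a 2001-point grid, locally refined tenfold around each
sign change, polished with Brent's method, deduplicated within
$10^{-4}$ Hz, and classified by the eigenvalues of the full
$3\times 3$ Jacobian (central differences).  A point is *stable* when
every real part is below $-10^{-6}$ Hz/s; eigenvalues within
$\pm 10^{-6}$ of zero mark the point *marginal* and exclude it from
stable counts, which keeps the bisection described next from
flickering exactly at the fold.

`bifurcation_point()` locates the critical GABAergic strength
$\hat a(b, \theta)$ — the saddle-node at which a high-firing stable
state and a saddle appear — by bisecting $a$ over the count of stable
equilibria to a default tolerance of $10^{-3}$.  With the default
constants this yields $\hat a(1, 1) \approx 0.264$ and
$\hat a(0.5, 1) \approx 0.117$, matching the published anchors 0.265
and 0.116 well within their ±0.005 band, and
$\hat a(0.6, 1) \approx 0.155$ where the literature value is 0.16;
the 0.005 gap at that third anchor is stable under grid and tolerance
refinement, so we report our computed value rather than tune toward
the printed one (which is consistent with a figure-read or
coarse-scan rounding).  The anchors are taken at $\theta = 1$, which
the source does not restate; $\theta$ is an explicit argument
everywhere.  The $\hat a(b)$ relation is sigmoid and increasing, the
$\theta = 0.5$ curve is shallower, and the two cross once near
$b \approx 0.6$ — all treated as qualitative properties in the tests.

## The allopregnanolone → GABAergic-strength map

Brain allopregnanolone $A$ (ng/mL) modulates GABA-A receptors through
two distinct mechanisms, combined as a sum of increasing Hill terms:

$$a(A) = a_f\,\frac{A^{h_w}}{e_w^{h_w} + A^{h_w}}
       + (1 - a_f)\,\frac{A^{h_g}}{e_g^{h_g} + A^{h_g}},$$

a *withdrawal* component (genomic effect on the receptor's α4 subunit
at sub-follicular concentrations; $e_w = 1.8$ ng/mL, $h_w = 6.5$) and
an *allosteric* component (positive modulation at follicular-to-
pregnancy concentrations; $e_g = 18$ ng/mL, $h_g = 2$).  The map is
strictly increasing and saturates below 1.

Every constant is derived, not assumed, and `calibration_chain()`
replays the derivation with provenance tags:

* $a_f = 1/(1 + 1.5) = 0.4$ — the maximal receptor-activity increase
  over baseline is taken as 150 % (mean of reported 100 % and 200 %
  maxima), and the follicular strength is what that increase carries
  to 1.
* A withdrawal paradigm shortens the GABA-A current time constant
  6-fold.  Integrating $I_0 e^{-t/\tau}$ gives a total-charge ratio
  that is *exactly* 6 ($\int_0^\infty e^{-t/\tau} dt = \tau$), while
  the source applies "about 3-fold" downstream.
  `integrated_current_ratio()` reports the exact closed form; the
  applied factor stays a separate, configurable input (default 3) so
  both numbers are visible and neither is silently reconciled.
  $a_w = a_f / 3 \approx 0.133$.
* The follicular brain level: luteal brain/plasma ratio $20/1.2$
  applied to follicular plasma 0.15 ng/mL gives 2.5 ng/mL by
  arithmetic, where the source prints 2.4; both are carried (the
  printed value is the downstream default, the arithmetic one is
  reported alongside).
* The withdrawal brain level: a finasteride paradigm drops plasma
  from 9 to 6 ng/mL; the same proportional drop applied to the 2.4
  follicular brain level gives $A_w = 1.6$ ng/mL.
* $(e_w, h_w)$ then solve the two constraints $a(A_w) = a_w$ and
  $f_w(2.4) = 0.866\,a_f$ ("essentially saturated at the follicular
  level").  The saturation fraction 0.866 is reverse-derived from the
  published $(e_w, h_w)$ pair because "asymptotically approached at
  $A \approx 2.4$" is not operational; it is an exposed argument.
  The solver reduces the system in closed form and polishes with
  Newton iterations to residuals below $10^{-8}$; infeasible
  constraint sets (e.g. demanding 99.9 % saturation barely above the
  withdrawal level) fail explicitly.

The calibrated map sends 1.6 ng/mL to $a \approx 0.132$ and
18 ng/mL to $a \approx 0.70$ — below and above, respectively, the
bifurcation anchors of the loop, which is the heart of the pathogenic
argument: withdrawal alone sits just *above* $\hat a$ at physiological
glutamatergic strength ($b = 0.5$), and a 20 % stress-driven rise to
$b = 0.6$ is enough to push $\hat a$ above it.

## The HPG–HPA endocrine loop

Axis activities on a 0–100 scale obey

$$\tau \dot{x}_1 = f(x_2) - k(x_1)\,x_1, \qquad
  \tau \dot{x}_2 = f(x_1) - k(x_2)\,x_2,$$

with $f(x) = 100/(1 + (x/e_x)^{h_x})$ the mutual inhibition
($e_x = 28$, $h_x = 4.2$ — the medians of the packaged
cross-species dose-response table) and
$k(x) = 1 + 4/(1 + (\alpha x/e_k)^{h_k})$ the self-limiting factor
($e_k = 25.57$, $h_k = 6.6$, $\alpha = 0.48$), which moves from 5 at
low activity (each axis ruled by its own negative feedback) to 1 at
high activity (the mutually inhibitory positive loop dominates);
$\tau = 30$ min.  The parameters are identical for both axes, so the
vector field commutes with coordinate exchange and every reported
object must respect that symmetry — the tests assert it.

Equilibria are enumerated two ways and merged: a scalar scan of
$k(x)x = f(x)$ along the diagonal (symmetric states) and multi-start
2-D Newton root finding from a $21 \times 21$ grid over the state
square, each candidate mirrored, polished to residuals below
$10^{-8}$, deduplicated within $10^{-4}$ and classified by the
$2 \times 2$ Jacobian.  At the default parameters this yields five
equilibria: a stable symmetric point near (17.5, 17.5), a stable
asymmetric pair near (86.1, 0.18)/(0.18, 86.1), and a saddle pair
near (81.9, 0.22)/(0.22, 81.9).  The saddle and stable members of
each asymmetric pair are only a few activity units apart with slow
eigenvalues of order $10^{-3}$/min, which is why the enumeration
polishes to tight residuals before classifying: a looser tolerance
merges the pair and miscounts the stable states.

`basin_map()` labels a regular grid of initial conditions (default
$101 \times 101$) by the attractor each trajectory reaches; the
integrator stops as soon as the trajectory enters a 0.5-unit capture
radius of a stable point, which cuts the cost several-fold without
changing labels (the slow manifold is entered long before).  The
low–low symmetric basin is the widest — high joint activations decay
mutually until self-limitation takes over — and the high-HPA/low-HPG
basin is the pathogenic region.  The circadian forcing that would
turn the fixed points into small limit cycles is deliberately not
modelled: its amplitude is small relative to the inter-basin
distances relevant to pathogenesis.

## Coupling and prevalence

`run_scenario()` composes the layers: endocrine steady state →
HPG activity → brain allopregnanolone → $a$ (via the map above), and
HPA activity → $b$, then classifies the thalamocortical regime at
$(a, b)$.  The source anchors the endpoints of both couplings but
gives no functional form, so the defaults are the simplest monotone
interpolants — piecewise-linear through (0 → 1.6, 20 → 2.4,
100 → 20 ng/mL) for HPG→A, and $b = 0.5\,(1 + 0.2\,\mathrm{HPA}/100)$
for HPA→b (rest 0.5, full activation 0.6) — and every scenario report
tags them "configured" as opposed to "computed".  Both are
replaceable functions, validated for monotonicity and range.

`prevalence()` reproduces the gender-prevalence argument: one
withdrawal episode per cycle over 460 cycles in 37 years gives a
daily probability $p_{woman} = 460/(37 \cdot 365) \approx 0.0341$;
against $p_{man} = 0.005$ this yields $G = p_{woman}/p_{man} \approx
6.81$ and $100\,G/(G+1) \approx 87.2\,\%$ women among patients.  The
unrounded ratio is used throughout: the separately published rounded
$p_{woman} = 0.037$ would give $G = 7.4$, not the published 6.8, so
the rounded figure is treated as display-only and both facts are
stated here rather than reconciled.

## The synthetic dose-response generator

`synth_dose_response()` samples a known Hill curve at log-spaced
inputs over $[e/10, 10e]$ and adds i.i.d. Gaussian noise, emulating
the shape of the pooled pharmacological dose-response experiments the
fitted tables came from: a handful of points (the packaged tables
have 4–71 per study, most around 6–12), inputs spanning roughly two
decades around the EC50, and response-scale noise.  It does *not*
emulate heteroscedastic assay error, censoring at detection limits,
between-study heterogeneity, or non-Hill saturation artefacts — so a
passing fit-recovery suite shows the estimator is correct and stable
under the stated noise model, not that the original studies' data
would be recovered.  The default recovery conditions are $n = 12$
points and noise s.d. 5 on the 0–100 response scale, with the
half-saturation recovered within ±15 % across seeds; noiseless
round-trips must recover parameters to $10^{-6}$ relative error.

`fit_hill()` itself uses bounded Levenberg–Marquardt least squares
with multi-start initials ($e$ at the input quartiles,
$h \in \{1, 2, 4, 8\}$), best residual wins, ties toward the smaller
$h$.  Whether the span `m` and `offset` are fixed or free is the
caller's choice (both modes are exposed because the original fits do
not state theirs).  Constant or direction-contradicting data raise a
classed failure; a rank-based (Spearman) monotone-association p-value
is attached as a diagnostic only and never gates the fit.

## Numerical choices, in one place

* Integration: `lsoda`, rtol $10^{-8}$, atol $10^{-10}$; convergence
  declared when the RHS infinity norm drops below $10^{-6}$ (Hz/s or
  activity/min); states are clamped to 0 when they undershoot by less
  than the solver tolerance.
* Equilibrium enumeration: 2001-point bracketing grid (tenfold local
  refinement), dedup $10^{-4}$, residual acceptance $10^{-8}$,
  stability threshold $\pm 10^{-6}$ on eigenvalue real parts.
* Bisection for $\hat a$: default tolerance $10^{-3}$ on a bracket
  $[0.01, 0.99]$, with explicit errors when the bracket does not
  straddle a regime change.
* Basin mapping: default $101 \times 101$ grid, horizon $10^4$ min
  ($\gg \tau = 30$ min), capture radius 0.5 units.  The packaged
  tests use $21 \times 21$–$41 \times 41$ grids and a 5000-min
  horizon, which already resolve every basin-scale assertion; the
  full-resolution map is a few minutes of compute and changes only
  the smoothness of the printed boundary.
* Randomness: only the synthetic generator and the
  random-initial-condition checks consume random numbers; every such
  path takes an explicit seed and the generator restores the caller's
  random state.

## Known limitations

* The couplings between the endocrine steady state and $(a, b)$ are
  anchored but otherwise invented; conclusions that depend on their
  shape (rather than their endpoints and monotonicity) are outside
  what this package can support.
* The thalamocortical model is a three-node mean-rate caricature: no
  cortical laminar structure, no conduction delays, no stochastic
  firing.
* The endocrine model resolves each axis as one scalar activity; no
  individual hormone species, no sex-specific parameters, no
  circadian forcing.
* The third published bifurcation anchor (0.16 at $b = 0.6$) is
  reproduced only to 0.005 (we compute 0.155); see the discussion
  above.
* Hill-parameter tables are taken at their printed values; the
  original per-study fits are not re-derived from raw data.
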