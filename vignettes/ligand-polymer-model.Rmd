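---
title: "Modelling ligand binding to biopolymers under tension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand binding to biopolymers under tension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(polyligand)
```

## The physical picture

In a single-molecule force-spectroscopy experiment a long biopolymer — the
motivating case is single-stranded DNA coated by single-stranded DNA binding
proteins (SSB) — is held between two handles and stretched at a controlled
force while its end-to-end extension is recorded. Small ligands that bind the
polymer occlude a patch of monomers and locally reorganise it, so the
measured elasticity depends on how much of the molecule is covered.

`polyligand` models this with an effective decomposition of the molecule
into two sub-chains:

* the **naked regions**, treated as an extensible worm-like chain (XWLC)
  with persistence length $L_p$, stretch modulus $K_0$, and contour length
  $(N - \sum_i n_i m_i)\,d_0$, where $n_i$ ligands bound in mode $i$ each
  occlude $m_i$ of the $N$ monomers;
* the **covered regions**, treated as a freely-jointed chain (FJC): each
  ligand–monomer complex is a rigid Kuhn segment of length $a_i$, randomly
  oriented, contributing $a_i\,\mathcal{L}(F a_i/k_BT)$ to the extension,
  with $\mathcal{L}(u) = \coth u - 1/u$ the Langevin function.

The total extension at force $F$ is

$$x(F) = \frac{x_n(F)}{L_c}\,\Big(N - \sum_i n_i m_i\Big) d_0
       + \sum_i n_i a_i\,\mathcal{L}\!\left(\frac{F a_i}{k_BT}\right),$$

where $x_n/L_c$ is the XWLC relative extension, obtained by solving the
extensible Marko–Siggia interpolation

$$\frac{F L_p}{k_BT} = \frac14\Big(1 - \frac{x_n}{L_c} + \frac{F}{K_0}\Big)^{-2}
  - \frac14 + \frac{x_n}{L_c} - \frac{F}{K_0}.$$

This decomposition assumes dispersely bound, randomly oriented ligands whose
perturbation of the polymer orientation averages out — a good description of
diffusing, non-cooperative binders such as SSB. It does not attempt to
describe cooperative binding, sequence effects, or secondary structure.

Units are fixed package-wide: pN, nm, pN·nm and s; temperature enters only
through $k_BT$ (default 4.11 pN·nm, 25 °C).

```{r fec}
ssdna <- polymer_spec(N = 5080, d0 = 0.57, Lp = 0.715, K0 = 700, kBT = 4.11)
ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
forces <- 10^seq(-1, 2, length.out = 120)
plot(forces, total_extension(forces, ssdna, ssb, coverage = 0),
     log = "x", type = "l", xlab = "Force (pN)", ylab = "Extension (nm)")
lines(forces, total_extension(forces, ssdna, ssb, coverage = 1), col = 2)
legend("topleft", c("naked", "fully covered"), col = 1:2, lty = 1, bty = "n")
```

In the high-force limit the extension depends on the binding mode only
through the coverage $c = n m / N$ and the Kuhn length per occluded monomer
$a/m$ (`highforce_asymptote()`): $a$ and $m$ are *not separately
identifiable* from high-force data, which matters for fitting (below). At
low force the initial slope is
$\frac{2 L_p}{3 k_BT}\big[1 + c\big(\frac{(a/m)a}{2 d_0 L_p} - 1\big)\big]$
(`lowforce_slope()`); the slope exceeds the naked-chain value exactly when
$(a/m)\,a > 2\,d_0 L_p$, i.e. when the bracket in the formula is positive —
the formula, not the looser rule-of-thumb inequality $(a/m)a > d_0 L_p$
sometimes quoted, is what the package implements and tests.

## Equilibrium coverage under tension

Bound ligands trade binding energy $\epsilon^b$ against the elastic free
energy of converting naked monomers into covered Kuhn segments. With the
one-dimensional ideal-gas chemical potential for the bound ligands, the
Gibbs free energy at force $F$ is minimised by

$$n_i^{(eq)}(F) = \exp\!\Big(\frac{E_i(F)}{k_BT}\Big), \qquad
E_i(F) = \epsilon_i^b + m_i d_0\,\Delta g_n^{el}(F) - a_i\,\Delta g_c^{el}(F),$$

where $\Delta g_n^{el}(F) = -\int_0^F x_n/L_c\,\mathrm{d}F'$ (adaptive
quadrature, relative tolerance $10^{-8}$, memoised per force) and
$\Delta g_c^{el}(F) = \frac{k_BT}{a}\ln\frac{u}{\sinh u}$, $u = Fa/k_BT$,
evaluated in overflow-safe form. The total coverage is capped at 100%
(`equilibrium_ideal()` scales all modes proportionally onto the constraint
when the unconstrained optimum over-fills the polymer — the cap itself is
physical, the proportional allocation across modes is a package convention;
single-mode systems are unaffected).

Because the naked elastic cost grows roughly as $F^2/K_0$ at high force
while the covered term grows only linearly, tension eventually expels the
ligands. Balancing $\epsilon^b$ against the dominant term gives the
closed-form estimate $F_t \sim \sqrt{\epsilon^b K_0/(m d_0)}$
(`transition_force_approx()`), about 50 pN for the SSB-like reference
parameters; the full model puts the actual collapse of the coverage far
lower, at 10–15 pN (`transition_force()`):

```{r transition}
transition_force_approx(ssdna, ssb)
transition_force(ssdna, ssb, threshold = 0.5, statistics = "ideal")
```

Two numerical conventions deserve note. First, "the" transition force is
not uniquely defined by a smooth coverage curve; the package defines it as
the 50% crossing of the capped equilibrium coverage, with the threshold
exposed as a parameter so sensitivity can be probed (the crossing is located
by bracketing and bisection to $10^{-3}$ pN). Second, at high coverage the
ideal-gas entropy underestimates crowding; the one-dimensional hard-rod
(Tonks) gas gives the single-mode closed form

$$c(F) = \frac{1}{1 + 1/W_0\!\big(\tfrac{m}{N} e^{E(F)/k_BT}\big)},$$

with $W_0$ the principal Lambert W branch — this predicts a maximum coverage
strictly below 100% (`equilibrium_coverage_tonks()`). The implicit hard-rod
equilibrium contains the term $\ln(N/m)$; this reading is the only one
algebraically consistent with the Lambert-W closed form (substituting
$y = c/(1-c)$ gives $y e^y = \frac{m}{N}e^{E/k_BT}$), and the package
verifies the closed form against direct root-finding of the implicit
relation in its tests. Since $E/k_BT$ is of order 30 for realistic binding
energies, $e^{E/k_BT}$ can overflow; all such exponentials are carried in
log space, and $W_0(e^\rho)$ is evaluated by a dedicated Newton iteration
on $w + \ln w = \rho$ that starts from a provably-below-root initial guess
(so convergence is monotone) and carries a hard iteration cap. A
general-purpose Lambert-W routine with an uncapped fixed-tolerance loop is
not safe here: we found arguments in the physically relevant range on which
such a loop fails to terminate.

```{r tonks}
eq <- equilibrium_curve(ssdna, ssb, forces = seq(0.5, 25, by = 0.5),
                        statistics = "ideal")
tk <- equilibrium_curve(ssdna, ssb, forces = seq(0.5, 25, by = 0.5),
                        statistics = "tonks")
plot(eq$force_pN, eq$coverage, type = "l", xlab = "Force (pN)",
     ylab = "Equilibrium coverage")
lines(tk$force_pN, tk$coverage, col = 2)
legend("topright", c("ideal gas (capped)", "Tonks gas"), col = 1:2,
       lty = 1, bty = "n")
```

## Binding kinetics and transient shortening

Mean-field kinetics treat the ligand counts as continuous variables (no
discrete placement or parking statistics; the effective rates absorb the
leading overlap effects). For one mode,

$$\frac{\mathrm{d}n}{\mathrm{d}t} = k_b\,\frac{N - n m}{m} - k_r\,n,$$

whose solution from an empty polymer is exponential saturation with
equilibrium coverage $1/(1 + k_r/k_b)$ (`one_mode_closed_form()`). Two
modes couple through the shared pool of naked monomers; with different
binding/release time scales, or with direct mode conversion, the extension
at fixed force can be *non-monotone in time*: a fast, strongly compacting
mode fills the polymer first and is then displaced by a slower mode that
occludes fewer monomers, so the molecule first shortens and then lengthens.

For direct conversion in sets of $s$ ligands (mode 1 occluding more
monomers than mode 2, $m_1 > m_2$), the conversion flux is parsed as

$$-k_{1\to2}\,n_1 + k_{2\to1}\,n_2\,\frac{N - n_1 m_1 - n_2 m_2}{m_1 - m_2},$$

added with opposite signs to the two equations: conversion $1\to2$ acts per
ligand (the set size cancels in the mean-field limit, $s\,k\,(n/s)$), while
$2\to1$ must recruit $m_1 - m_2$ free monomers per converted ligand and is
therefore proportional to the hole count. This parsing was chosen for
dimensional consistency, exact reduction to the plain two-mode system when
the conversion rates vanish, and because it reproduces the expected
phenomenology (transient mode-1 dominance handing over to mode 2); it is a
documented modelling choice, not the only conceivable one.

The systems are integrated with `deSolve`'s stiff-capable `lsoda` at
relative tolerance $10^{-10}$ and absolute tolerance $10^{-12}N$ — rates in
realistic schemes span five orders of magnitude, and at these tolerances
the integrator reproduces the one-mode closed form to better than $10^{-8}$
relative everywhere. The default output grid is 400 log-spaced points from
$10^{-3}/k_\mathrm{fastest}$ to $20/k_\mathrm{slowest}$. Negative count
excursions beyond $-10^{-9}N$ abort; smaller ones are clamped to zero with
a warning.

```{r kinetics}
sch <- kinetic_scheme(list(
  binding_mode(m = 65, a = 5, kb = 1, kr = 0.1, label = "mode1"),
  binding_mode(m = 35, a = 5, kb = 5e-2, kr = 1e-5, label = "mode2")))
traj <- integrate_kinetics(sch, ssdna, force = 5)
plot(traj$time, traj$extension, log = "x", type = "l", xlab = "Time (s)",
     ylab = "Extension (nm)")
```

## Fitting: what is identifiable, and how the fits work

`fit_fec()` recovers the coverage $c$, Kuhn length $a$, and site size $m$
from a force-extension curve; `fit_kinetics()` recovers effective rate
constants from an extension trace at fixed force. Choices that were
genuinely open and how they were resolved:

* **Loss in extension space** (nm²): the measured quantity in a
  force-clamp experiment is extension at set force, so residuals are taken
  there, optionally weighted per point. The loss, weighting and start
  strategy are surfaced in the fit report rather than hidden.
* **Deterministic multi-start**: bounded quasi-Newton (`nlminb`) from a
  fixed low-discrepancy Halton grid over the bounds (8 starts by default),
  so fits are bit-reproducible without a seed.
* **Integer site size**: $m$ counts monomers, and relaxing it continuous
  creates a flat ridge with $a$ (only $a/m$ matters at high force). When
  freed, $m$ is profiled over an integer grid with a continuous sub-fit per
  candidate; the profile is kept on the fit object, so a flat profile —
  the signature of a high-force-only design — is visible rather than
  silently resolved. Standard errors come from the curvature of the loss at
  the optimum and are labelled approximate; directions of vanishing
  curvature get infinite rather than fabricated errors.
* **Rates in log space**: effective rates span decades, so
  `fit_kinetics()` optimises $\log_{10} k$ with bounds.

```{r fit}
curve <- generate_fec(ssdna, binding_mode(m = 35, a = 5), coverage = 0.6,
                      forces = 10^seq(-1, log10(60), length.out = 120),
                      noise_sd = 2, seed = 7)
fit <- fit_fec(curve, ssdna, free = c("c", "a"), start = list(m = 35))
summary(fit)
```

## The synthetic-data generator

`generate_fec()` and `generate_kinetic_trace()` evaluate the forward model
and add i.i.d. Gaussian extension noise with an explicit seed (the caller's
RNG state is saved and restored, so no global state leaks; identical
arguments give bit-identical data). They emulate the *model's own* data:
independent homoscedastic noise on a clean force grid. Real traces have
drift, force-calibration error, correlated noise, secondary-structure
artefacts at low force, and discrete binding events; passing the package's
recovery tests therefore demonstrates correctness of the estimator under
the stated model, not robustness to those effects. A noise level of 2 nm
(roughly 0.1% of the reference contour length) is used as the default
"realistic" scale in the examples and tests.

## Degenerate inputs and numerical corners

* The Langevin function is evaluated by series below $u = 10^{-4}$ and in
  the form $1 + 2/(e^{2u}-1) - 1/u$ above, avoiding cancellation and
  overflow; $\mathcal{L}(0) = 0$ exactly.
* The XWLC solve brackets the root on $[0,\,1 + F/K_0)$ where the residual
  is strictly increasing (a property asserted by test, not assumed), then
  polishes with Newton steps; residuals stay below $10^{-9}$ from
  $10^{-3}$ to $10^{3}$ pN.
* Zero force returns exactly zero extension and zero elastic free energies;
  $n_i = 0$ contributes nothing to the mixing entropy ($n\ln n \to 0$).
* Over-occlusion ($\sum n_i m_i > N$) is rejected at the type boundary.
* Coverage-form inputs are converted to counts once, at the boundary; a
  single internal representation avoids double bookkeeping.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the reference system
($N = 5080$ monomers) throughout: equilibrium curves on ~30–80-point force
grids, kinetic trajectories on 400-point time grids, force-extension fits
on 60–200-point curves, and Monte-Carlo checks with 20–100 seeded
replicates. These sizes were chosen as representative of a single
experimental pulling cycle.

## Known limitations

* Cooperative binding, overlap non-linearities, and discrete (parking)
  placement statistics are out of scope; the hard-rod correction covers
  crowding entropy only, and only for a single mode.
* The multi-mode 100%-cap allocates proportionally across modes — a
  convention, untestable from single-mode data.
* Kinetic rates are *effective*: solution concentration is absorbed into
  $k_b$, so fitted rates are condition-specific.
* The closed-form transition estimate neglects the covered-chain term and
  the sub-quadratic parts of the naked free energy; it is an order-of-
  magnitude tool (off by ~4× for the reference system, by design shown
  alongside the full computation).
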