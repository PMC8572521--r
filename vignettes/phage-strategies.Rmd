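---
title: "Modelling phage infection strategies in a fluctuating chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage infection strategies in a fluctuating chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagestrat)
```

## The model

`phagestrat` simulates two bacterial species competing for one limiting
nutrient in a chemostat, each attacked by its own bacteriophage. Seven state
variables evolve in normalized biovolume units: uninfected bacteria $B_1,
B_2$, infected bacteria $I_1, I_2$, free phages $P_1, P_2$ and the dissolved
nutrient $N$. Per-capita growth follows a Type-2 (Monod) response

$$G_k(N) = x\, y_k \frac{N}{N + N_H},$$

with a metabolic rate $x$ shared by both species and scaling constants
$y_1 > y_2$ distinguishing the fast from the slow grower. The full dynamics
are

$$\dot B_k = G_k(N) B_k - x B_k - i B_k P_k,$$
$$\dot I_k = (1 + c)\, i B_k P_k + [g_k]\, G_k(N) I_k - x I_k - s_k I_k,$$
$$\dot P_k = n\, s_k I_k - c\, i B_k P_k - d P_k,$$
$$\dot N = D(t) (N_0 - N) - \sum_k G_k(N) B_k - \sum_k [g_k]\, G_k(N) I_k
  + \sum_k (1 - n)\, s_k I_k,$$

where $i$ is the (normalized) adsorption rate, $c$ the phage-to-bacterium
biovolume ratio, $n$ the burst volume fraction, $d$ the phage decay rate and
$D$ the chemostat turnover. Lysis releases the fraction $n$ of infected-cell
biovolume as phage and returns the remainder $1 - n$ to the nutrient pool —
the *viral shunt* (toggled by `shunt_enabled` for comparison runs). The
nutrient pool is shared, so consumption and shunt release sum over both
species even though the infection terms are species-specific.

### Infection strategies

The strategy enters solely through the lysis (phage induction) rate $s_k$ as
a function of total host density $h_k = B_k + I_k$:

* **lytic** — constant: $s_k = s_{\max}$;
* **Piggyback-the-Loser (PtL)** — increasing sigmoid
  $s_k = s_{\max} h_k^2 / (h_k^2 + S_H)$: induction rises with host
  abundance, so lysogeny dominates when hosts are rare;
* **Piggyback-the-Winner (PtW)** — decreasing law
  $s_k = s_{\max} / ((h_k r)^2 + H)$: induction is suppressed when hosts
  abound;
* **none** — phage-free control; infected and phage compartments are held
  at zero.

The lysogenic/lytic life-cycle switch is encoded by the indicator $[g_k]$:
infected cells grow — and, by the same token, consume nutrient — exactly
while the current induction rate does not exceed the switching rate
$s_{\text{switch}}$. Because the PtL law increases and the PtW law decreases
in $h_k$, the single rule `lysis rate <= s_switch` yields
lysogeny-when-rare for PtL and lysogeny-when-abundant for PtW. At the
default $s_{\text{switch}} = 0.0033\,h^{-1}$ (1% of $s_{\max}$) the switch
sits at host density 0.201 for PtL and 19.90 for PtW
(`switch_density()`), i.e. $2.01\times10^6$ and $1.99\times10^8$
particles/mL.

Purely lytic infections never grow. Infected cells are not re-infected (no
$i I_k P_k$ term), and the uninfected compartments are not diluted by the
chemostat outflow — washout acts on the nutrient only.

### Environmental fluctuation

Resource variability is a sinusoidal modulation of the turnover rate,

$$D(t) = a D \sin(2\pi t / T) + D,$$

with relative amplitude $a < 1$ (positivity) and period $T$. The mean over
one period is exactly $D$, so forcing changes the *timing* of supply, not
its average.

## Units

Laboratory abundances (particles/mL) are converted to normalized biovolume
by dividing by the bacterial half-saturation abundance
$N_H = 10^7$ particles/mL; phage abundances are additionally scaled by the
phage-to-bacterium biovolume ratio $c = 3.14\times10^{-4}$. A laboratory
adsorption rate in mL/h therefore rescales by $N_H / c$:
$1.64\times10^{-10}$ mL/h becomes $\approx 5.22\,h^{-1}$. The bundled
defaults keep the conventional rounded value `i_norm = 5.23`. Two printed
reference numbers are mutually inconsistent at the third digit (the phage
initial density 3.10e-4 versus $10^7 c / N_H = 3.14\times10^{-4}$); the
package reproduces both as given — initial conditions use 3.1e-4, the
adsorption normalization uses $c$ — rather than forcing a consistency the
source values lack.

The metabolic rate $x = 0.0206\,h^{-1}$ is taken as a fixed constant; the
body-mass conversion chain behind it is out of scope.

## Parameters at a glance

| parameter | default | units | meaning |
|---|---|---|---|
| `x` | 0.0206 | 1/h | metabolic rate (growth scale and loss) |
| `y1`, `y2` | 7.5, 4 | — | metabolic scaling, fast/slow grower |
| `N_H` | 1 | — | half-saturation density (defines the unit) |
| `i_norm` | 5.23 | 1/h | normalized adsorption rate |
| `c` | 3.14e-4 | — | phage/bacterium biovolume ratio |
| `n` | 0.02 | — | burst volume fraction (1−n recycled) |
| `s_max` | 0.33 | 1/h | maximum lysis rate |
| `d` | 0.0866 | 1/h | phage decay |
| `D` | 1/24 | 1/h | mean turnover rate |
| `N0` | 2 | — | supply concentration |
| `SH` | 4 | — | PtL half-saturation (squared density) |
| `r`, `H` | 0.5, 1 | — | PtW correction parameters |
| `s_switch` | 0.0033 | 1/h | life-cycle switching rate |
| `a`, `T` | 0, 720 | —, h | forcing amplitude and period |

Growth-rate variants (`y1`, `y2`) of (3.75, 2) and (15, 8) represent weak
and strong bacteria–environment coupling; `s_switch` values of 0.001 and
0.165 are used by the switching-point sensitivity presets.

## Numerical choices

* **Integrator.** Adaptive embedded Runge–Kutta 5(4) (Cash–Karp pair,
  `deSolve::rkMethod("rk45ck")`) on a C implementation of the right-hand
  side. An R implementation (`phage_derivs`) is exported as the readable
  reference; the two are tested to agree to 1e-6.
* **The growth switch is evaluated inside every RHS call** — no event
  detection. The discontinuity is handled by the step-size control; the RHS
  stays a pure function of $(t, y)$.
* **Clamping.** Components pushed marginally negative by the integrator are
  treated as zero when evaluating rates; the stored solution itself is not
  floored, and trajectories are verified to stay above $-10\,\text{atol}$.
* **Tolerances.** Single-trajectory runs default to
  `rel_tol = abs_tol = 1e-8`. The scan and sweep drivers default to
  `rel_tol = 1e-6, abs_tol = 1e-8`: persistence classification at the
  attractor level is unchanged down to `rel_tol = 1e-11` (checked for the
  sharpest boundary the package measures), while the stiffest cells
  (Piggyback-the-Loser at supply 30) integrate about 75 times faster.
* **Horizon.** Default `t_end` = 43,800 h (five years) with the final 20%
  analysed, so even one-year forcing periods express several cycles before
  the analysis window and one full cycle inside it. Output is sampled
  hourly (every 2 h in sweeps).
* **Initial state.** The reference initial condition ($B_k = 0.83$,
  $I_k = 0.17$, $P_k = 3.1\times10^{-4}$, $N(0) = N_0$) is used everywhere;
  attractor-level results were checked to be insensitive to $N(0)$ chosen
  anywhere in the admissible supply range.

## Analysis layer

**Persistence classification.** A component survives if its *maximum* over
the post-transient window reaches the extinction threshold (default 1e-6
normalized, about 10 bacteria particles/mL — far below every attractor
scale, far above integrator noise). The maximum, not the final value, so
populations on large-amplitude cycles that dip low are not misclassified.
Each phage and its infected compartment count as one *infection* state that
survives only if both $I_k$ and $P_k$ do. The persistence code 0–4 counts
surviving states among {fast grower, its infection, slow grower, its
infection}; the full flag vector is kept alongside, so combinations off the
canonical ladder lose nothing. Raising the threshold can only lower the
code (tested). Extinction is *not* hard-coded into the dynamics — the ODEs
have no absorbing floor; it is purely a classification-time judgement.

**Extrema detection.** Post-transient local extrema by sign change of the
discrete differences, with a relative-amplitude floor of 1e-3 below which a
series is declared steady and summarised by its mean. Plateaus are carried
through so flat-topped cycles register once.

**Bifurcation scans** run one simulation per supply value $N_0 \in
[0.6, 30]$ and record per-variable extrema plus the persistence state; the
forced variant uses $a = 0.5$, $T = 7$ days. (A tabulated period list
24/162/720/8760 h exists in the sources with 162 h where the scan
convention is 7 days = 168 h; the scans follow the 7-day convention, and
the table value remains available by overriding `bif_T_h`.) Integration
failures are recorded per grid point, never fatal to a scan.

**2-D sweeps** classify persistence on amplitude × supply (period fixed at
30 d) or period × supply (amplitude fixed at 0.9, periods log-spaced over
1 d…1 yr) grids, supply in [0.6, 8]. Default resolutions (60 supply points
for scans; 25 × 25 sweeps) resolve the region boundaries at desk-scale
cost; the test suite uses 15 × 15 versions of the same grids. All drivers
are deterministic: repeated runs are bit-identical.

**Threshold bisection** (`find_critical_N0`) brackets a survival transition
in $N_0$ and bisects the simulated predicate — either one component's
survival flag or a minimum persistence code. Under the reference PtW
parameterisation the fast grower's extinction boundary under constant
supply measures $N_0 = 10.05$ (bisection tolerance 0.05); this value is
robust to integrator tolerance (1e-6…1e-11 relative), horizon (1–10
years), extinction threshold (1e-4…1e-8) and initial nutrient level.
Mechanistically, above the boundary the transient phage bloom crashes both
uninfected populations and the system reorganises onto a
lysogenic-infected-resident attractor on which the fast grower's invasion
rate $G_1(N) - x - i P_1$ is negative, so the extinction is self-
maintaining. Near such boundaries trajectories traverse subnormal
floating-point magnitudes, which is why survival there is a genuinely
knife-edge numerical judgement; the bisection protocol pins every setting
for reproducibility.

## What the bundled scenarios show

With the reference parameters at $N_0 = 2$: without phage the slow grower
is competitively excluded (persistence code 1); adding the phage under any
of the three strategies yields full four-state coexistence (code 4) — the
classic top-down rescue of a weaker resource competitor. Enabling the viral
shunt shifts the onset of bacterial coexistence to lower supply for every
strategy (enrichment by recycling, measured at ≈ 0.33–0.35 supply units).
Under fluctuation sweeps, amplitudes up to 50% leave each strategy's
coexistence range unchanged; PtL sustains full coexistence over at least as
much of the grid as PtW; and raising growth rates ($y_1 = 15$, $y_2 = 8$)
widens full coexistence under period forcing for the lytic and PtL models.
Each statement above is computed by the test suite or the acceptance
script; none is asserted beyond what those runs measure.

## What the model leaves out

The generator is a deterministic mean-field idealisation. It omits:
demographic stochasticity and stochastic prophage induction; explicit
latent periods and burst-size kinetics (lysis is a rate, not a delay);
re-infection and superinfection immunity dynamics beyond the single-phage
assumption; evolution of resistance; stoichiometric (C/N/P) accounting of
the lysate; spatial structure and diffusion limitation; and any
non-sinusoidal (stochastic or pulsed) resource variability. Passing tests
therefore demonstrate the internal consistency and qualitative structure of
this idealisation — coexistence ranges, orderings between strategies,
direction of the shunt effect — not quantitative predictions for any real
community. Dilution acts only on the nutrient pool, a deliberate reading of
the model equations; chemostat variants that also wash out cells and
particles would shift every boundary.

## Session

```{r}
sessionInfo()
```
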