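---
title: "Modelling culture-dependent mESC phenotypes with nanogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling culture-dependent mESC phenotypes with nanogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

nanogate simulates a four-species stochastic gene network for mouse
embryonic stem cell (mESC) pluripotency. The species are the Oct4-Sox2
heterodimer ($OS$), Nanog ($N$), Rex1 ($R$, the experimentally accessible
reporter) and Erk activity ($E$, the output of autocrine FGF4/MAPK
signalling). All interactions are described at the transcriptional level
with activating Hill kinetics $H(x) = x^n/(k^n + x^n)$, a single shared
half-saturation constant $k$, and Hill coefficient $n = 2$ (Nanog acts as a
homodimer; Oct4-Sox2 as a heterodimer). The deterministic drift is

$$
\begin{aligned}
\dot{OS} &= s_{12}\,H(OS) - d_{OS}\,(1 + i_{OS} Y_{in})\,OS\\
\dot{N} &= \bigl[s_3 H(OS) + s_4 H(N)\bigr]\,\frac{1}{1 + p\,H(E)}
            - d_N\,(1 + i_N Y_{in})\,N\\
\dot{R} &= s_5 H(OS) + s_6 H(N) - d_R\,(1 + i_R Y_{in})\,R\\
\dot{E} &= s_7 H(OS) - d_E\,E
\end{aligned}
$$

Two feedback structures organise the dynamics:

* **FGF4/Erk negative feedback.** Oct4-Sox2 drives Erk (via FGF4), and Erk
  represses Nanog transcription with strength $p$. The repression factor
  $1/(1 + p H(E))$ multiplies both Nanog production terms; whether it
  should act on only the autoregulatory term is not decidable from the
  biology, and applying it to the bracketed sum is the form under which
  $p = 0$ removes the feedback exactly. Culture conditions map onto $p$:
  LIF/serum has active Erk signalling ($p > 0$, here 15), 2i blocks
  Mek/Erk ($p = 0$).
* **The Nanog gate on differentiation.** An extrinsic differentiation
  signal $Y$ is transmitted into the cell as
  $Y_{in} = Y\,k_Y^h/(k_Y^h + N^h)$, a *decreasing* S-shaped function of
  Nanog: only cells that have lost Nanog feel the signal, which then
  raises the degradation of $OS$, $N$ and $R$ by the factors
  $(1 + i_j Y_{in})$. Linear enhancement is the minimal choice consistent
  with "the signal increases degradation". An Oct4-Sox2-negative cell is a
  differentiated cell. The decreasing form of the gate is the only one
  consistent with the gate-keeper role of Nanog (high Nanog blocks
  propagation); we note that one sentence in the source literature states
  the opposite limit and treat it as a typographical slip.

Noise enters as multiplicative, zero-mean Gaussian fluctuations on the
three transcription-factor species only ($\sigma_{OS}, \sigma_N, \sigma_R$;
the signalling species $E$ and the gate are noise-free). The
Euler-Maruyama update for $X \in \{OS, N, R\}$ is
$X \leftarrow \max\{0,\; X + f_X\,\Delta t + \sigma_X X \sqrt{\Delta t}\,Z\}$,
with clamping at zero applied after the full update (the noise is evaluated
at the pre-update concentration). Multiplicative noise is what makes the
low- and high-expressing subpopulations equally wide on a logarithmic
fluorescence scale, which is how the data look.

Units are minutes and arbitrary concentration units throughout
(three days of culture = 4320 min).

## The calibrated reference parameter set

No reference parameter table ships with the model's source literature, so
the package recovers one by calibration ([`calibrate()`]) against the
phenotype constraints and freezes the accepted set as
`inst/extdata/params_lif_serum.cfg`:

| constraint | target |
|---|---|
| bimodal Nanog/Rex1 under LIF/serum | ~20% NL cells at 3 days, NH/NL medians ~2 log10 apart |
| unimodal high expression under 2i | monostable NH at $p = 0$, all else unchanged |
| homogeneous Oct4-Sox2 | low CV, unimodal |
| rare state transitions | ~0.05 valid transitions/cell/24 h |
| prolonged residences | ~9 days (NL), ~11 days (NH), exponential |
| structural landmarks | bistable at $p = 15$; $s_4 \in \{30,40,50\}$ inside the bistable $s_4$ window |

The search is staged: a cheap deterministic structural screen (fixed-point
counts via `find_fixed_points()`), a stochastic screen scoring short
population runs, and a local refinement of $\sigma_N$ and $s_4$ against the
NL fraction and the transition rate. It is Latin-hypercube seeded, budget
bounded and idempotent given a master seed.

Design choices worth recording:

* **The network clock.** The degradation rates are $d_j = 0.04$/min
  (effective turnover half-life ~17 min at the transcript level at which
  the model is written). The clock matters because the transition-validity
  rule (below) compares basin relaxation with a fixed one-hour window: with
  slow clocks ($d \lesssim 0.01$/min) trajectories hover near the saddle
  for hours and shallow boundary crossings accumulate as spurious "valid"
  transitions, and no noise amplitude then yields clean exponential
  residence times of several days. $d = 0.04$/min gives committed, rare
  switches whose residence distributions are exponential (empirical-vs-
  fitted CDF distance < 0.06 in the shipped configuration).
* **The landscape geometry** is set analytically before any stochastic
  tuning: $OS^* = 2k$ with $H(OS^*) = 0.8$; $H(E^*) = 0.467$ so that
  $p = 15$ gives a repression factor of 1/8; $s_4 = 35$ sits mid-window in
  the bistable interval $(20, \sim 72)$; $s_3$ sets the NL level roughly
  two decades below NH. Only $\sigma_N$, $s_3$ and $s_4$ were then refined
  numerically.
* **Initialisation.** Three-day population snapshots start every cell at
  the Nanog-high fixed point, emulating a sorted NH (or 2i-adapted)
  population re-establishing heterogeneity. This is not an arbitrary
  choice: mean residences of 9/11 days imply a *stationary* NL share near
  45%, so the observed ~20% at day 3 is only consistent with a population
  that started NH and has not yet equilibrated.
* $Y = 0$ in all self-renewal analyses (Figs of the bistability,
  transition and sweep kind); $Y > 0$ only in the differentiation
  experiments. $k_Y = 4$ places the gate threshold between the NL level
  (~1.2) and the basin boundary (~8.4), so the gate opens only after
  commitment to NL.

## Basins, valid transitions and residence times

With noise, cells no longer sit at fixed points but reside in attractor
basins. The NL/NH boundary is the Nanog coordinate of the saddle between
the two stable states (`basin_boundary()`; it also equals the middle root
of the one-dimensional reduced Nanog map, which the test-suite uses as an
independent oracle for the 4-D Newton solver). A boundary crossing counts
as a **valid transition** only if the cell then stays on the destination
side for at least 60 consecutive minutes; shorter excursions are treated as
fluctuations and do not reset the basin label. Basin membership is assessed
on the raw Nanog series without smoothing -- the residence rule is the
filter. Cells ending inside an unvalidated excursion keep their prior
label. Residence intervals bounded by two valid transitions are uncensored;
leading/trailing intervals are censored and excluded from the means.

Under the reference set, a 1000-cell, 3-day run yields ~18-20% NL cells
about two decades below the NH mode and ~0.07-0.09 transitions per cell per
day; a 500-cell, 100-day run yields mean residences near 9.5-10 days (NL)
and 10-10.5 days (NH) with near-exponential interval distributions. These
are the quantities `scripts/acceptance.R` recomputes.

One caveat belongs here rather than in a footnote. The transitions-versus-
noise curves at fixed $s_4$ rise from zero, attain an interior maximum and
decline once noise dominates (the validity rule then rejects almost
everything) -- the qualitative law holds. But the *numeric* noise amplitude
at which the decline sets in is, in this landscape, at $\sigma_N \approx
0.25$-$0.30$ for $s_4 = 40$, roughly twice the operating amplitude. A
decline threshold as close to the operating point as some published
figures suggest ($\approx 0.14$) would require the mean residence time to
fall from ~10 days to hours within a ~20% change of $\sigma_N$, i.e. an
escape-rate prefactor on the sub-second scale, which no minute-scale Hill
landscape can produce. The corresponding literal check in the acceptance
tests is expected to fail and is retained as an honest record.

## Differentiation after 2i withdrawal

Withdrawal is modelled as (i) a per-cell logistic ramp of the repression
rate, $p_i(t) = p_{max}/(1 + e^{-s(t - t_{mid,i})})$ with lognormal
midpoints (median 720 min, log-sd 0.5, slope 0.015/min, $p_{max} = 40$ --
beyond the upper fold near 28, so the NH state vanishes and every cell is
forced into NL); (ii) the differentiation signal at $Y = 5$; and (iii) a
reduced Rex1 turnover, scaling $(s_5, s_6, d_R)$ jointly by 0.06 so the
steady level is preserved while the kinetics slow (the noise amplitude
scales by $\sqrt{0.06}$, keeping the stationary spread invariant). The
lognormal-midpoint logistic is the minimal smooth, positive, unimodal
choice for "a time-dependent stochastic increase of $p$"; the midpoint
spread is what produces asynchronous Rex1 downregulation. The resulting
sequence per cell is NH$\to$NL switch, gate opening, then sudden Oct4-Sox2
collapse; a cell is classified differentiated (absorbingly) once its
Oct4-Sox2 stays below 10% of the starting level for 60 min. Absolute
differentiated fractions are not quantitative predictions: proliferation
and cell death are outside the model.

`fit_ramp()` estimates the ramp from population-mean relative expression
(qRT-PCR-like tables sampled every 3 h): stage 1 fits $p_{max}$, the
midpoint median and log-sd to the Nanog curve; stage 2 fits the Rex1
turnover scale with stage 1 frozen. Two numerical points: residuals are
taken on the log scale, because the late Nanog plateau (which identifies
$p_{max}$) is invisible in linear residuals; and the logistic slope is held
at its template value, because at 3-hourly sampling it trades against
$p_{max}$ and the midpoint along a flat valley of the objective. Every
objective evaluation simulates with the same seeds, so the fit is
deterministic. On synthetic truth the fit recovers $p_{max}$ and the
midpoint median within 15% and the turnover scale within a third.

## Synthetic observed data

No flow-cytometry or qRT-PCR measurements are available to the package, so
`gen_flow_sample()` and `gen_qpcr_timecourse()` generate surrogates with
the documented statistical shape: log-normal mixtures (default LIF/serum:
weights 0.2/0.8, modes two decades apart, log10-sd 0.25; 2i: one high
component) and delayed-exponential decay curves normalised to 1 at $t = 0$
(Nanog onset immediate, Rex1 delayed ~12 h). These emulate the *shape* of
reporter fluorescence and relative mRNA data -- bimodality, equal log-scale
widths, normalisation conventions -- but none of their values are measured
quantities, and passing tests against them shows internal consistency, not
agreement with any particular experiment. Real data in the same CSV shapes
can be substituted directly (`distribution_distance()` compares intensity
samples on the log10 CDF scale; binary cytometry formats are out of scope).

## Numerical choices and degenerate inputs

* Integration step $\Delta t = 0.1$ min by default; summary statistics move
  by well under two percentage points when the step is halved. An explicit
  stability warning triggers when $d_{max}\Delta t > 0.5$.
* Per-cell noise streams come from a counter-based splitmix64 generator
  keyed by (master seed, cell id) with Box-Muller normals, so populations
  are bit-reproducible, independent of execution order and of R's global
  RNG. R-level sampling (ramp midpoints, bootstrap, search designs) is
  seeded through `withr::with_seed`.
* Fixed points: multi-start damped Newton with central-difference Jacobians
  (relative step $10^{-6}$), drift-norm tolerance $10^{-8}$, relative
  deduplication at $10^{-6}$. The start lattice is logarithmic over
  $(OS, N)$ with $R$ and $E$ started at their algebraically slaved values
  -- the two fast variables are enslaved at any fixed point, so a full 4-D
  lattice would only multiply the cost. Zero-production axes degenerate the
  lattice to the origin, which is always included.
* Bifurcation scans solve each grid value independently and link branches
  by their per-value labels (the branches are well separated in Nanog);
  tie-breaks take the smaller Nanog value. The bistable interval is the
  maximal contiguous grid run with exactly two stable OS-positive states.
* Eigenvalue real parts within $10^{-8}$ of zero are labelled `marginal`
  and surfaced as a warning rather than silently classified.
* Bimodality (calibration): a two-component Gaussian mixture on log10
  values must beat one component by >10 BIC units with both weights >= 5%.

## Problem sizes

The shipped tests and the acceptance script use 1000 cells x 3 days for
snapshot phenotypes, 500 cells x 100 days for residence statistics,
120-400 cells for screens, fits and property checks, and 20 seeded random
parameter sets for the fixed-point oracle comparison. These sizes put
Monte-Carlo error well inside the tolerances being checked (binomial SE
~1.3 percentage points on the NL fraction; ~2000 uncensored residence
intervals per basin).

## Known limitations

* No proliferation, cell death, cell-cycle or cell-cell coupling: absolute
  differentiated-cell counts and any fitness-weighted population
  composition are outside scope.
* Transcription and translation are lumped; no delays or mRNA species.
* The parameter set is *a* set satisfying the published constraints, not
  *the* unpublished original; quantities not pinned by a constraint (e.g.
  absolute concentration scales) are conventional.
* Continuation is naive (no pseudo-arclength), adequate only because the
  branches here are well separated; fold points are located to grid
  resolution.
* The noise-axis caveat above: σ-axis landmarks from the source figures
  are not reproduced quantitatively, and the package documents why.
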