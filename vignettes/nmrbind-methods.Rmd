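---
title: "Models and methods behind nmrbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
library(dplyr)
```

nmrbind analyses three families of solution-NMR observables for a small
aromatic ligand interacting with a nicked DNA decamer duplex: dilution
chemical-shift series (self-association), diffusion coefficients
(binding constants), and free-vs-complexed shift tables (binding-site
mapping). This vignette explains the models, the conventions, the
tunable parameters, and the numerical and design choices, in the order
a user meets them.

## Units and sign conventions

Concentrations are millimolar everywhere. Dilution shift *changes* are
in Hz; chemical-shift-perturbation (CSP) tables are in ppm; diffusion
coefficients are in 10⁻¹⁰ m² s⁻¹. There is no unit autodetection — the
readers (`read_dilution_table()`, `read_diffusion_table()`,
`read_shift_table()`) each accept exactly one documented CSV dialect,
because silently converting Hz and ppm is the most likely way to ruin
such an analysis. A positive shift change always denotes a
low-frequency (upfield) shift, the signature of ring-current shielding
by aromatic stacking; CSPs are `delta_free - delta_complex` with the
same sign meaning.

## The isodesmic self-association model

A camptothecin-family ligand stacks indefinitely in water. The
isodesmic model assumes every stacking step has the same association
constant $K_a$. Writing $C = K_a L_0$ for total ligand concentration
$L_0$, the monomer concentration $m$ solves the mass balance
$L_0 = m/(1-K_a m)^2$, and the fast-exchange-averaged shift change
relative to the monomer shift is

$$\Delta\delta_{obs} \;=\; \Delta\delta_{max}\,
  \frac{2C + 1 - \sqrt{4C+1}}{2C},$$

where the fraction equals $K_a m$ — the stacked fraction — and
$\Delta\delta_{max}$ is the limiting shift change between monomer and
oligomer. The fraction lies in $[0,1)$, rises strictly with both $C$
and $K_a$, and the whole expression is antisymmetric in
$\Delta\delta_{max}$ (most protons shift upfield on stacking,
$\Delta\delta_{max}>0$; a few shift the other way and fit with a
negative value). `isodesmic_shift()` evaluates the algebraically
equivalent form $2C/(1+2C+\sqrt{1+4C})$, which avoids the subtractive
cancellation of the textbook expression at small $C$; the test suite
checks it against an independent bisection solution of the mass balance
at $10^{-8}$ relative accuracy.

### Reference-shift handling

Dilution tables are referenced to the lowest measured concentration:
the first point is 0 *by construction*, while the model's
$\Delta\delta_{obs}$ is referenced to the true (infinite-dilution)
monomer shift. At the lowest concentrations used here
(0.012–0.013 mM) the predicted stacking shift is a few Hz, so the
default in `fit_isodesmic()` treats the lowest-concentration shift as
the monomer shift, *excludes the construction-zero reference point*
(it carries no information — it is zero whatever the parameters), and
fits the remaining changes directly. This choice was validated against
the tabulated per-proton fits of the packaged dilution data: it
reproduces all thirteen compound-1 constants to three decimals, e.g.

```{r}
dil1 <- read_dilution_table(nmrbind_example("dilution_compound1.csv"), "1")
fit_isodesmic(filter(dil1, proton == "H9"))
```

Two alternatives are provided for sensitivity analysis:
`include_reference = TRUE` keeps the zero point in the residuals, and
`offset_free = TRUE` adds a third fitted parameter $\delta_0$ so the
model becomes $\Delta\delta_{max}\,x(K_a c) + \delta_0$. The offset
variant is also the estimator matched to the synthetic generator (see
below), whose re-referencing makes the true offset
$-\Delta\delta_{obs}(c_{min})$.

### Optimiser

The objective is mildly ill-conditioned — $K_a$ and
$\Delta\delta_{max}$ are strongly correlated, since over a limited
concentration window a larger limiting shift with a smaller constant
produces nearly the same curve. `fit_isodesmic()` therefore uses
Levenberg–Marquardt (`minpack.lm::nls.lm`, `ftol = ptol = 1e-14`,
up to 500 iterations) on $\log K_a$ (which enforces positivity),
restarted from $K_a^{(0)} \in \{0.5, 2, 8\}$ mM⁻¹ with
$\Delta\delta_{max}^{(0)}$ set to twice the most extreme observed
change, keeping the best restart. Non-convergence is never silent: the
`converged` flag is carried into every downstream summary. A test
compares the optimum against an exhaustive profiled grid search
($\Delta\delta_{max}$ solved in closed form at each $K_a$ on a refined
log grid).

### Compound-level aggregation

`summarize_ka()` reports the unweighted arithmetic mean and the sample
($n-1$) standard deviation of the included per-proton constants.
Individual protons can deviate for reasons outside the model (overlap,
exchange contributions); exclusions are therefore *explicit user
input*, never auto-detected — automating an outlier rule would invent
a criterion the data do not define. With the packaged data the
analyst's exclusions are H12 (compound 1) and H23, H19 (compound 2).

## DOSY binding analysis

Binding of the ligand (L, ~475 Da) to the nicked duplex (~6.9 kDa) is
quantified from diffusion coefficients in the equimolar mixture under
four hard model assumptions, echoed in every report:

1. 1:1 stoichiometry, $\mathrm{DNA} + \mathrm{L} \rightleftharpoons
   \mathrm{DNA\cdot L}$ with $K_a = [\mathrm{DNA\cdot L}]/([\mathrm{DNA}][\mathrm{L}])$;
2. fast exchange, so observed coefficients are population-weighted
   averages;
3. ligand self-association neglected in the mixture (defensible here
   because the measured binding constants exceed the stacking constants
   by an order of magnitude);
4. the complex diffuses like the free duplex, so the observed duplex
   coefficient in the mixture stands in for $D_{complex}$.

The chain implemented by `analyze_binding()` is
$MF_L = (D_{obs} - D_{complex})/(D_L - D_{complex})$, then
$[\mathrm{DNA\cdot L}] = (1-MF_L)\,C_L$, then
$K_a = [\mathrm{DNA\cdot L}]/((C_{DNA}-[\mathrm{DNA\cdot L}])(C_L-[\mathrm{DNA\cdot L}]))$.
Assumption 4 can be replaced by an independently measured complex
coefficient (`d_complex =`), which also enables the duplex-side
consistency check `complex_conc_dna_side()` — with the default
approximation that contrast is degenerate by construction.

Two conventions matter in practice. First, the free-ligand coefficient
must come from the *most dilute* available measurement
(`as_binding_experiment()` enforces this), because self-stacking
depresses the apparent coefficient at working concentrations. Second,
mole fractions outside $[0,1]$ by more than the propagated measurement
noise abort the analysis rather than being clipped: such values mean
the two-state fast-exchange model is wrong for these data, and a
silently clipped fraction would launder that failure into a plausible
number.

### Uncertainty of the binding constant

`ka_sigma` is the first-order (delta-method) propagation of the stated
coefficient uncertainties through the closed-form chain, with a
central-difference gradient. Near saturation $K_a$ depends
hyperbolically on the complex concentration
($K_a = x/((C-x)^2)$ at equimolar totals), so its sampling
distribution is strongly right-skewed and heavy-tailed: a raw
Monte-Carlo standard deviation is dominated by draws that approach
saturation and can exceed the delta-method value by orders of
magnitude while the bulk of the distribution agrees well.
`ka_uncertainty_mc()` therefore reports, besides the raw SD, a robust
sigma — half the central 68.27% interquantile width, the
Gaussian-equivalent spread customarily quoted for heavy-tailed derived
quantities — after dropping (and counting) draws outside the physical
domain. The test suite requires delta-method and robust Monte-Carlo
sigmas to agree within a factor of two on the packaged experiments.
At the precision of the packaged coefficients (±0.05 on ~1 unit) the
relative uncertainty of $K_a$ is large, roughly 75–90%; the bound
*fraction*, in contrast, is determined to a few percent. Reports quote
both.

`check_concentration_trend()` implements the qualitative dilution
check: a self-associating species' apparent coefficient should be
non-increasing with concentration within the stated uncertainties;
consecutive increases beyond the combined sigma are flagged.

## Chemical-shift perturbation and nick localisation

`compute_csp()` keeps the raw difference and a 3-decimal rounded value
(the precision of ppm tables). `flag_significant()` applies
$|\Delta\delta| \ge$ 0.02 ppm to the rounded value; with
`rounding_slack = TRUE` (default) the comparison allows 0.001 ppm of
slack, admitting values printed as 0.019 — at the resolution limit of
a rounded table, a 0.019 and a 0.020 are not distinguishable. Both
behaviours are tested; neither is asserted to be "the" correct reading
of a rounded table.

The duplex map (`nick_map()`) places the nick between T5 and G6 of
strand 1; the default nick-adjacent set is the two base pairs on each
face — G6–C15 and T5–A16 flanking the nick, T4–A17 and T7–A14 adjacent
to them. `localize_to_nick()` counts flagged DNA protons inside this
set. On the packaged compound-1 table all seven flagged protons are
nick-adjacent; on the compound-2 table nine of ten are — G3 H1′
(0.022 ppm) sits three units from the nick, a reminder that CSPs
report shielding changes, not contacts, and long-range ring-current
effects can leak past the binding site.

## The synthetic generators

`synthetic_spec()` freezes ground truth, grids, noise levels and the
seed; the three generators are bit-reproducible given a spec and
produce tables the readers accept unchanged. The noise model is
additive homoscedastic Gaussian on each observable (Hz, coefficient
units, ppm), matching the single symmetric uncertainties with which
such measurements are reported; no heteroscedastic or
across-proton-correlated structure is emulated. Defaults are the
study's own conditions: the 8-point dilution grid from 0.013 to
0.789 mM, a stacking constant of 6.4 mM⁻¹ with a 112 Hz limiting
shift and 3 Hz shift noise, a binding constant of 76 mM⁻¹ with free
coefficients 2.12/0.75 and 0.05 coefficient noise, and the measured
free-duplex H1′ baseline with the compound-1 perturbation pattern and
0.005 ppm noise.

* `simulate_dilution_series()` applies the forward isodesmic model,
  adds noise, then re-references so the first point is exactly 0 —
  the convention of measured tables.
* `simulate_dosy_experiment()` solves the mass-action equilibrium at
  the true constant and forms the fast-exchange averages with the
  spec's complex coefficient. Setting `d_complex < d_free_dna`
  quantifies the bias of the duplex-coefficient approximation — a
  sensitivity study the analysis functions support via their
  `d_complex` argument.
* `simulate_csp_tables()` perturbs the baseline at named units and
  adds noise to the complexed table only.

Noiseless generation followed by the matching estimator is the
identity: exactly for DOSY and CSP, and exactly for dilution series
when the offset parameter is fitted (the re-referencing gives the
generated data a true offset of $-\Delta\delta_{obs}(c_{min})$, which
the two-parameter fit has no freedom to absorb).

### What the recovery study does and does not show

The parameter-recovery study (200 replicates on the study grid, 3 Hz
noise, true $K_a$ uniform in 2–10 mM⁻¹, fixed seed) achieves a median
relative $K_a$ error well under 25% when the estimator sees direct
observations of the model. Re-referencing changes this materially:
subtracting the noisy lowest-concentration measurement from every
point removes the absolute-offset information and roughly doubles the
effective noise, and no estimator recovers it — matched-offset
nonlinear least squares and generalised least squares on the
differenced model both show median errors around two to three times
the direct-observation figure. A comparative test asserts this
ordering. The practical reading: with shift noise at the few-Hz level,
per-proton stacking constants from an 8-point referenced dilution
series carry tens-of-percent uncertainty, which is why the
compound-level mean over many protons — not any single proton — is the
reported quantity.

Passing these simulations shows the estimators are correct *under the
assumed noise model*; real dilution series add concentration
measurement error, baseline drift and proton-specific exchange
broadening that the generators deliberately do not emulate.

## Numerical choices and degenerate inputs

* Both quadratic closed forms (`isodesmic_shift()`,
  `solve_equilibrium()`) use conjugate forms immune to subtractive
  cancellation; `solve_equilibrium(0, ...)` returns 0 and the large-
  $K_a$ limit approaches the stoichiometric bound smoothly.
* `free_fraction()` errors on zero diffusion contrast (binding
  unobservable by DOSY) rather than returning infinities.
* Readers reject non-numeric cells (naming row and column), duplicate
  concentrations, duplicate unit/class pairs, shifts outside
  0–20 ppm, and dilution series with a nonzero reference point; the
  Unicode minus and ASCII hyphen are both accepted.
* Degenerate summaries are defined: a single included fit reports its
  own $K_a$ with SD 0; an exclusion list that removes every fit is an
  error.
* Test problem sizes — 200 recovery replicates, 10⁴ Monte-Carlo draws,
  500 false-positive seeds — were chosen so the full suite exercises
  every stochastic claim in well under a minute of compute.

## Known limitations

The package consumes tabulated values only: no FID/JCAMP parsing, peak
picking, or Stejskal–Tanner fitting of gradient attenuation data.
Self-association supports only the isodesmic model (no dimerisation-
only or cooperative nucleation–elongation variants); binding supports
only 1:1 fast-exchange stoichiometry (no multi-site or slow-exchange
models); CSP flagging is a threshold rule, not a structural
calculation — no NOE-derived distances or docking. The printed
uncertainty of a literature binding constant cannot in general be
reproduced without knowing its error model; nmrbind reports its own
propagated and Monte-Carlo uncertainties instead.
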