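---
title: "Mechanistic dissolution, absorption, and virtual bioequivalence for racemic ibuprofen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic dissolution, absorption, and virtual bioequivalence for racemic ibuprofen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibuvbe)
```

## The problem

Immediate-release ibuprofen tablets are a classic case where the dissolution
rate, not permeability, limits the absorption rate: ibuprofen is a weak acid
(pKa 4.45) with a very low intrinsic solubility (0.068 mg/mL) whose total
solubility rises steeply with pH. Because the drug buffers its own particle
surface, the pH *at the particle surface* differs from the bulk medium pH and
becomes the single product-related parameter that distinguishes formulations.
This package implements that chain quantitatively: estimate the particle
surface pH from in vitro dissolution profiles, propagate it through a
gastrointestinal absorption model with per-enantiomer disposition, and ask
bioequivalence questions about hypothetical test products — safe spaces,
sample sizes, and virtual-trial success rates.

## The diffusion layer model

Each particle size bin dissolves by diffusion across a stagnant layer:

$$\frac{dr_i}{dt} = -\frac{D}{\rho\, h_i}\left(S(\mathrm{pH_s}) - C_b\right),
\qquad h_i = \min(r_i, h_\max),$$

with $D$ the aqueous diffusion coefficient, $\rho$ the true density, $C_b$
the bulk concentration (dissolved amount over vessel or lumen volume), and
the surface solubility given by the Henderson–Hasselbalch form for a
monoprotic acid, $S(\mathrm{pH_s}) = S_0\,(1 + 10^{\mathrm{pH_s} - \mathrm{pKa}})$.
The surface pH is held constant for a run — the model's central simplifying
assumption — so a single number characterizes a product in a medium. The
driving force is clamped at zero when $C_b \ge S$: neither particle growth
nor precipitation is modelled, and a bulk concentration above the solubility
at the *medium* pH only raises a supersaturation warning.

Staged protocols (an acidic pretreatment followed by the buffered treatment
medium) carry dissolved drug and remaining solid across the stage boundary;
volume and pH switch instantaneously.

### Numerical treatment

The solver integrates $u_i = r_i^2$ rather than $r_i$. In the $h_i = r_i$
regime $du/dt = -2D(S-C_b)/\rho$ is constant, so the equation stays smooth
as a bin empties and crosses $u = 0$; depleted bins simply stop contributing
to the solid mass (which uses $\max(u,0)$). This removes the $1/r$
singularity that otherwise stalls adaptive steppers at vanishing radii.
Dissolved mass is computed algebraically as dose minus remaining solid, so
in vitro mass balance holds to solver precision by construction.
Integration uses `deSolve::lsoda` with relative tolerance $10^{-6}$ and
per-bin absolute tolerances scaled to $10^{-6} u_i(0)$.

### Fitting surface pH

`fit_surface_pH()` minimizes the sum of squared residuals between observed
and simulated fraction dissolved with a one-dimensional Nelder–Mead search
(two-point simplex with reflection, expansion, and contraction). Proposals
are reflected back into pH (3, 8); the search stops when the simplex spread
falls below $10^{-4}$ pH units. Goodness of fit is the squared Pearson
correlation between observed and predicted profiles, with fits flagged
acceptable above $r^2 = 0.90$; flat observed profiles (zero variance) are
rejected as degenerate rather than yielding an undefined correlation.

## Drug substance and particle defaults

The bundled racemic ibuprofen parameters are documented assumptions, not
fitted values: $S_0$ = 0.068 mg/mL, pKa = 4.45, $D$ = 4.5·10⁻⁴ cm²/min
(≈7.5·10⁻⁶ cm²/s), $\rho$ = 1.06 g/mL, dose 200 mg, MW 206.28 g/mol. The
default particle population is a lognormal volume distribution discretized
on 20 log-spaced bins with D50 = 120 µm and geometric SD 1.6, the same for
reference and test products. The D50 was chosen once so that a product at
the low end of the surface-pH range (5.64) dissolves on the reported
timescale — roughly three quarters released at 30 min and complete release
between 1 and 2 h — which also keeps the surface-pH estimate identifiable
from standard sampling schedules across the whole 5.4–6.3 range. At the
high end (pH ≥ 6.4) dissolution in this parameterization completes faster
than the reported 0.75 h; making it slower would require implausibly coarse
material under these $D$ and $h_\max$ assumptions, and we accept the
mismatch as a limitation. The diffusion-layer cap $h_\max$ defaults to
30 µm and is exposed as configuration.

## Gastrointestinal absorption and disposition

The oral model chains nine compartments (stomach, duodenum, two jejunum and
four ileum segments, colon). Solid transits as first-order flow at
1/MRT(particles), dissolving in each lumen by the same DLM with the fixed
surface pH; dissolved drug transits at 1/MRT(fluid) and is absorbed from
small-intestinal segments at $k_a = 2\,P_\mathrm{eff}/R$ (segment radius
$R$; colon and stomach absorption off by default). Central fluid MRTs are
0.12 h (stomach) and 3.4 h (small intestine, allocated uniformly over the
seven segments); fine-particle stomach MRT is 0.27 h. Within a compartment
each size bin is a (mass, count) cohort whose effective radius is
$(3m/4\pi\rho n)^{1/3}$; transit mixes incoming and resident particles,
which preserves mass exactly at the cost of blurring radii within a cohort.
A smooth mass-proportional shutoff regularizes the $m^{1/3}$ depletion
singularity. The right-hand side is compiled (C, under `src/`), with a
reference R implementation selectable via `solver_opts` and tested for
agreement; total mass (solid + lumen + central + eliminated + excreted) is
conserved to below $10^{-6}$ of dose.

Absorbed racemic drug splits 50:50 into R and S central compartments.
Disposition is deliberately one compartment per enantiomer — the published
enantiomer model's full parameterization (stereoselective protein binding,
CYP kinetics) is not publicly tabulated — with Vss = 0.091249 L/kg for
both, CL 1.0 L/h (R) and 2.0 L/h (S), and a unidirectional first-order
R→S inversion at 0.20 h⁻¹ standing in for the racemase-mediated pathway
(about 60% of an R dose inverted, terminal half-lives near 2 h at 70 kg).
These give realistic racemate exposures (Cmax ≈ 20–25 mg/L after 200 mg)
but are assumptions; absolute exposure predictions are not a contract of
this package. Cmax and tmax are extracted on the clinical sampling schedule
(0.33 to 24 h), not the continuous curve, mirroring trial analysis; ties go
to the earliest time. One consequence worth knowing: the grid-restricted
Cmax can decrease by a fraction of a percent as dissolution gets faster
when the true peak slides between sampling points.

## Virtual populations and trials

`draw_population()` samples each physiological parameter from a lognormal
distribution centred (as the median) on its table value with the stated CV,
truncated to a plausible range by rejection (never clipping, which would
create point masses at the bounds). Parameters flagged for within-subject
variability — the stomach and small-intestine MRTs (CV 150%) and Vss
(CV 10%) — are redrawn each period from a lognormal centred on the
subject's own value, the hierarchical analogue of "WSV equal to BSV".
GI pH (CV 6–16%) and volumes (CV 30%) vary between subjects only, and are
sampled independently across segments. Note that truncation compresses the
realized CV of heavy-tailed draws: a 150% CV parameter truncated to
physiological bounds has a substantially smaller sample CV, which is the
intended behaviour (moment recovery is tested with effectively unbounded
limits). Sequences alternate TR/RT by subject index for exact balance;
sex and age are recorded but do not enter the simplified disposition.

## Bioequivalence statistics

All statistics work on log Cmax with the lognormal convention
$\sigma^2 = \ln(1 + CV^2)$:

* `crossover_be()` — GMR from the mean within-subject log difference; 90%
  CI with $t_{0.95,\,n-2}$ (crossover ANOVA with a sequence term; a paired
  $n-1$ variant is available); TOST decision against 80.00–125.00%.
* `estimate_variance_components()` — one-way moment decomposition after
  centring by treatment; negative estimates truncate to zero.
* `sample_size()` — the normal-quantile closed form
  $n = 2(z_{1-\alpha}+z_{1-\beta})^2 \ln(1+CV^2)/(\ln GMR - \ln\theta)^2$
  against the nearer limit, rounded up to even. This rule reproduces every
  row of the planning table in the test suite; an iterative noncentral-t
  alternative (`method = "nct"`) is provided for comparison and typically
  lands within one even step.
* `predict_ci()` — the planning-mode CI
  $GMR\,\exp(\pm t_{0.95,n-2}\,\sigma\sqrt{2/n})$.

## Sensitivity screening

`morris_screen()` implements Morris elementary effects on a $p$-level grid
($\Delta = p/(2(p-1))$, default $p = 4$) in unit-scaled space, so $\mu^*$
is comparable across parameters with different units; $r$ randomized
one-at-a-time trajectories cost $r(k+1)$ model evaluations. Defaults
($p=4$, $r=50$) follow common screening practice and are configurable.
`select_driver()` takes the $\mu^*$-largest parameter, breaking exact ties
by larger $\sigma$ (more interaction), then lexicographically. On the
dissolution model over documented ranges (surface pH 5–7, solubility
scalars 0.5–2, $h_\max$ 10–50 µm), with the fraction dissolved at 30 min
as the output, surface pH ranks first at $r \ge 20$ across seeds. The
output time matters: at late times the fraction dissolved saturates at
100% over much of the box, the ceiling damps the surface-pH effect, and
small-$r$ rankings become Monte-Carlo noisy.

## Safe space and virtual bioequivalence campaigns

`map_safe_space()` simulates a crossover trial at each candidate test
surface pH with a *common seed*, so every grid point sees the same virtual
population and the product effect is isolated; the safe interval is the
maximal contiguous run of grid points whose 90% CI lies inside
80.00–125.00% for the chosen analyte (default R, the more discriminative
enantiomer), with optional bisection refinement of the endpoints.
`run_vbe_campaign()` runs `runs × replicates` independent trials with fresh
populations, seeding each replicate as `xor(seed + 7919·run, replicate)`
and recording the seed per trial, so the dependence of success rates on the
run/replicate split can be audited rather than guessed at.
`success_rate_vs_power_check()` contrasts an empirical success rate with
closed-form TOST power at matched assumptions — a diagnostic, not a test:
when the mechanistic within-subject CV differs from the clinically observed
one, the two legitimately disagree, and the sign of the discrepancy is the
scientifically interesting output.

## Problem sizes

The test-suite and acceptance-script workloads are chosen to estimate each
quantity to well inside its tolerance: 10⁴ simulated crossover trials for
the Monte-Carlo power check (binomial SE ≈ 0.4%), 10⁴ subjects for
variance-component recovery (±0.5 CV points), four true surface pH values
with five noisy replicates each for parameter recovery, and mechanistic
virtual-trial checks at 4–12 subjects on a 5-bin particle grid. The
narrative drivers under `analysis/` use 12–24 subjects and N = 10 trial
campaigns.

## What the synthetic data do and do not emulate

The generator forward-simulates the same DLM used for fitting and adds
additive Gaussian noise on the percent scale (dissolution assay error is
roughly homoscedastic in percent), clipped to [0, 100]; with zero noise it
is bit-identical to the forward model. It emulates mean profiles per
condition — per-vessel variability, assay autocorrelation, and
bioanalytical error are deliberately out of scope. The PK generator draws
log Cmax directly from the lognormal crossover model with known variance
components; it validates the statistics independently of the mechanistic
pipeline but says nothing about model misspecification in real data.
Passing tests therefore demonstrate internal consistency and correct
statistics, not fidelity of the disposition assumptions to any particular
clinical dataset.

## Known limitations

* Particle surface pH is constant along the GI tract and across a run.
* No precipitation or supersaturation kinetics (warning only); no
  bile-micelle solubilization; no gut-wall metabolism or enterohepatic
  recirculation.
* GI pH draws are carried in the population tables but do not feed back
  into the dissolution driving force (the surface-pH formulation absorbs
  that dependence), so their simulated impact is nil by construction.
* Disposition is a documented one-compartment simplification; absolute
  safe-space endpoints and success percentages depend on it and are not
  reproduction targets.
* The racemate is analysed by summing enantiomer concentrations before
  Cmax extraction, mirroring achiral bioanalysis.
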