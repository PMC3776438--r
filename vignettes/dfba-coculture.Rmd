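---
title: "Dynamic flux balance modeling of a glucose/xylose yeast co-culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flux balance modeling of a glucose/xylose yeast co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codfba)
```

## The system

Efficient conversion of lignocellulosic hydrolysates to ethanol requires
fermenting both hexose and pentose sugars. A batch co-culture of a
respiratory-deficient (petite) *Saccharomyces cerevisiae* strain with
wild-type *Scheffersomyces stipitis* divides the labor: the petite
*S. cerevisiae* ferments glucose to ethanol and, lacking an electron
transport chain, neither competes for the scarce oxygen nor reassimilates
ethanol once glucose is gone; *S. stipitis* consumes the remaining glucose
and then the xylose, microaerobically, with high ethanol yield. Oxygen
supply (set by the gas–liquid transfer coefficient $k_La$) and the inoculum
composition are the two operating handles.

`codfba` implements a dynamic flux balance analysis (DFBA) of this system:
a community flux balance linear program embedded in extracellular mass
balance ODEs, with Michaelis–Menten uptake kinetics bounding the exchange
fluxes at every instant.

## The model

### Community flux balance program

Each species $i \in \{c, s\}$ has a stoichiometric matrix $A_i$, flux
vector $v_i$ with bounds $v_{i,\min} \le v_i \le v_{i,\max}$, and biomass
weights $w_i$. The community program stacks the matrices block-diagonally
(the species share no metabolites; they interact only through the shared
broth) and maximizes the total growth rate

$$\max_{v_c, v_s} \; \mu = \mu_c + \mu_s = w_c^T v_c + w_s^T v_s
\quad \text{s.t.} \quad A_i v_i = 0, \;\; v_{i,\min} \le v_i \le v_{i,\max}.$$

Because the blocks are independent, each member's growth rate is
individually maximal at the community optimum; fixing all fluxes of one
member to zero reproduces the pure-culture program exactly, a property the
tests exercise.

The optimal flux *vector* of an FBA program is generally degenerate. Since
the ODE layer consumes exchange fluxes, not just $\mu$, reported fluxes
must be unique: after fixing $\mu$ at its optimum a second, parsimonious
program minimizes $\sum_j |v_j|$ (implemented by the standard positive
split $v = p - q$). This removes futile cycles and makes trajectories
reproducible across solvers and platforms.

The LP engine is a dense bounded-variable two-phase primal simplex
(compiled, Bland's rule, so degenerate FBA bases terminate). Feasibility
and optimality tolerances are $10^{-9}$, appropriate for the
few-dozen-variable programs this package solves; tests cross-check every
optimum against an independent pure-R simplex and, on networks of at most
12 reactions, against exhaustive vertex enumeration
(`bruteforce_lp()`).

### Extracellular balances

With biomass densities $X_c, X_s$ (gdw/L), sugars $G, Z$ and ethanol $E$
(g/L) and dissolved oxygen $O$ (mM):

$$\dot X_i = \mu_i X_i, \qquad
\dot G = v_{g,c} X_c + v_{g,s} X_s, \qquad
\dot Z = v_{z,s} X_s,$$
$$\dot E = v_{e,c} X_c + v_{e,s} X_s, \qquad
\dot O = v_{o,c} X_c + v_{o,s} X_s + k_La\,(O^\ast - O),$$

where exchange fluxes are signed (uptake negative) and the sugar/ethanol
fluxes are converted from mmol/gdw/h by fixed molar masses (glucose
0.18016, xylose 0.15013, ethanol 0.04607 g/mmol). $O^\ast = 0.24$ mM is
the saturation concentration of oxygen in water at 30 °C and 1 atm.
$k_La$ can be given directly or derived from the gas sparge rate via the
linear two-point calibration (25 cc/min → 5.5 h⁻¹, 50 cc/min → 10.1 h⁻¹,
`kla_from_sparge()`).

### Uptake kinetics

Upper bounds on uptake magnitudes, evaluated from the current broth state
(`uptake_caps()`):

$$v_g = v_{g,\max}\frac{G}{K_g+G}\cdot\frac{1}{1+E/K_{ieg}}, \qquad
v_z = v_{z,\max}\frac{Z}{K_z+Z}\cdot\frac{1}{1+G/K_{igz}}
      \cdot\frac{1}{1+E/K_{iez}}, \qquad
v_o = v_{o,\max}\frac{O}{K_o+O}.$$

The $1/(1+G/K_{igz})$ factor produces diauxic growth: *S. stipitis*
defers xylose until glucose nears exhaustion. Ethanol inhibition with
$K_{ieg} = 10$ g/L applies to the glucose uptake of both species (the
functional form is shared; only *S. stipitis* has a xylose system).
Units are deliberately heterogeneous — sugars and ethanol in g/L, oxygen
in mM — and no conversion happens inside the kinetics.

Calibrated defaults (`yeast_uptake_params()`):

| parameter | *S. cerevisiae* 311 | *S. stipitis* | units |
|---|---|---|---|
| $v_{g,\max}$ | 21.5 (pure) / 18.5 (co-culture) | 6.5 | mmol/gdw/h |
| $v_{z,\max}$ | — | 5.5 | mmol/gdw/h |
| $v_{o,\max}$ | 2.5 | 11 | mmol/gdw/h |
| $K_g$ | 0.5 | 1 | g/L |
| $K_z$ | — | 0.25 | g/L |
| $K_o$ | 0.005 | 0.0125 | mM |
| $K_{ieg}$ / $K_{iez}$ | 10 / — | 10 / 4.5 | g/L |
| $K_{igz}$ | — | 0.5 | g/L |

The reduced co-culture $v_{g,\max}$ reflects unmodeled species
interactions that handicap *S. cerevisiae* in glucose competition; it is
a context flag the caller selects explicitly (`context = "co_culture"`),
never inferred from the inputs.

### The maintenance toggle

The petite *S. cerevisiae* cannot generate ATP once glucose is exhausted,
so its non-growth-associated maintenance demand (a positive lower bound on
the ATP hydrolysis reaction) makes the whole community program infeasible
— which would wrongly zero the *S. stipitis* fluxes too. In co-culture
context the simulator therefore sets the glucose-only members'
maintenance lower bound to zero once $G$ falls below $10^{-6}$ g/L
(`maintenance_toggle()`). The threshold is far below measurement
resolution; its exact value only shifts the switch by a fraction of a
time step. If the program is still infeasible (total starvation) every
maintenance bound is relaxed, and as a last resort all growth and
exchange fluxes are reported as zero — starving cultures stand still
rather than crash the integrator.

## Numerical choices

- **ODE–LP coupling.** The LP is solved inside every right-hand-side
  evaluation (direct embedding). The oxygen balance makes the system
  stiff — dissolved oxygen collapses to a microaerobic quasi-steady state
  within minutes while sugars evolve over hours — so the default
  integrator is `deSolve`'s `lsoda` at `rtol = 1e-6`, `atol = 1e-8`.
  Halving the tolerances moves final titers by far less than 0.1 %
  (tested).
- **Nonnegativity.** Uptake bounds vanish continuously as substrates
  approach zero, which keeps the vector field well behaved; states are
  additionally clamped at zero and derivatives that would push a zero
  state negative are suppressed.
- **Output.** Results are reported on a uniform grid (default 0.1 h);
  batch events (glucose depletion, xylose crossing the 0.5 g/L batch-end
  cutoff) are linearly interpolated between grid points.
- **Calibration.** The staged least-squares protocol replaces manual
  trial-and-error fitting: each stage minimizes a weighted sum of squared
  residuals (each series normalized by its data maximum, so g/L sugars
  and mM oxygen contribute comparably) with bounded Levenberg–Marquardt.
  Two details matter with an adaptive integrator in the loop: the
  finite-difference step is widened to ~1 % of the parameter
  (`epsfcn = 1e-4`), because the default near-machine-epsilon step falls
  below the integrator's output granularity and yields spurious zero
  gradients; and parameter vectors whose simulation fails to integrate
  return a flat penalty residual, steering the optimizer back to
  integrable regions instead of aborting the fit.
- **Parameter identifiability.** Under microaerobic conditions oxygen
  uptake is supply-limited ($v_o \approx k_La(O^\ast-O)/X$), so
  $v_{o,\max}$ is unidentifiable from microaerobic data. The recommended
  staging mirrors the experimental protocol: sugar parameters from an
  anaerobic batch ($k_La = 0$, $O(0) = 0$), then $v_{o,\max}$ from an
  aerobic batch with the sugar parameters fixed.
- **Sensitivity analysis.** Scaled coefficients
  $S = (\bar p/\bar y)\,(\Delta y/\Delta p)$ use one forward simulation
  per perturbation; $S$ estimates at 1 % and 0.5 % perturbations agree
  within 5 % on smooth responses (tested).
- **Ethanol-growth threshold.** The smallest aeration supporting growth
  on ethanol balances oxygen transfer against uptake at quasi-steady
  state; `oxygen_supply_cap()` solves the resulting quadratic exactly and
  the threshold is found by bisection. The answer scales with the assumed
  biomass density, which is therefore an explicit argument (default
  1 gdw/L).

## Design decisions in the open corners

- **Knockout screen scope.** The petite phenotype arises from
  mitochondrial DNA damage, so the screen enumerates single and paired
  knockouts of mitochondrial-compartment reactions only, accepting those
  with lower biomass yield, higher ethanol yield and lower oxygen demand
  than wild type (yields per unit glucose uptake on a fixed reference
  medium) and, optionally, zero growth on ethanol. Candidates are
  returned in a fixed order (singles by id, then pairs lexicographically).
- **Inoculum optimization.** Grid search (fraction step 0.05, aeration
  within the validated envelope $k_La \le 10.1$ h⁻¹) rather than formal
  dynamic optimization; ties break toward the smallest *S. cerevisiae*
  inoculum. Undefined productivities (xylose cutoff never crossed) are
  excluded rather than erroring.
- **Inoculum response directions.** The mechanism is that a larger
  *S. stipitis* share builds more biomass by glucose exhaustion and so
  converts xylose faster: batch time grows with the *S. cerevisiae*
  fraction over the useful range, while a small *S. cerevisiae* admixture
  raises the ethanol yield of the glucose phase. The two effects compete
  and produce an interior productivity optimum (at 0.1/0.9 g/L on the
  synthetic community); the tests assert this competing-trends structure.
- **Above-envelope aeration.** At high aeration *S. stipitis*
  reassimilates ethanol, which this model does not represent; simulations
  with $k_La > 10.1$ h⁻¹ therefore emit a warning rather than an error.
  The constant-DO comparison mode takes its DO value as a parameter.

## The synthetic community

All tests and the acceptance script run on synthetic networks
(`make_toy_species()`, `make_toy_community()`) of at most ten reactions
whose FBA optima have closed forms: exchange reactions, a low-ATP
fermentative route producing ethanol, a high-ATP respiratory route
consuming oxygen (mitochondrial compartment, so the knockout screen
applies), an ATP maintenance demand, and a biomass drain (100 mmol ATP
per gdw, chosen so growth rates land in the 0.2–0.6 h⁻¹ range of
microaerobic yeasts). Default yields are integer-friendly (2 ATP + 2
ethanol per fermented sugar, 26 ATP per respired sugar at 6 O₂) so oracle
arithmetic is exact. The community pairs a glucose-only
"cerevisiae-like" member (respiration knocked out) with a
glucose+xylose "stipitis-like" member carrying the calibrated kinetics
above.

This toy reproduces the study system's qualitative behavior:
fermentative overflow, diauxic sugar use, the microaerobic oxygen crash,
the maintenance crisis of the petite member after glucose depletion, an
interior inoculum optimum at 0.1/0.9 g/L, productivity increasing with
aeration while the titer barely moves, and sizable gains from xylose
transporter improvements (+12 % productivity for +25 % $v_{z,\max}$;
+72 % for complete diauxy removal).

What it does not emulate: genome-scale stoichiometry (cofactor balances,
byproducts like glycerol and acetate), ethanol reassimilation,
gene–protein–reaction logic, or measurement artifacts. Passing tests
therefore demonstrate the correctness of the machinery — LP optima, mass
balances, integration, calibration, optimization — not the biological
accuracy of any particular genome-scale reconstruction. Published
reconstructions in SBML (with flux-bound and objective annotations) can
be loaded with `load_sbml()` and run through the identical pipeline.

Problem sizes used by the test-suite and acceptance script: networks of
7–10 reactions, batches of 12–60 h at 0.05–0.3 h reporting steps, grids
of 11–21 design points, 50 randomized LP-oracle comparisons, and 10
noisy calibration replicates — small enough to run on one CPU in a few
minutes while exercising every code path.

## Known limitations

- Batch operation only: no fed-batch or continuous modes, no pH,
  temperature or CO₂ balances, and a single-film oxygen transfer model.
- The community objective is the sum of growth rates; no multi-level or
  altruistic objectives.
- LP performance targets desk-scale networks; genome-scale models will
  solve but slowly, and a dedicated LP library would be the right engine
  for them.
- Ethanol reassimilation at high aeration is out of the validated
  envelope and deliberately unmodeled.
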