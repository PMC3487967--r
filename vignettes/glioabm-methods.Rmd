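---
title: "glioabm: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glioabm: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glioabm is a hybrid discrete–continuum simulator of early vascularized brain
tumor growth and its response to EGFR tyrosine-kinase inhibitors (TKIs,
gefitinib-like).  This vignette is the package's own account of the model:
what is simulated at each biological scale, which parameters matter and why
they default to the values they do, what the built-in signaling network is a
stand-in for, and which design choices were genuinely open.

# The four scales

**Molecular.**  Every tumor cell carries a small EGFR-signaling plus
cell-cycle ODE network, integrated each one-hour agent step with an adaptive
embedded Runge–Kutta 4(5) method (relative tolerance $10^{-6}$, absolute
$10^{-9}$, free substepping).  The network is *declarative*: a rate-law
table whose rows are signed mass-action or Michaelis–Menten terms
(`pathway_spec()`, `read_rate_table()`), so a user holding the original
kinetic tables can drop them in verbatim.  Two quantities leave this scale:
the migration potential $MP = d[\mathrm{PLC}\gamma]/dt$, and the cell-cycle
pair ([CDh1], [cycCDK]) that gates division ([CDh1] < thr$_1$ and
[cycCDK] > thr$_2$, both strict).

**Cellular.**  Each hour a cell reads the glucose at its site: below the
dead threshold it dies (absorbing), between the dead and active thresholds
it waits in reversible quiescence, above the active threshold it is active.
Active cells with $MP > \sigma_{PLC\gamma}$ migrate to their most attractive
free Moore neighbor; the rest progress toward division and, when the cycle
switch has flipped, place an offspring on the most attractive free neighbor.
Attractiveness is $P_j = \psi G_j/F_j + (1-\psi)\varepsilon_j$ with
$\varepsilon_j \sim N(0,1)$ and search precision $\psi = 0.7$; a cell ready
to divide with no free neighbor becomes quiescent until space appears.

**Micro-environmental.**  Glucose, oxygen, TGF$\alpha$, VEGF and the drug
obey
$$\partial_t u = D\,\Delta u + X_{ves}\,q\,(u_{blood} - u)
  + X_{tum}(S - U) - \delta u$$
on the lattice with zero-flux boundaries (mirrored ghost cells), solved by
forward Euler with the 5-point Laplacian.  Substeps satisfy
$\Delta t \le 0.9 / (4D/h^2 + q + \delta)$ — the reaction terms enter the
bound and the 0.9 safety factor keeps the checkerboard mode damped; sitting
exactly on the diffusive limit is neutrally stable and the transvascular
term then blows up.  Fibronectin does not diffuse:
$F \mathrel{+}= \Delta t\,(X_{ves}\beta - X_{tum}\gamma F)$.
Negative values produced by the zeroth-order uptake terms are clamped to
zero and counted.

**Tissue.**  Tip endothelial cells carry their sprouts.  Direction weights
combine saturating chemotaxis and haptotaxis,
$$P_k = \frac{\alpha k_v}{k_v + V}\,(V_k - V) + \lambda\,(F_k - F),$$
for up/down/right/left; negative (down-gradient) weights clamp to zero, the
stay weight $P_5$ is the mean of $P_1..P_4$, and the five are normalized.
Sprouts older than 18 h (strict) with a free von-Neumann neighbor branch
when two uniform draws fall in $I_2$ and $I_3$, emitting daughters below and
to the right and resetting sprout age; otherwise one draw decides migration.
A `"literal"` mode moves tips only rightward (the migration sub-rule
exactly as printed); the default `"generalized"` mode samples the direction
from the full normalized distribution, because the literal rule cannot
produce the upward or leftward growth visible in vascular patterns — with
it the network can never wrap around the tumor and the interior is never
resupplied.  Both modes ship; the branching rule is identical in both.  Tips landing on existing
endothelium fuse sprouts (anastomosis); two tips reaching one site leave a
single merged tip.

**Treatment.**  The drug field follows the same reaction–diffusion law,
delivered through every vessel site.  Receptor blockade is quasi-static:
binding/unbinding is much faster than phenotype switching, so the occupied
fraction is $[TKI]/(k_m + [TKI])$ and each agent step caps the cell's free
receptor at $EGFR_{eff} = EGFR_0\,(1 - [TKI]/(k_m+[TKI]))$.  Default
$k_m = 0.033\ \mu M$ (the scale of gefitinib's EGFR kinase IC50); the blood
level (1.5 $\mu$M) and the drug field's slow decay are set so the
near-tumor concentration is close to 1 $\mu$M over the first 100 h,
matching the concentration used in the in-vitro comparison the original
study calibrated against.

# The default signaling network is a stand-in

The original kinetic tables live in supplementary files that are not part of
the main text, so the shipped network (`default_pathway()`) is a documented
surrogate with the published topology: ligand binding (k1/ku),
dimerization-mediated receptor autophosphorylation (k2, second order in the
ligand–receptor complex), saturating dephosphorylation that recycles
receptor and ligand (V4, K4), PLC$\gamma$ activation (k3) and slow
relaxation (k5), and a cell-cycle module (cyclin–CDK synthesis against
CDh1 antagonism, driven by a logistically saturating mass variable that is
reset at division).

Its constants were fixed once, before any test was frozen, by calibrating to
the *printed* facts about the real network — the only constraints available:

* the $\pm 10\%$ sensitivity scan of $MP$ must stay below 1.8% on the
  percentage-change scale, with initial EGFR (X2) and TGF$\alpha$ (X1) the
  two most sensitive inputs.  This pinned the readout regime: $MP(t) \propto
  a\,e^{-at}$ with $a = k_3\,[\mathrm{pEGFR}]^*$, so every upstream
  elasticity is damped by the common factor $(1 - a t)$; choosing $k_3$ so
  that $a \cdot 48\,h \approx 1$ makes the network's migration readout
  maximally robust, and ligand sequestration plus second-order
  phosphorylation rank X2 and X1 above the rate constants;
* the division period is about a day: the logistically saturating mass
  variable (`kg`, `kg2`; carrying scale 4) flips the CDh1/cycCDK switch
  near Mass $\approx 2.5$ (~15 h), and young cells spend their first hours
  in the migratory phenotype before settling to divide.  Mass saturation is
  not cosmetic: cells that cannot divide (quiescent) would otherwise grow
  exponentially stiff cycle equations;
* cell-cycle progression is deliberately *not* rate-limited by the
  receptor: the source attributes the whole treatment effect to the
  migration potential, and a receptor-gated cycle freezes the treated
  tumor, which then never starves and never shows the published
  fall-then-rise survival curve.  The receptor–cycle link is topological
  (shared species), not kinetic;
* under 1 $\mu$M drug the signaling cascade stalls (receptor occupancy
  ~98% at $k_m = 0.033\,\mu M$, quadratically suppressed phosphorylation),
  so treated cells essentially stop migrating while still cycling.

The sensitivity readout time (48 h of single-cell simulation at the
reference condition, ligand free to deplete) is a design choice the source
never states; it is the e-folding time of PLC$\gamma$ activation, where the
migration readout is least parameter-sensitive.

# Stated world of the synthetic scenario

Geometry and timing are as published: a 200×200 lattice of 20 µm spacing
(4–5 mm tissue slice), 1 h steps, a parent vessel column near the left
boundary with 6 tip cells, and a cluster of 40 tumor cells in a disc of
radius 5 placed about a third of the way across the domain (site 65 of
200) so the developing vasculature reaches it within the simulated window,
ages uniform on [0, 24) h
(each cell's pathway state is the reference state integrated forward by its
age, so cycle phases are staggered consistently).  Cluster size and position
are not printed in the source and are package choices.

Field coefficients are expressed in lattice units per hour and are
documented placeholders ordered by the published diffusivity ranking
(oxygen > glucose > VEGF ≥ TGF$\alpha$; the drug diffuses like glucose).
Two initial profiles deviate from flat starts, for structural reasons
recorded in the project ledger:

* **Glucose** starts as the uniform background minus a small
  tumor-centered Gaussian dip (amplitude 0.1, width 12 sites), the imprint
  of avascular growth before the simulated window, and the per-cell uptake
  is kept low (0.05/h against a blood level of 1) with the quiescence
  threshold at 0.5 and the death threshold at 0.4.  In strongly-consuming
  regimes the quasi-steady depletion well forms *during* the run and its
  active-to-quiescent conversion front sweeps the whole core within a few
  hours — a quiescence avalanche incompatible with the published monotone
  growth of the active population.  In the weak-uptake regime the well
  deepens slowly and conversions stay below concurrent births.
* **VEGF** starts as a tumor-centered halo (amplitude 0.1, width 50).  With
  a zero start, tips sit still while endothelial matrix deposition raises
  fibronectin at their own sites; since the haptotaxis term is evaluated as
  neighbor-minus-self, a stationary tip digs its own trap and the
  vasculature never moves.  A pre-established halo is also the biologically
  expected state: the angiogenic switch precedes sprouting.

$\sigma_{PLC\gamma}$ defaults to a fixed constant (0.011) equal to the
population-mean $d[\mathrm{PLC}\gamma]/dt$ of the drug-free reference
world over its first ~60 h (the published definition of the threshold as an
average rate of change).  The threshold feeds back on the population —
changing $\sigma$ changes who migrates, which changes the mean — so no
exact fixed point exists; over the full 150 h the mean drifts to ~0.016 as
secreted TGF$\alpha$ accumulates.  An optional live population-average
mode re-evaluates $\sigma$ each hour.

# What a green test does and does not establish

The synthetic world reproduces most published *shapes*: active-cell growth
that is non-decreasing at daily resolution, endothelial counts strictly
growing toward the tumor, treated runs with far fewer migration events, a
suppressed mean PLC$\gamma$ rate, and a survival percentage that falls to
an interior minimum (~hour 200) and recovers as the neo-vasculature feeds
the compact treated tumor.  Two published statistics are *not* met by the
stand-in world and their acceptance tests are intentionally left failing
rather than weakened: the quiescent population rises but does not fall by
150 h (endothelial cells cannot enter live-tumor sites, so perivascular
reactivation cannot reach a >1000-cell interior; and division-blocked cells
re-enter quiescence every hour, ratcheting the count), and the fold-change
robustness bound |R| <= 0.1894 / CV = 0.2007 fails because ten-fold
rescaling of the migration potential flips whole cohorts across the fixed
$\sigma_{PLC\gamma}$ threshold, switching the colony between dispersed and
compact morphologies with ~70% swings in the 100 h active count.  (With the
live population-average $\sigma$ mode the migratory set is invariant under
multiplicative MP rescaling, which softens the failure — measured max |R|
0.45 and CV 0.16 against 0.71 and 0.33 for the fixed threshold — but still
misses the printed bound, and that mode erases the published
treated/untreated migration contrast, so the fixed-threshold default
stands.)  Absolute cell counts, exact event hours
and figure-level patterns all depend on the unpublished parameter tables
and are not asserted.

# Numerical choices

* Adaptive RK45 (Cash–Karp) per cell per hour; non-convergence raises an
  error carrying cell and hour.  Concentrations clamp at zero (counted).
* Explicit diffusion with automatic substepping as above; NaN is a hard
  failure.  Mass conservation under pure zero-flux diffusion is exact to
  round-off and asserted at $10^{-10}$ over 100 steps.
* Ties in site attractiveness resolve to the first-indexed neighbor;
  fibronectin in the score is floored at $10^{-6}$.
* Agent and tip update order is re-randomized every step from the single
  seeded RNG stream; identical seed + config reproduces a run bit-for-bit.
* Division thresholds and the 18 h branching age are strict inequalities;
  equality does not trigger.

# Known limitations

Two dimensions only; no vessel regression, pericytes, blood flow or
pressure; no stochastic chemical kinetics (the molecular scale is ODE);
oxygen is transported and consumed but gates no cellular rule (the
published rules key on glucose, with oxygen's proliferative role implicit
in the cycle's drive); migratory cells consume matrix only through the
tumor-occupancy mask.  The literal branching rule biases growth rightward
and downward; the generalized mode removes the bias but is not the rule as
printed, so both ship and neither is asserted as correct.
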