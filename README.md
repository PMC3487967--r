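# glioabm

Multi-scale agent-based simulation of vascularized brain tumor growth and
EGFR tyrosine-kinase-inhibitor (TKI) treatment, for computational cancer
biologists studying how molecular signaling, nutrient fields and
angiogenesis jointly shape tumor progression and drug response.

## The model

Tumor cells live on a 2-D square lattice (default 200×200 sites of 20 µm —
a 4–5 mm tissue slice) and are updated hourly across four scales:

* **Molecular** — each cell integrates an EGFR-signaling + cell-cycle ODE
  network, `dX_i/dt = Σv₊ − Σv₋`, defined by a declarative rate-law table
  (mass-action and Michaelis–Menten terms).  The migration potential is
  `MP = d[PLCγ]/dt`; division readiness is `[CDh1] < thr₁` and
  `[cycCDK] > thr₂`.
* **Cellular** — glucose thresholds decide death / reversible quiescence /
  activity; active cells migrate when `MP > σ_PLCγ`, otherwise proliferate.
  Offspring and migration sites maximize `P_j = ψ G_j/F_j + (1−ψ) ε_j`,
  `ε_j ~ N(0,1)`, `ψ = 0.7`.
* **Micro-environmental** — glucose, oxygen, TGFα, VEGF and drug follow
  `∂u/∂t = DΔu + X_ves q (u_blood − u) + X_tum (S − U) − δu` with zero-flux
  boundaries (explicit finite differences, automatic stable substepping);
  fibronectin follows `∂F/∂t = X_ves β − X_tum γ F`.
* **Tissue** — sprout-tip endothelial cells migrate with direction weights
  `P_k ∝ (α k_v/(k_v+V)) ∇V + λ ∇F` (stay weight = mean of the four moves),
  branch after 18 h given free space and the stated interval draws, and
  fuse on contact (anastomosis).
* **Treatment** — the drug permeates vessels and blocks receptor by
  Michaelis–Menten occupancy: `EGFR_eff = EGFR₀ (1 − [TKI]/(k_m + [TKI]))`.

Analyses include the ±10% local sensitivity scan of MP
(`S = (ΔMP/MP)/(ΔP/P)`), the fold-change robustness index
`R = (ACN_p − ACN₀)/ACN₀` on the active cell number at 100 h, the CV of
variational outcomes, survival percentage of paired treated/drug-free runs,
and proliferation-rate series.

The published kinetic tables for the signaling network live in unavailable
supplementary material; the package ships a documented stand-in with the
published topology and accepts user tables verbatim
(`read_rate_table()`).  See `vignettes/glioabm-methods.Rmd` for every
default and its rationale.

## Worked example

```r
library(glioabm)
cfg <- default_config(list(lattice = list(L = 100L), horizon = 72,
                           tumor = list(center_i = 60L, center_j = 50L)))
res <- run_simulation(cfg)
tail(res$metrics[, c("hour", "live", "active", "migratory", "proliferative",
                     "quiescent", "ec", "mean_plc")], 4)
```

```
   hour live active migratory proliferative quiescent  ec   mean_plc
70   69  298    272       189            83        26 537 0.01947630
71   70  302    273       192            81        29 546 0.01942180
72   71  307    278       194            84        29 554 0.01907516
73   72  312    279       197            82        33 561 0.01872256
```

After 72 h the initial 40-cell cluster has grown to 312 cells: 279 are
active (189 currently migrating up the glucose/fibronectin score, 82 on the
proliferative track), 33 are quiescent in the nutrient-depleted core, and
the vasculature has grown from 106 to 561 endothelial sites as sprouts
chemotax toward the tumor's VEGF halo.  `mean_plc` is the population-mean
migration potential (concentration/h), the quantity the TKI suppresses.

Treatment comparison and analyses:

```r
pair <- run_paired_treatment(default_config(list(horizon = 300)))
pair$survival            # 100 * treated viable / drug-free viable, per hour
sensitivity_scan()       # +/-10% scan of the migration potential
```

## Command line

```sh
Rscript inst/cli/glioabm.R run --hours 150 --drug off --seed 1 --outdir out/
Rscript inst/cli/glioabm.R sensitivity --outdir out/
Rscript inst/cli/glioabm.R robustness --hours 100 --baseline 10 --small --outdir out/
Rscript inst/cli/glioabm.R report --outdir out/
```

`run` mirrors the original tool's `angiog_tumor(time, isdrug)` entry point
and writes a metrics CSV, agent table, vessel edge list, field snapshots
and a reconstructible JSON manifest.

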