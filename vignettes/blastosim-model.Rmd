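---
title: "The blastosim model: four rules for a self-organising blastocyst"
author: "blastosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The blastosim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`blastosim` simulates mouse preimplantation development as an off-lattice
collection of soft, unit-radius circles (2D; spheres in the 3D validation
mode) that move by overdamped gradient dynamics in a pairwise interaction
potential

$$V(d) = e^{-d} - S\,e^{-d/\beta},$$

where $d$ is the centre-to-centre distance in cell radii, $\beta = 5$ sets
the attraction range, and $S$ is an *attraction factor* that carries all of
the biology: adhesion differences between lineages and the
polarity-dependent coupling of trophectoderm (TE) cells. Positions follow

$$\frac{d\mathbf{x}_i}{dt} = -\nabla_i \sum_{\text{pairs}} V + \eta,$$

integrated with an explicit Euler scheme (step `dt = 0.1`) plus additive
Gaussian noise of standard deviation $10^{-3}$ per coordinate per step. TE
cells also carry a polarity unit vector $\hat e$ whose orientation relaxes
under the pairwise alignment potential $V_p = -\cos\theta_{ij}$ with a
damping prefactor of 0.1 (ten times slower than the positions) and angular
noise $\pi \times 10^{-3}$ per step.

Development is driven by cell division: a circle is picked uniformly at
random, its daughter is inserted at the midpoint between the mother and its
nearest neighbour (in 3D, at the centre of the mother's three nearest
neighbours), and the system relaxes before the next division. The event
clock advances by $1/N$ per division ($N$ = number of circles), the expected
waiting time when every circle divides at unit rate, so growth is
exponential. Because each biological TE cell is represented by **two**
circles (TE cells are about twice the size of the others), uniform circle
selection automatically gives TE twice the biological division rate of the
inner cell mass (ICM).

Four developmental rules act on this substrate:

1. **Polarity, if surface cell.** At the 16-cell stage, cells with fewer
   than 5 contact neighbours become TE, acquire an outward radial polarity,
   and are expanded to two circles each; the rest become undetermined ICM.
   For TE–TE pairs the attraction factor is the polar expression
   $S = -1.4\,(\hat e_1 \times \hat r_{12})\cdot(\hat e_2 \times \hat
   r_{21})$: maximal (+1.4) for parallel polarities perpendicular to the
   separation, negative for antiparallel ones. This favours a single-file
   polarised sheet; as the TE proliferates, the sheet must lengthen, the
   enclosed area grows, and a cavity emerges without any osmotic mechanism.
2. **Fate switching by FGF4 (ICM only).** From E3.0 to the endpoint, when
   an ICM cell divides, mother and daughter convert to primitive endoderm
   (PrE) with probability equal to the fraction of high-FGF4 cells
   (epiblast or undetermined ICM) among the mother's ICM contact
   neighbours, and to epiblast (EPI) otherwise. This local
   activation/neighbour-mediated inhibition is a discrete Turing-like
   mechanism; on a static lattice it drives the PrE share to one half at
   any system size (see `lattice_ratio_trace()`).
3. **Differential adhesion.** From E3.5, every pair involving a PrE cell
   has its attraction factor reduced from 0.6 to 0.4, so PrE cells sort
   passively to the ICM surface facing the cavity.
4. **Positional apoptosis.** At E4.5, PrE cells surrounded by more than 3
   non-PrE ICM neighbours — PrE trapped in the epiblast core — are removed.

The endpoint is classified as a successful blastocyst when the TE forms one
closed ring enclosing the ICM, a cavity exists with the ICM to one side,
the PrE seals the epiblast from the cavity, and no cell sits in the wrong
layer; failures map to five mutually exclusive error categories
(`?classify`).

## The stage clock and its calibration

The model has no absolute time unit. One *stage unit* is defined as the
E3.0 to E3.5 interval; polarity fires at the 16-cell stage, fate switching
at E3.0 (`sum(1/(1:15))` on the event clock, which is exactly the 16-cell
stage of an unperturbed embryo), differential adhesion one stage unit
later, and the endpoint two further units after that. The default
`stage_unit = 0.717` was calibrated once so that the unperturbed ensemble
averages about 132 biological cells at the endpoint, and is not otherwise
tuned.

Keeping rules 2–4 at fixed absolute times while the polarity rule tracks
the 16-cell stage is what makes the scaling experiments work: an embryo
halved at the 8-cell stage reaches 16 cells one doubling later, still
specifies and terminates on the absolute schedule, and therefore ends at
half size with near-normal lineage proportions; aggregates of two embryos
end at double size. The delayed-FGF experiment shifts only the rule-2 onset
by one stage unit; cells that remain undetermined at the endpoint (their
fate never re-evaluated after the late onset) are counted as epiblast,
which is what lowers the PrE share in that condition.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `S_default` | 0.6 | attraction factor for ordinary pairs |
| `S_pre` | 0.4 | attraction for any pair with a PrE cell (rule 3) |
| `S_neutral_adhesion` | 0.5 | ICM-ICM factor in the neutralized mode |
| `beta` | 5 | attraction range of the potential |
| `polar_prefactor` | 1.4 | TE polar coupling; 1.5 tears the sheet, 1.3 cannot hold it |
| `te_te_cutoff` | 2.5 | TE pairs interact only below this distance |
| `global_cutoff` | 5 | range of the TE-ICM potential (about 2 cell diameters) |
| `icm_global_potential` | TRUE | ICM-ICM pairs interact without cutoff |
| `dt`, `relax_max_steps` | 0.1, 300 | Euler step and per-division relaxation budget |
| `noise_sd_position` | 1e-3 | additive positional noise per step |
| `stage_unit` | 0.717 | E3.0 to E3.5 interval on the event clock |

All distances are cell radii and all rates are per event-clock time; the
potential is dimensionless energy.

## Numerical choices

* **TE interaction topology.** Each TE circle forms polar bonds with its 2
  nearest TE circles only (within the 2.5 cutoff); other TE pairs in range
  keep the repulsive term as soft volume exclusion. If instead every TE
  pair within the cutoff carries the polar attraction, diagonal bonds
  condense the TE into multi-row rafts and no cavity ever forms. In 3D the
  bonded set is the mutual halfway-point true nearest neighbours: each
  cell's 20 closest candidates are filtered by whether the pair midpoint is
  closer to a third cell, which separates nearest from next-nearest
  neighbours where a plain distance threshold cannot.
* **Forces.** TE-TE forces use the full analytic gradient of $V$ at fixed
  polarities, including the dependence of the polar factor on the
  separation direction; this tangential term acts as the bending stiffness
  of the TE sheet, and without it the closed ring wrinkles around the ICM
  instead of bowing outward into a cavity. Polarities evolve only by the
  separate alignment equation, as specified.
* **Rule neighbourhoods.** The developmental rules count *contact*
  neighbours with the scale-free halfway-point rule (capped at the
  interaction range). Under the global ICM potential the ICM packs well
  below the two-body equilibrium spacing, so a fixed-radius count would
  include second-shell cells and mis-trigger the apoptosis rule.
* **Relaxation.** Each relaxation phase stops early once the largest
  deterministic displacement per step falls below `conv_tol = 1e-3`, with a
  cap of 300 steps; small embryos converge well before the cap, late-stage
  embryos use the full budget. The noise amplitude is small enough that it
  never masks the convergence criterion.
* **Classifier conventions.** The authors' exact geometric thresholds are
  not published, so the classifier declares its own: the cavity is the
  largest empty disc inside the TE ring (grid rasterisation at half-radius
  resolution) and must exceed 3 cell cross-sections with its centre at
  least 2 radii from the ICM centroid; the PrE seals the epiblast when
  every straight path from an EPI cell to the cavity centre passes within
  one cell radius of a PrE cell (1.5 radii in 3D, where monolayer holes
  are wider); ring closure requires consecutive circles along the ring to
  be in contact. Single-lineage ICM categories are assigned before shell
  state, since composition is the defining readout of the FGF mutants.
* **Degenerate inputs.** Coincident cells raise an overlap error; a cell
  with no ICM neighbours adopts epiblast under rule 2; midpoint ties in the
  halfway-point rule retain the neighbour (the permissive reading).

## What the simulations emulate — and what they do not

The generator reproduces the published study conditions: 2D embryos grown
from one cell to an endpoint of about 132 biological cells, ensembles of
independent replicates (the desk-scale default is 50; the published setting
is 200), and the perturbation panel (rule deletions, FGF depletion/excess,
one-stage-unit FGF delay, halving and aggregation at or before the 8-cell
stage). It does not model intracellular gene-expression dynamics, FGF4
diffusion fields, osmotic cavity mechanics, PrE apico-basal polarity, or
any imaging-derived quantity; passing tests therefore say nothing about
those aspects of real embryos.

## Known limitations

* **Failure taxonomy.** Our wild-type failures are predominantly TE-ring
  ruptures (classified `NO_TE`), whereas the published failures are
  predominantly PrE-layer errors with only ~1% TE breaks. The overall
  success fraction matches; the split across failure modes does not.
* **Sorting is near-complete.** With the default relaxation budget,
  differential adhesion sorts almost every replicate fully by E4.5, so the
  incidence of embryos retaining a deep PrE cell (a few percent) sits below
  the published 13–15%. The trapped fraction is controlled by how far from
  equilibrium the ICM is allowed to remain — a quantity the source model
  does not pin down — and we chose not to tune the relaxation budget
  against it. For the same reason the delayed-FGF reduction in the PrE
  share is weaker here than published.
* **Strongly cohesive single-lineage ICMs** (FGF depletion/excess,
  neutralized adhesion) often wrap and tear the TE ring late in
  development; these endpoints are classified by their ICM composition,
  which is the phenotype those experiments report.
* The 3D mode is a qualitative validation (shell connectivity, cavity,
  seal); its count-based layer diagnostics are not calibrated, and shell
  inflation is marginal — only a fraction of 3D replicates open a cavity,
  the rest collapse into a compact ball. The published 3D validation
  presumably relied on settings (surface-cell threshold, daughter
  placement, relaxation) that are not fully specified.

## Problem sizes

Desk-scale ensembles use 50 replicates per condition (about 4 s per
wild-type replicate), the lattice model $10^5$ asynchronous updates, and
the 3D validation a single replicate to ~120 cells. The published ensemble
size (200) is available by setting `n_replicates = 200`.
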