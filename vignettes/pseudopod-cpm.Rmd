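---
title: "Pseudopod-driven Cellular Potts migration models and their quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudopod-driven Cellular Potts migration models and their quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podcpm)
```

## The modelling problem

Migrating cancer cells can change their speed and directional persistence
with local cell density. `podcpm` provides a two-dimensional Cellular Potts
Model (CPM) in which that density dependence can be studied mechanistically:
cells are sets of lattice sites sharing an identifier, and motion emerges
from stochastic identifier-copy attempts accepted through a Metropolis rule
on an energy function. On top of the base model the package implements four
persistence mechanisms — a target-direction bias, an actin-activity memory
(Act), an explicit pseudopod finite-state machine, and an extended pseudopod
model in which pseudopods pull on the cell and adhere at their tips — plus
the track-statistics suite needed to quantify the resulting migration
(speed, directional autocorrelation, streaming angles, Ripley L clustering,
correlograms).

## Base model

The energy of a configuration is

$$H = \sum_{(\vec v, \vec v_n)} J_{\tau(\sigma(\vec v)),\tau(\sigma(\vec v_n))}
      \left(1 - \delta_{\sigma(\vec v),\sigma(\vec v_n)}\right)
    + \lambda_V \sum_\sigma \left(v(\sigma) - V_\tau\right)^2,$$

a contact (surface) energy over unordered Moore-neighbor pairs with unlike
owners plus an elastic area constraint. A copy attempt proposes that a
uniformly drawn target site adopt the identifier of a uniformly drawn Moore
neighbor; it is accepted with probability $1$ when $\Delta H \le 0$ and
$e^{-\Delta H/T}$ otherwise. One Monte Carlo step (MCS) performs
`width * height` elementary attempts. Conventions chosen where the
formulation leaves freedom:

* **Periodic boundaries.** Avoids wall artifacts in density sweeps;
  centroids are maintained as unwrapped running sums so exported tracks are
  continuous across the seam and need no post-hoc unwrapping.
* **Pair counting.** Each unordered neighbor pair contributes once; a
  doubled-count convention would only rescale $J$.
* **Medium.** Identifier 0, no area constraint, no model state; it
  contributes nothing to the persistence, Act, pulling or tip-adhesion sums.
* **Connectivity constraint (optional).** A copy that would locally split
  the losing cell — its sites in the Moore neighborhood of the flipping site
  no longer form one Moore-connected component — is vetoed. This is the
  standard local test; it does not detect rare global splits. Removing a
  cell's last site is allowed and retires the cell.
* **Cell death.** A cell reaching area zero is retired from bookkeeping.

Cells are initialized as distinct random single pixels and grow to their
target area within the first few hundred MCS; measurements discard a
configurable equilibration period (1,000 MCS in all shipped study
configurations).

## Persistence extensions

**Basic persistence.** Each cell carries a target direction
$\vec t_{new} = (1 - dr)\,\vec t_{old} + dr\,\Delta\vec x/|\Delta\vec x|$
with $dr = \min(1/dt, 1)$, updated once per MCS from the centroid shift
(the finest centroid signal available); a zero shift leaves $\vec t$
unchanged, the continuous limit of the update. A copy attempt in update
direction $\vec s$ contributes
$\sum_{\sigma \in S} -\lambda_P\, v(\sigma)\, (\vec s \cdot \vec t_\sigma)$
over the involved cells.

**Act.** Every site remembers its last protrusive activity: a freshly
conquered site gets activity $Max_{act}$, which decays by one each MCS
(stored internally as a time stamp, which makes the decay free). A copy
attempt gains
$-(\lambda_{Act}/Max_{act})(GM_{act}(\text{source}) - GM_{act}(\text{target}))$,
where the geometric means run over the Moore neighborhood *including the
central site*, restricted to sites sharing the evaluated site's owner
(including the center is the original Act convention; excluding it only
rescales $\lambda_{Act}$). Copies from active contexts into less active
ones are therefore favored — the local positive feedback that produces
persistent motion. A site lost to the medium has activity zero.

## Pseudopod finite-state machine

Each cell owns a fixed number of pseudopods (default 3), each an ordered
chain of actin sites evolving per MCS:

* **INIT** — the first actin site is placed at the rounded cell centroid,
  but only if that site belongs to the cell; otherwise the pseudopod simply
  retries next MCS. The growth direction is drawn from a von Mises
  distribution centered on the cell's current movement direction with
  concentration `init-dir-strength`.
* **GROWING** — with probability `p-ext` (0.3) per MCS the chain proposes a
  tip extension along a von Mises draw around the current growth direction
  (`cont-dir-strength`), discretized to the nearest of the 8 Moore steps;
  the continuous direction is kept separately so repeated discretization
  does not lock growth onto lattice axes. A step landing on an own pixel is
  appended (and the growth direction becomes the realized step direction); a
  step into another cell fires the touch behavior; a step into medium simply
  fails. After `max-growth-time` MCS, or 20 MCS without a successful
  extension, the pseudopod starts retracting. The growth timer starts at the
  INIT to GROWING transition; the stall counter resets on every successful
  extension.
* **RETRACTING** — with probability `p-retr` (0.3) per MCS one site is
  removed: the tip (`retraction-mode = backward`, default) or the origin
  (`forward`, treadmilling). An empty chain goes INACTIVE.
* **INACTIVE** — re-enters INIT with probability
  `1/time-between-extensions` per MCS (geometric dwell).

The chain couples to the lattice in both directions: a copy attempt whose
flipping site has an actin site of the *growing* cell in its Moore
neighborhood (center included) gains `-neighboring-actin-bonus`, and an
attempt that would shrink a cell near its *own* actin is blocked outright
($\Delta H = \infty$). The block is what keeps every actin site inside its
cell, which the test suite verifies at every sampled MCS.

The cell's "movement direction" (used at INIT and by the poof-dir rule) is
not defined by the pseudopod description itself; the package smooths the
per-MCS centroid displacement with the same exponential form as the
persistence target direction (`movement-decay-time`, default 10 MCS).

## The extended pseudopod model

Three interaction mechanisms are added:

* **Tip adhesion.** When the site changing identity is adjacent to a foreign
  cell, each involved cell $\sigma$ compares two distances: $r_\sigma$ from
  the site to $\sigma$'s nearest pseudopod tip and $r_{\sigma_o}$ to the
  nearest tip of the neighboring foreign cell. The gaining cell receives no
  bonus if both exceed `max-distance-for-tip-bonus`, `-tip-bonus` if exactly
  one is within range, and `-2 tip-bonus` if both are; for the losing cell
  the same quantity enters with opposite sign, so a growth that displaces
  another cell nets zero and pseudopods cannot energetically "poke" into
  neighbors. Two conventions had to be fixed here: distances are measured
  from the site changing identity, and only the nearest foreign neighbor
  cell is considered when several touch the site.
* **Pulling.** Each involved cell gains
  $-F (\vec s \cdot \vec f_\sigma)/v(\sigma)$ where $\vec f_\sigma$ is the
  vector sum of its pseudopods' origin-to-tip vectors — pseudopods pull the
  whole cell in their combined direction, scaled down for heavier cells.
* **Touch behavior.** A pseudopod whose growth step lands in another cell
  has its growth rejected and then, depending on `touch-behavior`: nothing
  happens (`nothing`); it retracts (`retract`); it latches on (`attach`,
  entering a TOUCHING state it leaves toward RETRACTING with probability
  `p-touch-retr` per MCS); or, with `poof-dir`, a *lateral* pseudopod — one
  whose origin-to-tip direction makes $\cos\alpha < 0.85$ with the cell's
  movement direction — is removed instantly and restarts at INIT, a Contact
  Inhibition of Locomotion rule. If the pseudopod vector or movement
  direction is degenerate (length zero) the alignment is undefined and the
  pseudopod is left alone.

## Calibration of the shipped presets

The package does not inherit numerical parameter values for the individual
models; `model_preset()` carries this package's own calibration, chosen once
so that each model sits in its characteristic qualitative regime on the
desk-scale study geometry (150×150 lattice, target area 250, 5,000 MCS,
cell counts 10–60, i.e. 11–67 % area coverage):

* **base** — `T = 15`, `J_cell,med = 8`, `J_cell,cell = 6`,
  `lambda-v = 1`: a single cell diffuses (MSD log-log slope ≈ 1, DAC ≈ 0
  beyond lag zero).
* **persistence** — `J_cell,cell = 4`, `lambda-persistence = 0.015`,
  `decay-time = 2`: a deliberately weak-coupling regime. Cohesive contacts
  let crowded cells merge and push through each other, which raises mean
  speed with density, while the weak, short-memory bias keeps the fitted
  persistence time at its dilute value. This regime choice matters: with
  stronger coupling or slower decay the same model develops emergent
  flocking (pushed centroids feed back into target directions), and
  persistence time then *rises* steeply with density — a behavior the model
  class is specifically not supposed to show here.
* **act** — `lambda-act = 80`, `max-act = 40`, `lambda-v = 2`,
  `J_cell,cell = 30`: dispersive cell–cell contacts (well above twice
  `J_cell,med`), so crowding obstructs the activity-driven protrusions and
  mean speed falls with density.
* **ariotti** — the plain pseudopod machine with cohesive contacts
  (`J_cell,cell = 6`): clusters form and mutual obstruction of fixed
  dendrites lowers speed as density grows.
* **pseudopod-ext** — `J_cell,med = 12`, `pull-strength = 60`,
  `tip-bonus = 60`, `max-distance-for-tip-bonus = 3`, poof-dir touch
  handling: dilute cells are partially trapped by the raised medium surface
  energy; with increasing density, tip adhesion plus pulling free cells
  collectively, and both mean speed and persistence time rise.

Two ablation observations from this calibration are worth recording. With
pulling but no tip adhesion the density–persistence correlation collapses
to about zero (rotating, weakly translating clusters); with tip adhesion
but no pulling, collective speed drops by roughly 30 % and the
density–speed trend disappears, though the density–persistence correlation
remains positive rather than turning negative. The joint rise of speed and
persistence with density therefore requires both mechanisms, while the
touch behavior fine-tunes rather than creates the effect.

## Measurement protocol

Simulated tracks are centroid positions recorded every MCS after a
1,000-MCS equilibration discard. Instantaneous speed uses net displacement
over non-overlapping 50-MCS subtracks; per-MCS centroid jitter would
otherwise dominate. The directional autocorrelation (DAC),

$$DAC(\tau) = \langle \vec e_{j\Delta t}^{\,i} \cdot
  \vec e_{(j+n)\Delta t}^{\,i}\rangle,$$

averages the dot product of normalized step directions over all cells and
offsets, weighting every valid (cell, offset) pair equally; zero-length
steps have no direction and are skipped. For simulated tracks the DAC is
computed on every 5th sample: the thinning raises the displacement-to-jitter
ratio of individual steps without changing the time axis. After removing
the lag-0 point ($\equiv 1$), $\phi\, e^{-\tau/\tau_p}$ is fitted by
bounded nonlinear least squares ($\phi \in [0,1]$,
$\tau_p \in (0, 10\,\tau_{max}]$; starting values $\phi_0 = DAC(\Delta t)$
and the first lag below $\phi_0/e$). Fits that do not converge or pin
$\tau_p$ at a bound are flagged, not thrown; when the DAC is essentially
zero, $\phi \to 0$ and $\tau_p$ is unidentifiable — the flagged results and
the product $\phi\,\tau_p$ are the honest summaries in that regime.

Density sweeps report the observed density as cell count over lattice area,
the Spearman rank correlation of density with mean speed and with
$\tau_p$ across all runs, and Pearson correlograms Fisher-averaged across
seed replicates ($z = \operatorname{artanh} r$, averaged, back-transformed;
correlations of exactly $\pm 1$ have infinite $z$ and are excluded unless
every replicate sits at the same bound).

Spatial clustering uses Ripley's $L(r) = \sqrt{K(r)/\pi}$ with the
isotropic edge correction on rectangular windows, as implemented in the
`spatial` package's `Kfn`; $r - L(r) = 0$ under complete spatial
randomness, negative under clustering, positive under dispersion.
Streaming is quantified by the mean pairwise angle between the displacement
directions of cell pairs, binned by center-of-mass distance (default bin
width 5 lattice units; bins with fewer than 20 pairs suppressed), with an
optional per-frame drift correction that subtracts the mean displacement of
each frame and rebuilds positions cumulatively (idempotent by
construction).

## Fixture generators

The seeded generators provide ground truth for every statistic without any
external data: Brownian walks (fixed step, uniform directions); persistent
random walks as fixed-speed von Mises turning walks — after $n$ steps the
direction autocorrelation is $c^n$ with $c = I_1(\kappa)/I_0(\kappa)$ the
mean turning cosine, so $\tau_p = -\Delta t/\log c$ and
`kappa_for_tau_p()` inverts the map (numerically, switching to the
asymptotic $I_1/I_0 \approx 1 - 1/2\kappa$ beyond the range where Bessel
evaluation is stable); streaming track sets mixing a shared drift with
private noise; and CSR, Thomas-type clustered, and sequential-rejection
hard-core point patterns. They emulate the *statistical* structure of cell
tracks — not cell shape, volume exclusion, track fragmentation, or
segmentation noise of real imaging data — so passing parameter-recovery
tests demonstrates correctness of the estimators, not robustness to imaging
artifacts.

## Problem sizes and limitations

Shipped study configurations use a 150×150 lattice, 5,000 MCS, cell counts
{10, 30, 60} and 3 seeds per condition; the engine sustains well over
$10^6$ elementary attempts per second on one core, so a full three-model
discrimination sweep completes in minutes, and the full-scale geometry
(400×400, 20,000 MCS) remains available through the same configuration
keys. Known limitations: strictly two-dimensional, one cell type per
simulation in the presets; the connectivity test is local; long pseudopods
can pull a cell apart when the area constraint is soft (the actin shrink
block protects the chain itself, not the rest of the cell); the
basic-persistence regime classification is parameter-sensitive (see the
calibration section); and the Act and persistence models share the
engine's single smoothed movement-direction definition, which the
underlying formulations leave open.
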