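---
title: "A homeostatic epidermis model with base-pair mutation tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A homeostatic epidermis model with base-pair mutation tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidermisevo)
```

## The model

Normal human skin accumulates somatic mutations throughout life, and deep
sequencing of small biopsies shows a patchwork of subclones whose size
distribution is broadly consistent with neutral drift even though canonical
driver genes (NOTCH1, TP53) are clearly under selection. `epidermisevo`
implements a three-dimensional hybrid cellular automaton of the
interfollicular epidermis built to study that tension: how strong can a
driver's advantage be before it breaks the homeostasis that real skin
visibly maintains?

Cells occupy a `Lx x Ly x Lz` voxel lattice (one keratinocyte per 15 µm
voxel; `Lx` is derived from the biopsy area so a 1 mm² simulation is
66 x 66 columns). The lateral boundary is periodic, for both cells and the
growth-factor field, which removes edge artifacts and keeps per-area
statistics independent of domain size. The bottom plane of the lattice is
the basal layer: the stem/progenitor compartment.

**Growth-factor niche.** A single diffusible growth factor stands in for
the fibroblast-derived niche. Its quasi-steady field obeys a
diffusion-decay-consumption balance,
`D ∇²u − λ_d u − c·u·[occupied] = 0`, with a Dirichlet source `u = s0` on
the basal plane, periodic lateral faces, and an absorbing boundary above
the top cell layer (growth factor escaping at the skin surface). Rates are
expressed relative to `D` with the voxel as the length unit, so only the
ratios `λ_d/D` and `c/D` matter. The field is re-solved to quasi-steady
state (Gauss–Seidel, tolerance `1e-5` on the per-sweep update scaled by
`s0`) before every daily cell step; consumption by occupied voxels is the
feedback that lets tissue height self-regulate.

**Cell decisions.** Each day every cell, visited in a fresh random
permutation, first risks death with probability
`p_die(u) = d_max K_die^h / (u^h + K_die^h)` and otherwise attempts
division with probability `p_div(u) = p_max u / (u + K_div)`. Both
responses are monotone and saturating; the steep death Hill exponent
(`h_die = 4`) confines death to the growth-factor-poor upper layers, which
is what allows a ~27-cell-tall column to be sustained by a basal churn of
only ~0.5 divisions per cell per week. A dividing cell places its daughter
on one of its four lateral neighbours or directly above (uniform weights by
default). If the target is occupied, the occupant and the entire column
above it shift up one voxel (knock-on displacement); cells pushed past the
top layer are shed. Every birth, death and shedding is ledgered, and
`births − deaths − sheds = ΔN` holds exactly at every step.

**In silico genomes.** Each cell carries a genome restricted to a gene
panel (72 synthetic genes by default, log-uniform lengths 2–120 kb,
GC fraction 0.41, one NOTCH1-like and one TP53-like gene). At every
division each daughter acquires `X_g ~ Poisson(μ_g L_g)` new substitutions
per gene, with the per-gene rates normalised so their length-weighted mean
is `3.2e-9` per bp per division. The reference base of an event is drawn
from a multinomial putting probability 1/2 on cytosine and 1/6 on each
other base (renormalised over bases present in the gene), reproducing the
UV-type C-enriched signature; the position is uniform among positions
holding that base; for cytosine the alternate base is T with probability
0.9 (C>T transitions), otherwise uniform. Genotypes are stored as a
persistent parent-pointer tree, so "all ancestral mutations are inherited"
costs one integer per cell. Within a lineage a position is never hit twice
(infinite-sites; collisions are redrawn), keeping every mutation usable as
a cell-fate marker. The engine draws the per-division total from the
superposed Poisson and assigns genes by their mutation mass, which is
distributionally identical to the per-gene draws.

**Driver mechanisms.** Neither driver touches division rates.

* *NOTCH1 persistence*: when a division targets a site occupied by a
  NOTCH1-class mutant, the occupant vetoes the displacement with
  probability `f0` and the division is aborted. The mutant persists; the
  neighbour's birth is lost. That lost birth is the "cost" coupling the
  advantage to tissue integrity: sweeping `f0` upward monotonically
  increases the departure-from-homeostasis metric (the catch-22 — a strong
  enough NOTCH1 clone damages the epidermis). An earlier design in which a
  vetoed division was merely redirected to another candidate site was
  discarded because it left `f0` with no population-level consequence at
  all, contradicting that catch-22.
* *TP53 UV protection*: on each scheduled sun day every cell lacking a
  TP53-class mutation is killed independently with probability `theta_s`;
  TP53 mutants are spared, and that reprieve is their entire advantage.
  The yearly sun-day set `S` can be evenly spaced or clustered
  ("vacation"). With an empty `S`, TP53 clones drift exactly neutrally —
  the implementation guarantees this bitwise, because UV draws are only
  consumed for eligible cells. The same guarantee makes "blocking
  exhaustion" exact: inside a TP53-fixed region a second-wave TP53 clone
  experiences sun days as no-ops.

**Departure from homeostasis.** `dH = log(mean((N_k − N_s)²))` between a
trajectory and a homeostatic reference, with the mean squared difference
floored at 1 cell² inside the log so identical series give 0 rather than
−∞.

**Logistic surrogate.** For scanning `(|S|, spacing, theta_s)` before
committing to lattice runs, `simulate_logistic_uv()` treats the population
as logistic growth `dN/dt = rN(1 − N/K)` advanced exactly by its closed
form, with an instantaneous multiplicative kill `N ← (1 − theta_s) N` on
each sun day. `scan_uv_parameters()` grids the schedule space and flags
combinations whose minimum density falls below a homeostasis floor
(default `0.8 K`) — too much simulated UV costs tissue density.

**Virtual sequencing.** True VAFs are `n/(2N)` (diploid heterozygous; copy
number is not tracked). Sequencing noise follows the observed-depth model:
per-variant depth `D_i ~ Gamma(k_p, θ_p)` (gamma MLE fitted to depth
samples via `MASS::fitdistr`; the continuous draw is rounded with floor 1
since it is used as a binomial trial count), variant reads
`f_i ~ Binomial(D_i, VAF_t)`, and `VAF_s = f_i / D_i`. Calls below the
detectability cutoff 0.005 are filtered out, the boundary value being
kept.

**Clone statistics.** Clone area is `2·VAF·B` for biopsy area `B`, clamped
at `B` (noise can push a VAF above 0.5). Clone sizes are discretised in
units of one cell footprint (`cell_size²`, 225 µm²) to match the discrete
neutral-drift theory `P_n(t) = e^{−n/(rλ t)} / (n ln(rλ t))` with
`rλ = 0.51`/week. Neutrality is assessed through the empirical first
incomplete moment `μ1(n) = Σ_{m≥n} m P̂(m) / ⟨n⟩` — the fraction of clone
mass in clones of size at least `n`, which is 1 at the minimum size,
nonincreasing, and log-linear with slope `−β` for exponential
(neutral-drift) size distributions. Two distributions are compared with
the two-sample Kolmogorov–Smirnov statistic and the asymptotic critical
value `D_α = c(α)·√((m+n)/(mn))`, `c(0.05) = 1.358`; the KS is applied to
the clone-size samples underlying the `μ1` curves (the statistic is
defined on samples, which keeps `D_α` valid) and the signed excess
`D_mn − D_α` is reported.

## Calibration

The SI-level response shapes and growth-factor constants of the original
model are not printed, so the package treats them as calibration targets
rather than inputs. Two experimentally anchored quantities pin the neutral
engine:

* basal progenitor loss/replacement ≈ **0.51 per week** (per basal cell:
  deaths at the basal plane plus upward displacements out of it), and
* equilibrium density ≈ **120,000 cells per mm²**.

With `s0 = 1`, `λ_d/D = 5e-4` and `c/D = 0.024` the occupied-column decay
length is ~6.5 voxels; `p_max = 0.13`, `K_div = 0.4` set basal divisions
near 0.09/day, and `d_max = 0.5`, `K_die = 0.010`, `h_die = 4` place the
death wall near column height 27. These defaults were frozen after pilot
grid runs on 0.04 mm² domains (540–730 simulated days) and validated on
0.25 mm²: density 119.6–123.3k/mm², basal loss 0.50–0.51/week. The
`calibrate()` helper re-runs that pilot search for user-modified targets.

## Measurement conventions

* **Basal lineage half-life.** All basal cells are labelled at `t0`; a
  lineage survives while at least one descendant occupies a basal voxel.
  The weekly surviving fraction is fitted with `S(t) = e^{−kt}` on the
  survival scale anchored at `S(0) = 1` (an exact datum — every labelled
  lineage is present at labelling). The anchoring matters: basal lineage
  turnover is a two-dimensional coalescing (voter-type) process whose
  survival curve has a slowly decaying `ln t / t` tail of rare persistent
  lineages — the holoclone-like survivors. An unanchored log-scale
  regression is dominated by that tail and roughly doubles the half-life;
  the anchored fit tracks the bulk decay and yields ~3.6–3.9 weeks under
  the calibrated defaults, with ~86% of lineages lost from the basal layer
  by simulated day 120. That tail is also why the lineage-loss percentage
  at 4 months sits ten points below what a pure exponential with the same
  half-life would give (95.6%): the voter-model coarsening is a structural
  property of any displacement-driven basal layer at this churn rate, as
  we verified against an independent lattice voter-model oracle.
* **Density.** Weekly population means over the final simulated year,
  scaled linearly by area to 1 mm².
* **dH references.** A test trajectory is compared against a neutral
  reference averaged over replicate seeds; with common seeds the `f0 = 0`
  case is bitwise the reference and `dH = 0` exactly.

## Numerical choices and degenerate inputs

* Gene coordinates are 0-based half-open, so `L = end − start` and BED-style
  tables load directly. Panels loaded from TSV carry only base counts; a
  deterministic block layout consistent with the counts is synthesised,
  which is immaterial to every statistic (only "uniform among positions of
  the same base" matters) but keeps reloads reproducible.
* Genes missing a base class renormalise the reference-base multinomial
  over the classes present.
* The GF solver stops when the largest per-sweep update falls below
  `gf_tol · s0`; for closed-form comparisons use `1e-7` (Gauss–Seidel
  per-sweep change understates the true error by the spectral-radius
  factor; at `1e-7` the profile matches the 1D diffusion–decay solution to
  0.02%). The daily re-solve warm-starts from the previous field, so the
  default `1e-5` costs only a few sweeps per day while the field tracks
  slowly moving occupancy.
* A daughter placed "above" from the top layer is shed immediately (birth
  and shed both ledgered); its unobservable genome is not generated.
* Depth draws are rounded to integers with floor 1; `fit_depth_model`
  refuses constant samples (the gamma MLE is degenerate there) and fewer
  than 30 observations.
* `sun_schedule(n = )` places `floor(seq(1, 365, by = 365/n))`, giving
  exactly `n` distinct days for any `n ≤ 365`.

## What the synthetic generator does and does not emulate

The default panel is synthetic: gene count (72), length range, GC content
and the single NOTCH1-like / TP53-like genes mirror a realistic
UV-exposed-skin panel, but the identities, per-gene empirical rates and
real hg19 sequence of any particular study panel are not reproduced; real
panels can be loaded from TSV. Consequently, passing tests demonstrate the
*mechanisms* — Poisson mutation accrual, signature enrichment, neutral
drift statistics, selection phenotypes — on panel-like inputs, not
concordance with any specific patient cohort. Test- and fixture-scale runs
also inflate mutation rates by 2–3 orders of magnitude to harvest enough
clones from millimetre-fraction domains; every rate-dependent assertion is
scale-aware (statistical tolerances follow the sample actually drawn).

## Problem sizes

Desk-scale defaults keep everything on one CPU: calibration pilots and
property tests run 0.01–0.09 mm² domains for up to ~1.5 simulated years;
the headline reproductions use 0.25 mm² (33 x 33 x 30) with 3 seeds — two
years for density, 26 tracked weeks for lineage kinetics, 12 weeks for the
turnover validation. Patient-scale settings (1–3.14 mm², 58 years) are
reachable through `sim_config()` but are hour-scale computations.

## Known limitations

* No melanocytes, fibroblasts, dermis, or mechanics; the niche is one
  diffusible field.
* No indels, copy-number changes, or trinucleotide-context signatures.
* Transient amplifying cells are only implicit (suprabasal divisions).
* The logistic surrogate is single-compartment; it does not resolve the
  TP53-mutant subpopulation (a two-compartment extension would).
* Knock-on displacement is strictly vertical, and UV kill by default
  strikes all layers (a basal-only flag exists).
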