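---
title: "An agent-based germinal center with virtual two-photon read-outs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based germinal center with virtual two-photon read-outs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcsim)
```

## The model

Germinal centers (GCs) are the micro-anatomical sites where B cells mutate
their receptors and are selected for affinity, organized into a dark zone
(DZ, division and mutation, CXCL12-rich) and a light zone (LZ, selection on
follicular dendritic cells (FDCs) and by T follicular helper (Tfh) cells,
CXCL13-rich). `gcsim` simulates this reaction as agents on a cubic lattice
(5 µm constant) filling a spherical GC of radius 160 µm, over up to 21 days
of real time, and then re-measures the simulation with the same procedures
two-photon microscopists apply to real GCs: reached-distance curves,
speed and turning-angle distributions, photoactivation transzone tracking,
DZ/LZ ratios and targeted antigen delivery.

### Space, chemokines, zones

The GC sphere sits in a bounding box; the equatorial plane perpendicular to
the z axis separates DZ from LZ (plane nodes count as LZ). FDC somata
(default 200) occupy random LZ nodes and extend dendrites two nodes along
each axis; dendrite nodes are transparent to movement and act as antigen
contact sites. CXCL13 is produced at FDC somata; CXCL12 at a stromal cap of
the spherical shell on the DZ pole (the DZ boundary toward the T zone).
Both fields solve the steady state of diffusion-production-degradation
(`-D lap(c) + k c = s`, 7-point stencil, zero concentration on the box
faces, conjugate gradients with residual control), are precomputed once per
FDC configuration, cached, and cross-checked against a transient
explicit-Euler relaxation in the test suite. Defaults `D = 600` µm²/min and
`k = 0.24`/min give a decay length of 50 µm, so concentrations span the GC
with a well-defined gradient structure; the absolute scale is arbitrary and
only enters relative to the sensitivity thresholds below.

### Motility: persistent random walk with transient chemotaxis

Cells repolarize every persistence time τ (drawn per cell from U[1, 2] min)
by turning at a Gaussian angle (mean 60°, width 25°) with uniform azimuth.
Chemokine sensitivity is hysteretic: a sensitive cell desensitizes where
the local concentration of its zone chemokine reaches `c_D` and resensitizes
only below `c_R < c_D`. While sensitive, the normalized gradient is added
to the random direction (weight `w = 1`) and renormalized. DZ-phenotype
cells sense CXCL12, LZ-phenotype cells and Tfh sense CXCL13. Thresholds are
expressed as multiples of the zone-boundary concentration `c_b` of the
respective chemokine:

| preset            | c_D      | c_R      | behaviour            |
|-------------------|----------|----------|----------------------|
| `reference`       | 2.0 c_b  | 1.0 c_b  | tight zones          |
| `low_resens`      | 2.0 c_b  | 0.4 c_b  | leaky (resensitizes too deep) |
| `boundary_desens` | 1.0 c_b  | 0.7 c_b  | leaky (desensitizes at the boundary) |

In the reference setting a cell desensitizes well inside its own zone and
resensitizes at the boundary, which is what keeps the zones separated while
individual cells still look like random walkers — the transient-chemotaxis
picture. The two alternative presets displace these surfaces and make the
zones leaky; the package reproduces the loss of transzone-migration
asymmetry under both.

Movement is stochastic on the lattice: each step of `dt = 20` s the cell
attempts a hop with probability `v dt / Δx` toward one of the six
neighbors, chosen with probability proportional to the positive projection
of its polarity, realizing off-axis net motion. A blocked move onto an
oppositely polarized mobile cell exchanges the two with probability 0.5;
boundary moves fail. At the B cell default speed of 7.5 µm/min this gives
one hop attempt with probability 0.5 per 20-s observation frame, which is
exactly the printed arithmetic behind the ~50% zero-speed observation:
2.5 µm of travel per frame against a 5 µm lattice constant. We deliberately
align the step with the standard 20-s imaging interval; a finer step with
proportionally smaller hop probability would inflate the zero-displacement
fraction toward `e^{-1/2} = 0.61` because hop counts per frame become
Poisson rather than Bernoulli. The cost of this choice is that within one
20-s frame only {0, 15} µm/min speeds exist on the lattice; diagonal
(next-to-next-neighbor) displacements appear at coarser observation
intervals, where several hops combine.

Cells in contact (B-FDC during a capture event, B-Tfh conjugates) and cells
in M phase are frozen: they skip repolarization and movement, and their
track samples carry a `frozen` flag so the analytics can exclude them, as
experimentalists exclude interacting cells.

### Shape space, affinity, mutation

Receptor genotypes live on a bounded 4-dimensional integer lattice
(coordinates in [-10, 10]); one unit step is one point mutation, distance
is L1. Affinity to the optimal clone at the origin is
`exp(-(d/Γ)²)` with `Γ = 2.8` mutation steps. The simulation core fixes
dimension 4 (the R-level operators are dimension-agnostic); the lineage
this model family descends from uses low-dimensional shape spaces, and the affinity
width is chosen so that a founder 5-10 mutations away (affinity 0.04 to
3e-6) is essentially unselectable while 2-3 well-placed mutations already
yield order-0.1 affinities — affinity maturation then happens within the
5-10 mutations the founders need to traverse. At each division every
daughter mutates with probability 0.3 to a uniformly chosen in-bound unit
neighbor.

### The reaction

Founders arrive as a Poisson process (2 cells/h for the first 4 days,
~100-200 per GC), start with DZ phenotype and a shape drawn uniformly from
the shells at distance 5-10, and divide 6 times before first
differentiation to the LZ phenotype. An LZ B cell (centrocyte) has a 10-h
antigen-search window: at FDC dendrite nodes it captures one antigen
portion per successful test (success probability =
`capture_efficiency × affinity × (1 - masked fraction)`, given the node
still holds free portions; a success freezes the cell for 5 min). A cell
that ends the window without any antigen dies; otherwise it seeks Tfh help
for up to 6 h. Tfh (250 motile, CXCL13-sensitive agents) polarize to the
neighboring centrocyte with the most collected antigen (ties uniform); a
polarized conjugate freezes both cells and delivers signal. A centrocyte
accumulating 3 h of polarized contact is positively selected; failing the
deadline it dies. Apoptotic cells stay visible on the lattice for 6 h
(they no longer sense CXCL12 and cannot migrate back to the DZ), then
clear.

A selected cell re-differentiates to the DZ phenotype with CXCL12
sensitivity reset and receives a number of divisions from the Hill function

P(a) = P_min + (P_max − P_min) · aⁿ / (aⁿ + K_Pⁿ),  P_min = 1, P_max = 6,
n_P = 1.3, K_P = 11.619,

where `a` counts its antigen-collection events. `K_P` follows the Hill
midpoint convention (P(K_P) = 3.5); fractional division numbers are
realized by stochastic rounding so the mean equals the Hill value exactly.
Dividing cells (7-h cycle, 10% jitter, final 30 min immobile M phase) split
their antigen asymmetrically (72% of divisions give one daughter 72%).
When a selected cell's clone finishes its division program, the sibling
with the most antigen leaves as a plasma cell; all others return to the LZ
as fresh centrocytes — recycling is therefore 1 − 2^(−P) per cohort (50%
at one division, 87.5% at three); at the reference mean of about two
divisions roughly 70% of division-phase products re-enter selection
rather than exiting, and plasma output per selection is an order of
magnitude above a one-exit-per-selection scheme.

### Antibody feedback

Plasma cells (assumed representative of all ~100 GCs of the organism,
diluted in 0.01 l) produce antibody in four affinity classes; soluble
antibody masks FDC-held antigen with binding kinetics
`db/dt = k_on·Ab·(1−B) − k_off·b` per class (`B` the total bound fraction,
`k_off = k_on·K_D`, `K_D` log-interpolated from 1e-6 M at affinity 0 to
1e-8 M at affinity 1), and antibody is eliminated with a 5-day half-life.
Only the free fraction of antigen is available for capture, so rising
output throttles further selection — the main negative feedback that bends
the population curve down after the peak, together with consumption of the
finite FDC antigen stock.

## Calibration

Paper-anchored quantities (speeds, persistence times, lattice constant,
mutation probability, influx, DND Hill parameters, exchange probability,
zone chemokines) are fixed. The micro-parameters the literature does not
state — FDC dendrite reach and antigen stock (50 portions/node), capture
efficiency (0.15), Tfh contact requirement (3 h within 6 h), feedback scale
(1e-17 mol/min per cell with a 5-day antibody half-life) — were calibrated
jointly against the macro-behaviour this model family is required to show:
a mean number of divisions per positive selection near 2, a bounded
population peak (reached around day 9 under these defaults), and decay of
the total B cell count to roughly half of its peak by day 11. The Tfh requirement of 3 h (rather than a few tens of
minutes) deserves a note: with short conjugates, selection throughput is
effectively unlimited and the simulated GC grows explosively until a
resource collapses — the long interaction time is what caps selection at
the Tfh capacity and produces bounded, smoothly declining kinetics. This
matches the observation in the source model family that light-zone B cells
must reside in prolonged interaction with Tfh for the DZ/LZ dynamics to
come out right.

## Virtual imaging

Tracks sample positions of all live B cells every 20 s (coarser intervals
subsample). The reached-distance curve is the ensemble mean of
`|r(t) − r(0)|`; the motility coefficient applies `M = <|r|>²/(6t)` through
the slope of a linear regression of mean displacement against `√t` over
4-9 min, avoiding the persistence-dominated quadratic start (a pointwise
variant of the same estimator is exposed as an option). For an ideal
persistent random walk measured this way the expected value carries the
Maxwell factor: `M → (8/3π)·v²τ/3 ≈ 23.9` µm²/min at the reference speed
and persistence — the lattice simulation lands close to this and to the
printed simulation value (~24.7).

Speed distributions are reported against their observation interval
(they are a property of the measurement, not the cell); turning angles
exclude values ≤ 10° because the lattice over-produces near-zero angles,
and zero-displacement intervals are skipped. Photoactivation labels all B
cells in a 40-µm sphere centered mid-zone at a configurable day and counts
labeled cells per zone over 6 h, with apoptotic labeled cells counted at
their death position until clearance. The transzone rate tracks all B
cells for ≤ 1 h and reports the percentage whose zone changes, by
direction. The targeted-delivery experiment flags half of the B cells as
DEC205-positive; at the injection day those in the LZ receive a full
antigen load (35 collection-equivalents, ~5-fold a typical FDC collector)
without FDC capture, for a 12-h window, and DZ/LZ ratios are recorded per
subset; disabling the Hill control (fixed 2 divisions) changes the
response qualitatively.

## What the generator does and does not emulate

The synthetic arena reproduces the statistical structure of GC imaging
data: lattice-resolution motility with zone-keeping chemotaxis, two-step
selection with resource competition, and realistic population kinetics.
It does not model receptor-level signaling, chemokinesis, Tfh-derived
CXCL13 or Tfh exchange between GCs, nucleotide-level hypermutation,
class switching, or memory-versus-plasma fate choice; absolute chemokine
concentrations and the antibody-feedback magnitudes are effective-scale
quantities rather than measured ones. Passing tests therefore certify the
model's internal mechanics and its agreement with the published
macro-read-outs, not microscopic fidelity of any single interaction.

## Numerical choices and degenerate inputs

The chemokine solve enforces a relative residual below 1e-8 with an
iteration cap and raises an error reporting the residual otherwise; an
empty source set returns the zero field. Zone classification assigns
boundary-plane nodes to the LZ. Division onto a full neighborhood is
deferred, not canceled. A zero polarity re-initializes isotropically.
Tie-breaks (Tfh polarization, equal antigen) are uniform. A run is fully
reproducible from configuration plus seed (one R RNG stream drives both
the R and the compiled layer). Problem sizes in the tests and the
acceptance script (arena radii 80-160 µm, 3-20 replicates, 6-12.5
simulated days) were chosen so the whole suite runs on a laptop-class
machine in minutes while leaving the reference conditions intact where a
printed number is being reproduced.

## Known limitations

Population kinetics beyond ~day 14 degrade toward extinction faster than
real GCs, which receive naive-cell input and Tfh turnover we exclude by
design. The zero-speed fraction and the speed-distribution support are
consequences of aligning the movement attempt with the 20-s frame (see
above); analyses at intervals below 20 s are not meaningful in this
discretization. The DZ/LZ ratio of the DEC205 experiment reproduces the
direction and timing of the published response, not its absolute
amplitude.
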