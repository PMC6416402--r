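---
title: "Conformational locks of a dimeric enzyme interface: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational locks of a dimeric enzyme interface: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflock)
```

## The model

A homodimeric enzyme E2 dissociates thermally through a chain of still-active
intermediates,

E2 ⇌ E2¹ ⇌ E2² ⇌ … ⇌ E2ᵐ ⇌ 2E1 ⇒ 2Ed,

where E1 is the folded monomer and Ed its irreversibly denatured form. The
true number of intermediates m is unknown, but the shape of the
residual-activity decay bounds it from below through the empirical
lock-counting relation

n = (0.13 + δ) / (0.13 − 0.05 δ),  δ = R − 1,

valid for 0 ≤ δ < 2.6 (the denominator vanishes at δ = 2.6). Each
countable step corresponds to a *conformational lock*: a group of
inter-subunit contacts that break together. For the Cu,Zn-SOD dimer the
structural route gives a concrete picture: the A–B interface carries four
hydrogen-bond residue pairs (all involving Ile149, Gly49 and Gly112,
≈ −57.7 kJ/mol in total, electrostatics-dominated) and twenty-five
hydrophobic residue pairs (≈ −87.7 kJ/mol, van der Waals-dominated), and
under a constant-velocity steered pull these pairs lose their interaction
energy in two distinct epochs — one group of 8 pairs (−30.10 kJ/mol) near
240 ps, a second group of 21 pairs (−115.23 kJ/mol) near 400 ps, with every
trace at zero by ~520 ps. Two epochs, two locks.

This package implements the full desk-side analysis: contact census from
structure, per-pair energy summaries from pull traces, rupture detection
and lock grouping, and the kinetic lock count — plus generators that
emulate the pull data so the whole pipeline runs and is tested without an
MD engine.

## Interface census

Contacts are classified from geometry alone, with all thresholds in
`contact_criteria()`:

| criterion | default | unit | note |
|---|---|---|---|
| H-bond donor–acceptor | 3.35 | Å | heavy-atom distance; donor/acceptor typing from a built-in per-residue table |
| H-bond hydrogen–acceptor | 2.70 | Å | only when the structure has hydrogens |
| D–H···A angle | ≥ 90 | deg | only when hydrogens are present |
| hydrophobic contact | 3.90 | Å | any inter-chain C/S–C/S atom pair |
| salt bridge | 0.60 | nm | anionic vs cationic group centroids |

These are the published HBPLUS/LigPlot-style defaults; crystal structures
without hydrogens (the common case) use the distance-only hydrogen-bond
rule. Hydrophobic contacts are counted both at atom level and collapsed to
unordered residue pairs, because "hydrophobic bonds" in interface
censuses can mean either; both counts are exposed. The salt-bridge cutoff
doubles as the exclusion statement for the dimer's only inter-chain
charged pair (Asp11–Lys9, whose centroids sit ≈ 0.70 nm apart).

Structure I/O and Kabsch-fit RMSD are delegated to `bio3d`; coordinates are
kept in Å internally (PDB native) and every reported geometric quantity
(COM separation, RMSD) is converted to nm at the API boundary. RMSD of
fewer than three atoms, or of a collinear selection, falls back to the
unfitted RMSD with a warning rather than attempting a degenerate
superposition. Multi-model PDB files are accepted as toy trajectories;
binary trajectory formats are out of scope.

## The synthetic dimer

The census needs a structure, and the real crystal structure cannot be
bundled, so `build_sod_like_dimer()` constructs a synthetic one whose
interface realizes, by construction, the published census: the 4
hydrogen-bond pairs at 2.9 Å donor–acceptor distance, the 25 hydrophobic
pairs carrying 75 apolar atom contacts inside the 3.9 Å cutoff, the
Asp11–Lys9 charged pair at 0.70 nm (excluded at the 0.6 nm cutoff), Cu/Zn
as flagged HETATM, and ballast atoms placing the chain centers of mass
2.82 nm apart. Residue centers come from a penalized least-squares layout
of the contact graph (edge targets ≈ 6.9 Å; floors of 9.4 Å between
non-interacting cross-chain residues, 7.8 Å within a chain, 11 Å between
unrelated charged pairs, solved from several deterministic starts);
contact atoms are then placed with controlled offsets along each edge, and
all remaining atoms are parked in each residue's back hemisphere. The
margins between design distances and cutoffs make the intended census
robust to the residual layout error, and the suite verifies the census
against a brute-force all-pairs distance scan.

This scaffold is deliberately *not* a stereochemically valid protein: bond
lengths, angles and packing are unphysical, and only the inter-chain
distance relations are meaningful. Passing the census tests therefore
shows that the detectors implement their geometric definitions correctly —
not that those definitions reproduce any particular experimental structure.
`dissociation_trajectory()` translates chain B rigidly along the COM axis
(2.82 → 6.83 nm), which emulates the pulled separation but none of the
intra-chain deformation a real pull produces.

## Energy traces and summaries

Each residue pair carries two short-range components, Coulombic and
Lennard-Jones; summaries report electrostatic = mean(coul),
vdW = mean(LJ), total = their sum, and tables aggregate by column sums.
The packaged tables satisfy the row identity |elec + vdW − total| ≤ 0.015
kJ/mol (they are printed to two decimals) and their column totals
reproduce the published values; note the hydrophobic table's printed vdW
column total (−74.10) differs from the sum of its own rows (−74.13) by one
rounding step, so the package reports computed sums throughout.

The averaging window matters: a trace that has ruptured averages toward
zero, so full-trace means dilute the bound-state energies. The pipeline
therefore averages each pair over its *bound phase* — from the start of
the trace to twice the smoothing window before its detected rupture — which
is what makes the recovered group energies match the tabulated depths;
`summarize_pair(window =)` exposes the choice, and full-trace averaging
remains available by passing `window = NULL` explicitly outside the
pipeline. Mismatched time grids are joined by nearest time within half the
smaller sampling interval.

## Rupture detection and lock grouping

`detect_rupture()` formalizes "the energy decreased obviously around t"
as: baseline = mean over the first 50 ps; smooth the total-energy trace
with a centered 10 ps moving average; the rupture time is the first
instant the smoothed magnitude falls below α = 0.1 of |baseline| and stays
there for 20 ps. A pair whose baseline magnitude is below the 0.5 kJ/mol
noise floor was never meaningfully bound and is reported as unassigned
(with the packaged energies this catches exactly one pair, Val5A–Gly49B at
−0.43 kJ/mol). All five knobs live in `lock_config()`.

Grouping is deliberately simple and order-free: sort the rupture times and
split recursively at the largest inter-event gap while it exceeds
`min_gap` (50 ps), up to `max_groups` (4), ties going to the earlier split
point. This is equivalent to cutting at the largest qualifying gaps, which
is how the suite's independent oracle checks it. With two epochs 160 ps
apart and per-pair jitter of a few ps, the split is unambiguous; the
50-seed benchmark (`evaluate_lock_recovery()`) recovers exactly two groups
with ≥ 96% membership accuracy and group epochs within ±20 ps of 240 and
400 ps.

## The parametric trace generator

`generate_traceset()` emits, per pair, total energy
`depth · S(t) + S(t) · OU(t)`: a sigmoid decay S centered at the pair's
group epoch (240 or 400 ps; 10–90% width 10 ps; per-pair center jitter
SD 5 ps) times the tabulated depth, plus Ornstein–Uhlenbeck noise
(correlation time 1 ps, SD 20% of |depth|) that decays with the same
envelope so every trace is exactly zero-mean after rupture. The component
split uses each pair's tabulated electrostatic fraction, which can lie
outside [0, 1] when the two components have opposite signs — exactly as in
the tables. Noise at 20% of depth is a realistic scale for short-range
pair energies sampled at 0.1 ps; the generator does not emulate
force-field specifics, long-range terms, or correlated rupture cascades,
so recovery results certify the detector against this idealized decay
model, not against real MD output.

## The mechanistic pull simulator

`simulate_pull()` integrates one overdamped Langevin coordinate (the
inter-chain separation increment) under the steering spring
F = −k[x(t) − x(0) − vt] plus harmonic bond forces; a bond breaks
irreversibly when its extension passes `break_extension`, and its energy
`depth · (1 − (x/e_b)²)` rises to exactly zero at the break. Defaults:
two effective bonds with break extensions 0.13 and 0.30 nm (the average
stretching distances at which the two locks let go), depths −12 and
−25 kJ/mol, friction γ = 300 kJ mol⁻¹ nm⁻² ps, T = 300 K, dt = 0.01 ps
with a hard stability guard dt·(k + Σs)/γ ≤ 0.2. The depths are several
k_BT so escape is force-assisted rather than purely thermal; that is what
gives the mean rupture force its robust increase with pulling velocity,
and the force fluctuation its growth with spring stiffness (k·√(k_BT/(k+s))
to leading order). The model is 1-D, solvent-free and rotation-free: it
reproduces the qualitative force phenomenology (tested as monotonicity
over 20 seeds per condition), and no quantitative force values should be
compared against any particular MD setup. At zero temperature and slow
pulling it has a closed-form rupture force, s·e_b, used as the test
oracle.

## Estimating R from kinetics

The lock-counting relation consumes R, but the operational definition of R
is not recoverable from the lock-counting formula alone; this package
adopts the convention R = (total activity loss)/(first-resolved-step
loss), the only reading under which a clean single-exponential decay gives
R = 1, δ = 0, n = 1, consistent with simple one-step dissociation. This
is a documented convention, prominently repeated here because comparisons
with other implementations of the theory hinge on it.

`estimate_R()` works in three stages. (1) Candidate transitions are local
minima of the smoothed activity derivative; candidates closer than 1/15 of
the time span are merged (an extended exponential transition can throw
several derivative minima, and splitting one true step in two would halve
the first-step height and inflate R), and candidates below a 5% step
height are dropped. (2) The number of steps is chosen by BIC over a
staircase model with exponential transitions whose rates come from the
derivative peaks. (3) The fit is polished by least squares in the
sum-of-exponentials family A(t) = L₀ − Σ hᵢ(1 − exp(−rᵢ(t − τᵢ)₊)); the
polish is accepted only when it stays within 20% of the plateau estimate,
since on noisy curves an unconstrained refit can chase noise with a tiny
spurious first step. On noiseless generated curves the chain recovers R to
machine precision; with 2% measurement noise the estimate is unbiased to
well under 1%. Uncertainty comes from a block bootstrap of the residuals
(blocks of ~5% of the series) re-run through the fast detection path and
recentered on the polished point estimate; across 100 seeded noisy curves
the nominal-95% interval covers the generator's n in well over 90% of
runs.

## Problem sizes and determinism

The suite and the acceptance script run on: the 388-atom synthetic dimer;
trace sets of 29 pairs × 6001 samples (600 ps at 0.1 ps); 50 seeded trace
sets for the recovery benchmark; 20 replicates per condition for the
velocity (0.001/0.01/0.08 nm ps⁻¹) and stiffness (100/250/400 kJ mol⁻¹
nm⁻²) sweeps; and 100 seeded curves for bootstrap coverage. These sizes
were chosen so every stochastic check is statistically comfortable while
the full analysis reruns in a few minutes on one core. Every generator
takes an explicit seed and restores the caller's RNG state; identical
seeds give bit-identical output, and `run_pipeline()` reruns are
byte-identical including the JSON report.

## Known limitations

- The census criteria are distance-based; π-stacking, cation–π and
  water-mediated interactions are not modeled, and reproducing any
  specific published census depends on the criteria chosen.
- The synthetic dimer validates detector geometry, not structural realism;
  the generators validate detection and counting logic, not force fields.
- Rupture kinetics are not modeled beyond monotone phenomenology: no
  Bell/Dudko–Hummer–Szabo fits, no free-energy reconstruction.
- Mutants are representable only as altered bond depths/epochs in the
  generators, not as structural changes.
- The Poltorak R convention above is a choice; n is reported both as the
  real value of the relation and as an integer ceiling, and δ ≥ 2.6 is
  flagged invalid rather than extrapolated.
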