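---
title: "Simulating and detecting the self-tying of a knotted protein chain"
author: "knotfold developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting the self-tying of a knotted protein chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

About 2% of deposited protein structures contain a backbone knot.  How an
unknotted, newly-translated chain ties itself into its native knot is a
question about the *order* of events: which contacts form first, which
region stays open, and how a terminal segment passes through it.  knotfold
implements, at one-bead-per-residue (C-alpha) resolution, the complete
computational machinery needed to study this on synthetic knotted chains:

1. biased ("ratchet-and-pawl") dynamics that drive a denatured chain
   toward a target contact map while keeping the external work minimal;
2. a-posteriori scoring of the trial trajectories by their probability
   under *unbiased* overdamped Langevin dynamics (the dominant-reaction-
   pathway idea), so that the least-steered path per start is retained;
3. exact topological classification of open chains (knot, slipknot, or
   unknot) through Alexander determinants after stochastic closure;
4. pathway-heterogeneity statistics over the order of native-contact
   formation, and a geometric classifier for the three knotting
   mechanisms reported for small trefoil proteins: threading, slipknot
   and mousetrap.

Everything runs on a generated 48-bead "shallow trefoil" toy protein, so
no structure downloads are required.

## The collective coordinate and the ratchet

The contact function is the smooth rational switch

$$C(r) = \frac{1 - (r/r_0)^p}{1 - (r/r_0)^q}, \qquad (p, q) = (6, 10),
\quad r_0 = 7.5\ \mathrm{\mathring A},$$

with the removable singularity at $r = r_0$ evaluated by its limit
$p/q = 0.6$.  The collective coordinate is the squared distance between
the instantaneous and native contact maps,

$$z(X) = \sum_{|i-j| \ge 3} \left[ C_{ij}(X) - C_{ij}(X_{\rm nat})
\right]^2 .$$

Two support modes exist for the pair sum, behind a flag: `"native"`
restricts it to pairs in contact in the native map (sparse, cheap) and
`"all"` uses every admissible pair.  The package default is `"native"`;
the folding campaign uses `"all"`, because with the toy's sparse contact
set the native-support coordinate rewards *any* compaction and lets the
chain collapse into glassy globules in which every native contact is
"formed" at the 1.2x tolerance while the fold is wrong (we measured
near-zero RMSD correlation in such traps).  The all-pair form penalizes
non-native contacts too and is the faithful reading of a contact-map
*distance*.

The ratchet bias is one-sided harmonic,

$$V(z; z_m) = \begin{cases} \frac{k_R}{2}(z - z_m)^2 & z > z_m \\
0 & z \le z_m, \end{cases}$$

where $z_m$ tracks the running minimum of $z$.  No force acts while the
chain spontaneously approaches the native map.  Backtracking is allowed
by a Metropolis rule: an uphill update $z_m \to z_t > z_m$ is accepted
when $e^{-\tilde\beta (z_t - z_m)} \ge u$.  The linear form in
$(z_t - z_m)$ is our reading of the (elided) published rule; the
artificial inverse temperature $\tilde\beta$ is calibrated so that an
uphill move of about 1% of the initial denatured $z$ (~0.6 units for the
toy) is accepted with probability of order 0.1, giving $\tilde\beta
\approx 4$; the campaign uses $\tilde\beta = 1$ (more permissive
backtracking), which the trap-escape experiments favored.  With
$\tilde\beta \to \infty$ the original monotone ratchet is recovered, and
the test suite asserts this.

Two engines apply the bias:

* `run_rmd()` — overdamped Langevin, $\Delta x = (D \Delta t / T)
  F + \sqrt{2 D \Delta t}\, \eta$, with $F$ the physical force minus
  $\nabla V$.  This is the formulation the path weights presuppose, and
  its contract (zero bias whenever $z \le z_m$; $k_R = 0$ unbiased;
  monotone $z_m$ at $\tilde\beta = \infty$) is tested per step.
* `run_mc()` with a `bias` argument — the same bias enters the
  Metropolis acceptance of crankshaft/Cartesian moves.  Crankshaft
  dynamics is the standard polymer-physics mimic of Brownian chain
  motion, and it is what the reference CG studies of knotted proteins
  used for folding; it reaches the folded state roughly two orders of
  magnitude faster than our Langevin integrator at equal wall time, so
  the end-to-end campaign uses it by default (`engine = "mc"`).

Units: energies in $k_BT$ at the reference temperature (the `temperature`
arguments are in units of that reference), lengths in Angstrom, time in
reduced units.  The mapping of the reduced temperature to 300 K is a
convention, not a calibration, and is flagged as such.

## Path weights (dominant reaction pathway)

A trial trajectory is scored by the log-probability of realizing its
frame sequence under the *unbiased* overdamped dynamics, the discretized
Onsager-Machlup action in the Ito convention (force at the step's
starting frame):

$$\log w = -\sum_t \sum_i \frac{\left| \Delta x_{t,i} - \frac{D_i \Delta
t}{k_B T} F_i(x_t) \right|^2}{4 D_i \Delta t} + \text{const}.$$

Weights are computed on saved frames with $\Delta t$ equal to the save
interval — an approximation (documented) that matches what an
analysis-side implementation can know.  Comparisons are only meaningful
between paths sharing the initial condition, frame count and stride;
`select_dominant()` enforces this and breaks ties by the lowest seed.
The Jacobian ($\nabla \cdot F$) term of higher-order discretizations is
deliberately excluded; at fixed endpoints and step count it shifts
weights by amounts that are second order in $\Delta t$, and the cited
dominant-pathway analyses omit it too.  For MC-generated trajectories
the weight ranks paths by their plausibility under an effective Brownian
dynamics of the same frames; this ranking is exactly what the selection
step needs.

## Knot and slipknot detection

Open chains have no knot type until closed.  `classify_conformation()`
votes over `n_closures` (default 100) stochastic closures:

* each terminus leaves along a short random stub whose direction forms
  an angle of more than 90 degrees with the oriented segment from the
  terminus to the C-alpha ten residues inward (no back-turning), with
  directions pointing away from the chain centroid preferred;
* the stub is prolonged radially to three bounding-sphere radii, and the
  two escape points are joined by an arc that stays far outside the
  bounding sphere ("closure at infinity");
* if the two termini are already adjacent (within two bond lengths, e.g.
  a ring analysed as an open chain) the straight chord closes directly —
  the stochastic protocol is for genuinely open chains.

The radial escape is our operationalization of "prolonged far out of the
protein": straight stochastic prolongations frequently thread back
through a lobe of a knotted curve, and on clean fixtures (an ideal
trefoil ring) the vote must be unanimous.  With it, the ideal-trefoil
vote fraction is exactly 1 for every seed, and straight rods and random
coils classify unknotted in >= 99% of closures.

Each ring is then KMT-simplified *as a closed curve* — repeated removal
of vertices whose elimination triangle no other segment pierces, an
exact ambient isotopy — and the Alexander determinant $|\Delta(-1)|$ is
computed from the underpass presentation of a generic projection:
crossings are enumerated with over/under from depth, the $(c-1) \times
(c-1)$ Alexander matrix at $t = -1$ is built (at $t=-1$ the crossing
*sign* drops out, only over/under matters), and the determinant is
evaluated by fraction-free Bareiss elimination over 128-bit integers.
Degenerate projections (parallel segments, crossings at vertices,
depth ties) are detected and retried with a fresh random rotation.

One correctness subtlety found during development: simplifying the
*open* chain before closure — common practice in the literature for deep
protein knots — silently unknots shallow knots, because the open-chain
isotopy may sweep through the terminal gap that the closure arcs later
traverse.  knotfold therefore never pre-reduces the open chain; only the
closed ring is simplified.  The cost is modest at toy scale.

Slipknots are found by re-running the closure vote on subchain windows
of lengths 20, 30, 40, ... (all start offsets, shortest first): a
globally-unknotted chain containing a knotted window is slipknotted, and
the first knotted window is reported as the knotted span.  A verdict
whose modal determinant collects less than 60% of the vote is
"ambiguous" — the majority rule plus a margin, which matters when event
frames are called on noisy trajectories.

## The synthetic world

`build_toy_native()` samples the knotted core along an open arc of a
**fat-torus trefoil** — the $(2,3)$ torus knot on a torus with main
radius $R = 8$ and tube radius $r = 6$ (Angstrom, before rescaling) —
resampled at the C-alpha virtual bond length 3.8 A, with a straight
4-bead N-terminal lead-in and a straight `knot_depth` (default 8) bead
C-terminal tail pointing radially outward.  Design choices that matter:

* the arc is opened at the torus angle where the curve reaches its
  largest radius, i.e. at the "surface": opening a central threading
  strand would destroy the open-chain knot (outside closures then
  correctly unknot it) — the toy would not be a shallow knot at all;
* $R$ and $r$ control strand-strand spacing and hence the native
  contact density: $(8, 6)$ gives 28 contacts at the 7.5 A / $|i-j| \ge
  3$ definition with a minimum non-bonded distance of 3.6 A — compact
  enough to behave like a small globular protein, open enough to avoid
  steric clashes;
* the chain's knot completes a few beads *before* the straight tail
  starts (around bead 35 of 48), so the mechanically relevant threaded
  segment is the last ~14 beads; the knot is removable by retracting
  them, which is what "shallow" means here and what the scripted
  fixtures exploit.

The generator re-verifies global knottedness (determinant 3) at build
time and annotates regions used by the analyses: `tail`, the
`threading_loop` (beads spatially surrounding the threaded segment) and
a two-strand `sheet` with sequence separation ~27, mirroring the early-
pairing antiparallel-sheet motif of real shallow-trefoil proteins.  The
sequence places hydrophobic residues (L) on the sheet strands and
alternating K/E elsewhere, so the non-native quasi-chemical term
actively promotes the sheet's early pairing.

What the toy does **not** emulate: side-chain packing, chirality of real
secondary structure, the true contact density of an 82-residue protein
(ours is ~0.6 contacts per residue against ~2.5), or solvent effects.  A
green end-to-end test therefore establishes that the *machinery* —
bias, sampling, topology detection, selection, statistics — functions
and composes correctly, not that the toy reproduces any particular
protein's kinetics.

`coil_ensemble()` draws self-avoiding random walks (bond length 3.8 A,
non-adjacent clearance 3.5 A), each verified unknotted; `denature()`
emulates thermal unfolding (high-temperature MC with pivot moves, then
local-move thermalization at the target temperature) and guarantees an
unknotted product with native overlap < 0.3, retrying with fresh seeds
otherwise.

### The force field

Bonded terms are anchored at the native geometry: harmonic bonds
(100 kT/A^2) and angles (20 kT/rad^2), 1- and 3-fold cosine dihedrals
(1 and 0.5 kT).  Native contacts get 12-10 wells with minima exactly at
the native distances.  Non-native interactions (mode `"with_nonnative"`)
are a short-range sigmoid well scaled by a quasi-chemical propensity
matrix and Debye-Hueckel electrostatics (Bjerrum length 7 A, screening
length 10 A, charges D/E = -1, K/R = +1, H = 0).  The propensity matrix
is a *synthetic* hydropathy-product stand-in (`quasichemical_matrix()`),
not a published statistical-potential table; any symmetric 20x20 matrix
can be supplied.  Short-range divergences are continued linearly below
0.7 sigma (C^1), so clashed starts produce large but finite forces —
the documented repulsion cap.

Two numerical guards: the 1/sin(theta) factor of the angle gradient is
clamped near collinear geometries (the harmonic angle force stays
bounded; exact elsewhere), and near-collinear dihedrals exert no torque.
Far tails of the quasi-chemical switch, the screened Coulomb term and
the contact function are cut where they fall below ~1e-3 of their scale.
All forces are validated against central finite differences to 1e-4
relative, term by term.

### Stated-world constants of the folding campaign

The desk-scale campaign (10 denatured starts x 5 attempts) uses, and the
vignette records once: `native_eps` = 2 kT (the toy's 28 wells need to
dominate chain entropy at the nominal temperature; 1 kT does not fold
it), quasi-chemical scale 0.5, excluded-volume diameter `sig_ev` =
3.0 A, ratchet `k_R` = 0.1 per CC^2 unit, backtracking
$\tilde\beta = 1$, temperature 1.1, 1.5e6 attempted MC moves per
attempt.  The excluded-volume diameter deserves a note: the toy native's
knot passages are strand gaps of 4-6 A; with a 4 A bead diameter those
passages cost tens of kT and threading never happens at desk scale,
while at 3.0 A they are thermally accessible (a few kT) and chain
*crossing* still costs ~200 kT, so topology changes remain impossible
except by genuine threading.  These constants were fixed from scratch
trajectories before the acceptance tests were written and are not
seed-tuned; the success criterion (some frame globally knotted AND
overlap >= 0.8 reached) mirrors the reference protocol's definition of a
productive knotting trajectory.

## Mechanism classification

At the first globally-knotted frame $f$, with a lookback window $W =
\max(5, 0.05 \cdot \text{frames})$:

* **slipknot** if any frame in the window before $f$ is slipknotted (the
  terminus entered hairpin-bent and straightened later);
* **mousetrap** if, over the window, the mean displacement of the tail
  region stays below 2 bead spacings (7.6 A) while the threading-loop
  region moves more than that (the loop snaps over a stationary,
  docked terminus);
* **threading** otherwise.

Displacements are measured after whole-chain Kabsch superposition of the
window's first frame onto frame $f$.  The thresholds are configuration,
not physics; they are validated against three scripted, piecewise-rigid
kinematic fixtures (no dynamics), one per mechanism, each ending at the
verified knotted toy native — which separates classifier correctness
from sampler stochasticity.

## Pathway similarity

For each trajectory the first-formation frame of every native contact
defines the binary order matrix $M_{ij} = 1$ iff contact $i$ formed no
later than $j$ (ties set both entries; never-formed contacts are
assigned $+\infty$, tied among themselves and flagged).  The similarity

$$\sigma(a, b) = 1 - \frac{\sum_{i \ne j} |M^a_{ij} - M^b_{ij}|}{N_c
(N_c - 1)}$$

is 1 for identical formation order, 0 for exactly reversed strict
order, and depends only on the order — any strictly increasing
reparameterization of time leaves it unchanged (property-tested).  The
distribution of $\sigma$ over all trajectory pairs quantifies pathway
heterogeneity: a folding process with one dominant pathway shows a
narrow, high-$\sigma$ distribution.

## Numerical choices and degenerate inputs

* Alexander determinants use exact integer arithmetic; overflow (never
  observed below ~60 crossings) returns a retry, not a wrong value.
* Exactly coincident ring vertices are deterministically perturbed by
  1e-6 A before projection; persistent projection degeneracy jitters by
  1e-7 A after half the retry budget.
* `update_zm()` treats $\tilde\beta = 0$ as "always accept" and
  $\tilde\beta = \infty$ as "always reject" exactly.
* MC boldness is tuned multiplicatively every 200 attempts during a
  burn-in window toward 50% acceptance, then frozen, so production
  sampling has fixed move sizes.
* All stochastic entry points take a `seed`; child seeds are derived by
  a fixed affine map modulo 2^31 - 1, and every run is bitwise
  reproducible under a fixed seed.

## Known limitations

* The toy's contact set is sparse; overlap is a coarse (1/28-grained)
  coordinate, and near-complete overlap does not imply native geometry
  (which is why the campaign bias uses the all-pair support).
* Path weights on saved frames approximate the continuum action; ranks
  are stable under stride refinement in our checks, but absolute weights
  are not physical probabilities.
* The equilibrium knotting comparison between the native-only and
  non-native model variants uses 24 independent replicates per variant,
  each equilibrated from the native for 6e4 MC moves (with pivot moves,
  which interconvert topology) at temperature 1.6 — just above the
  toy's folding transition, where the knotted fraction is neither 0 nor
  1.  Independent replicates make the binomial error honest; a single
  long trajectory's samples are hysteretic.  It is a directional check
  (the non-native model keeps its knot at least as often), not an
  estimate of the published fractions, which required cluster-scale
  sampling.  At much longer equilibration both variants unfold at this
  temperature; the finite, matched budget is part of the stated world.
* Mechanism thresholds are geometric conventions; on real trajectories
  (as opposed to fixtures) borderline threading/mousetrap calls are
  possible and the evidence fields should be inspected.
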