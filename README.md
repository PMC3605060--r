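# knotfold

Coarse-grained simulation and analysis of how a protein chain ties itself
into its native knot.

About 2% of known protein structures are natively knotted, and how an
unknotted nascent chain threads itself into a trefoil is a question about
the *order* of folding events rather than just the final structure.
knotfold is an R toolkit for studying this at one-bead-per-residue
(C-alpha) resolution, aimed at structural bioinformaticians and polymer /
biophysics researchers who want a self-contained, reproducible desk-scale
pipeline:

* **Ratchet-and-pawl biased dynamics (rMD)** over the contact-map
  collective coordinate
  z(X) = Σ_{i<j} [C_ij(X) − C_ij(X_nat)]², with the smooth contact
  function C(r) = [1 − (r/r₀)⁶]/[1 − (r/r₀)¹⁰], r₀ = 7.5 Å.  The bias
  (k_R/2)(z − z_m)² acts only when z exceeds its running minimum z_m,
  which may backtrack via a Metropolis rule with artificial inverse
  temperature β̃.  Engines: overdamped Langevin (`run_rmd()`) and
  Metropolis Monte Carlo with crankshaft/Cartesian/pivot moves
  (`run_mc()`).
* **Dominant-reaction-pathway (DRP) selection**: trial trajectories are
  scored a posteriori by the discretized Onsager–Machlup log-weight of
  the *unbiased* overdamped dynamics,
  log w = −Σ_t Σ_i |Δx_i − (D Δt/k_BT) F_i|²/(4 D Δt),
  and the highest-weight path per initial condition is retained
  (`path_log_weight()`, `select_dominant()`).
* **Knot & slipknot detection for open chains**: Alexander determinants
  |Δ(−1)| computed by exact integer arithmetic from the underpass
  presentation of a generic projection, after stochastic chain closure
  (100 closures, exit directions at >90° from the terminus→anchor
  segment, arc at infinity), with majority voting, subchain scanning for
  the minimal knotted portion, and slipknot calls
  (`classify_conformation()`, `first_knotting_event()`).
* **Pathway statistics**: the σ similarity between two folding
  mechanisms (fraction of native-contact pairs formed in the same
  order; 1 = identical, 0 = reversed), its distribution over all
  trajectory pairs, overlap at the first knotting event, RMSD-plane
  density projections, and a threading / slipknot / mousetrap mechanism
  classifier validated on scripted kinematic fixtures.
* **A synthetic world**: a generated 48-bead shallow-trefoil toy native
  (fat-torus trefoil core + straight tails), Gō-type force fields with
  optional non-native quasi-chemical + Debye–Hückel terms, denatured
  coil ensembles, and an end-to-end folding campaign — no downloads.

## Worked example

```r
library(knotfold)

# a 48-bead shallow trefoil toy native, verified knotted at build time
nat <- build_toy_native()
nat
#> <native_structure> 48 beads, 28 native contacts, regions: tail,
#>   threading_loop, sheet, sheet_strand_1, sheet_strand_2

classify_conformation(nat$reference, closure_spec(n_closures = 50),
                      scan = c(20, 30, 40), seed = 1)
#> <knot_assignment> globally_knotted (det 3, votes 1.00), span 7-36

# denature, then one ratchet-biased folding attempt (MC engine)
ff <- build_forcefield(nat, mode = "with_nonnative",
                       params = ff_params(native_eps = 2, sig_ev = 3,
                                          qc_matrix = quasichemical_matrix(0.5)))
start <- denature(nat, ff, seed = 11)
tr <- run_mc(start, ff, move_set(), n_moves = 1.5e6, temperature = 1.1,
             seed = 21, save_stride = 15000,
             bias = ratchet_state(k_R = 0.1, beta_tilde = 1),
             native = nat, support = "all")
first_knotting_event(tr, closure_spec(n_closures = 15), seed = 1)
#> [1] NA

# the full campaign: 10 denatured starts x 5 attempts, DRP selection,
# sigma / overlap / mechanism analyses (about 12 min on one CPU)
res <- run_folding_campaign(nat, campaign_config(seed = 42))
res
#> <campaign_result> 50 attempts, 1 knotting successes over 1 starts; 1 selected paths
#> mechanism census:
#>  threading   slipknot  mousetrap unresolved
#>          0          0          1          0
round(res$analysis$overlap_at_first_knot, 2)
#> [1] 0.89
```

The knot assignment reads: all 50 stochastic closures returned
Alexander determinant 3 (a trefoil), and the smallest knotted subchain
spans residues 7–36 — the last 12 residues are a free tail, i.e. the
knot is *shallow*.  The single biased attempt above folds only
partially and never knots (`NA`) — knotting is a rare event, which is
the point: in the seed-42 campaign, 1 of 50 attempts self-ties (at 89%
of native contacts formed, matching the late-knotting phenomenology of
real shallow-trefoil proteins), and the dominant-path selection,
mechanism census and overlap-at-knotting analyses are reported in
`res$manifest` and `res$analysis`.

## Command line

```sh
Rscript inst/cli/knotfold.R make-fixtures --out fixtures --seed 1
Rscript inst/cli/knotfold.R knotscan --traj traj.xyz --every 5 --closures 100
Rscript inst/cli/knotfold.R run-campaign --config config.json --out out
```

Configuration files are JSON; see `?campaign_config`.

## Documentation

The methods vignette (`vignettes/knotfold-methods.Rmd`) explains the
model, the collective coordinate and ratchet, the closure protocol and
its failure modes, the synthetic world's stated constants, and what a
green test does and does not establish.
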