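# Dynamics engines: ratchet-and-pawl biased overdamped Langevin (rMD),
# Metropolis Monte Carlo with crankshaft/Cartesian/pivot moves, and the
# high-temperature denaturation protocol.

#' Ratchet-and-pawl bias state
#'
#' The rMD bias applies no force while the collective coordinate z is at
#' or below its running reference value `z_m`, and a harmonic penalty
#' `(k_R/2) (z - z_m)^2` above it.  `z_m` tracks the running minimum of z
#' but is occasionally allowed to move up (backtracking) via a Metropolis
#' rule controlled by the artificial inverse thermal energy `beta_tilde`.
#'
#' @param k_R ratchet constant (kT per squared collective-coordinate unit).
#' @param beta_tilde artificial inverse thermal energy of the backtracking
#'   Metropolis rule; `Inf` recovers the strictly monotone ratchet, `0`
#'   always accepts backtracking.  Default 4: an uphill move of ~1% of the
#'   toy's initial denatured z is accepted with probability ~0.1.
#' @param z_m initial reference value (default `Inf`: initialized to the
#'   first z encountered).
#' @return list of class `ratchet_state`.
#' @export
ratchet_state <- function(k_R = 0.02, beta_tilde = 4, z_m = Inf) {
  if (k_R < 0) stop("k_R must be >= 0")
  if (beta_tilde < 0) stop("beta_tilde must be >= 0")
  structure(list(k_R = k_R, beta_tilde = beta_tilde, z_m = z_m),
            class = "ratchet_state")
}

#' Ratchet bias potential
#'
#' @param z collective-coordinate value(s).
#' @param state a [ratchet_state()].
#' @return `0` where `z <= z_m`, `(k_R/2)(z - z_m)^2` above; continuous and
#'   C1 at `z = z_m`.
#' @export
bias_potential <- function(z, state) {
  ifelse(z <= state$z_m, 0, 0.5 * state$k_R * (z - state$z_m)^2)
}

#' Metropolis update of the ratchet reference z_m
#'
#' Downhill moves of z always lower `z_m`; uphill moves raise it only when
#' `exp(-beta_tilde (z_t - z_m)) >= u` (backtracking).
#'
#' @param z_t current collective-coordinate value.
#' @param state a [ratchet_state()].
#' @param u uniform random number in `[0, 1)`.
#' @return The new `z_m` value.
#' @export
update_zm <- function(z_t, state, u) {
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  if (z_t <= state$z_m) return(z_t)
  if (is.infinite(state$beta_tilde)) {
    if (u == 0) return(z_t) else return(state$z_m)
  }
  if (exp(-state$beta_tilde * (z_t - state$z_m)) >= u) z_t else state$z_m
}

#' Biased (ratchet-and-pawl) overdamped Langevin dynamics
#'
#' Integrates `x <- x + (D dt / T) F + sqrt(2 D dt) eta` where `F` is the
#' physical force minus the gradient of the ratchet bias potential on the
#' contact-map collective coordinate.  With `k_R = 0` this is plain
#' unbiased overdamped Langevin dynamics.
#'
#' @param start starting [conformation()].
#' @param native a [native_structure()] (defines the collective coordinate).
#' @param ff a [build_forcefield()] object.
#' @param state a [ratchet_state()].
#' @param n_steps number of integration steps.
#' @param dt time step (reduced units).
#' @param temperature temperature in units of the reference temperature.
#' @param seed integer RNG seed (trajectories are bitwise reproducible).
#' @param save_stride store every `save_stride`-th step (frame 0 included).
#' @param D per-bead diffusion coefficient (A^2 per reduced time unit).
#' @param support collective-coordinate support rule, see
#'   [collective_coordinate()].
#' @param debug_check when TRUE, per-step verification that no bias force
#'   is applied while `z <= z_m` (count returned as attribute
#'   `bias_violations`).
#' @return A [trajectory()] with per-frame `cc_value`, `bias_energy` and
#'   `potential_energy`; attributes `zm_trace` and (optionally)
#'   `bias_violations`.
#' @export
run_rmd <- function(start, native, ff, state = ratchet_state(),
                    n_steps = 10000L, dt = 0.01, temperature = 1,
                    seed = NULL, save_stride = 50L, D = 0.1,
                    support = c("native", "all"), debug_check = FALSE) {
  stopifnot(n_steps >= 1L, dt > 0)
  xc <- as_coords(start)
  if (nrow(xc) != ff$spec$n) stop("bead count mismatch")
  sp <- cc_support_pairs(native, match.arg(support))
  p <- native$params
  res <- with_seed(seed, cpp_run_rmd(
    xc, ff$spec, sp$i, sp$j, sp$cnat, p$r0, p$exponents[1], p$exponents[2],
    state$k_R, if (is.infinite(state$beta_tilde)) 1e12 else state$beta_tilde,
    state$z_m, as.integer(n_steps), dt, D, temperature,
    as.integer(save_stride), debug_check))
  if (isTRUE(res$aborted))
    stop("rMD integration blew up (per-step displacement > 5 A); ",
         "reduce dt or check the starting structure")
  ns <- res$n_saved
  n <- nrow(xc)
  arr <- array(t(res$frames[seq_len(ns), , drop = FALSE]), dim = c(3, n, ns))
  arr <- aperm(arr, c(2, 1, 3))
  out <- trajectory(arr, dt = dt * save_stride,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    cc_value = res$cc[seq_len(ns)],
                    bias_energy = res$ebias[seq_len(ns)],
                    potential_energy = res$epot[seq_len(ns)])
  attr(out, "zm_trace") <- res$zm[seq_len(ns)]
  attr(out, "zm_final") <- res$zm_final
  if (debug_check) attr(out, "bias_violations") <- res$violations
  out
}

#' Monte Carlo move set
#'
#' @param crankshaft maximum crankshaft rotation angle (radians).
#' @param cartesian maximum single-bead displacement (Angstrom).
#' @param pivot_enabled include global pivot moves (equilibrium sampling;
#'   pivot moves may pass the chain through itself, so they decorrelate
#'   topology as well as geometry).
#' @param target_acceptance target Metropolis acceptance for the boldness
#'   auto-tuning (default 0.5).
#' @return list of class `move_set`.
#' @export
move_set <- function(crankshaft = 0.6, cartesian = 0.4,
                     pivot_enabled = FALSE, target_acceptance = 0.5) {
  stopifnot(crankshaft > 0, cartesian > 0,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(crankshaft = crankshaft, cartesian = cartesian,
                 pivot_enabled = pivot_enabled,
                 target_acceptance = target_acceptance),
            class = "move_set")
}

#' Metropolis Monte Carlo dynamics
#'
#' Local crankshaft (sub-chain rotation between two beads at sequence gap
#' <= 6) and Cartesian single-bead moves mimic physical chain dynamics;
#' optional global pivot moves give fast equilibrium sampling.  Move
#' boldness is auto-tuned toward the target acceptance during a burn-in
#' window, then frozen.
#'
#' @param start starting [conformation()].
#' @param ff a [build_forcefield()] object.
#' @param moves a [move_set()].
#' @param n_moves number of attempted moves.
#' @param temperature temperature (units of the reference temperature).
#' @param seed RNG seed.
#' @param save_stride save every `save_stride`-th attempted move.
#' @param bias optional [ratchet_state()]: adds the rMD bias on the
#'   contact-map collective coordinate to the Metropolis criterion.
#' @param native required when `bias` is given.
#' @param tune auto-tune boldness during burn-in (default TRUE).
#' @param burn_in number of moves of the tuning window (default
#'   `min(n_moves %/% 5, 20000)`).
#' @param support collective-coordinate support rule for the bias, see
#'   [collective_coordinate()].
#' @return A [trajectory()] with `potential_energy` per saved frame;
#'   attributes `acceptance` (per move type and total) and `boldness`
#'   (tuned maxima).
#' @export
run_mc <- function(start, ff, moves = move_set(), n_moves = 10000L,
                   temperature = 1, seed = NULL, save_stride = 100L,
                   bias = NULL, native = NULL, tune = TRUE,
                   burn_in = NULL, support = c("native", "all")) {
  stopifnot(n_moves >= 1L)
  xc <- as_coords(start)
  if (nrow(xc) != ff$spec$n) stop("bead count mismatch")
  burn_in <- as.integer(burn_in %||% min(n_moves %/% 5L, 20000L))
  bias_on <- !is.null(bias)
  if (bias_on && is.null(native)) stop("bias requires `native`")
  if (bias_on) {
    sp <- cc_support_pairs(native, match.arg(support))
    p <- native$params
    ccargs <- list(sp$i, sp$j, sp$cnat, p$r0, p$exponents[1], p$exponents[2],
                   bias$k_R,
                   if (is.infinite(bias$beta_tilde)) 1e12 else bias$beta_tilde,
                   bias$z_m)
  } else {
    ccargs <- list(integer(0), integer(0), numeric(0), 7.5, 6L, 10L, 0, 0, Inf)
  }
  res <- with_seed(seed, do.call(cpp_run_mc, c(
    list(xc, ff$spec, moves$crankshaft, moves$cartesian, moves$pivot_enabled,
         moves$target_acceptance, tune, burn_in, as.integer(n_moves),
         temperature, as.integer(save_stride), bias_on), ccargs)))
  ns <- nrow(res$frames)
  n <- nrow(xc)
  acc <- c(crankshaft = res$acc_crank, cartesian = res$acc_cart,
           pivot = res$acc_pivot, total = res$acc_total)
  if (isTRUE(tune) && is.finite(res$acc_total) && res$acc_total == 0)
    stop("zero MC acceptance after tuning; check the starting structure")
  arr <- array(t(res$frames), dim = c(3, n, ns))
  arr <- aperm(arr, c(2, 1, 3))
  out <- trajectory(arr, dt = save_stride,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    cc_value = res$cc, potential_energy = res$epot)
  attr(out, "acceptance") <- acc
  attr(out, "boldness") <- c(crankshaft = res$crank_max,
                             cartesian = res$cart_max)
  attr(out, "zm_final") <- res$zm_final
  out
}

#' High-temperature denaturation protocol
#'
#' Emulates thermal unfolding: a high-temperature Monte Carlo run (with
#' pivot moves, for fast decorrelation) followed by thermalization at the
#' target temperature with local moves only.  The result is verified to be
#' globally unknotted and to have native overlap below `max_overlap`;
#' failing draws are retried with fresh seeds.
#'
#' @param native a [native_structure()].
#' @param ff a [build_forcefield()] object.
#' @param t_high,t_eq high and equilibration temperatures (t_high > t_eq).
#' @param n_high_steps,n_eq_steps attempted MC moves in the two stages.
#' @param seed RNG seed.
#' @param max_overlap maximum admissible native overlap (default 0.3).
#' @param closure a [closure_spec()] used for the unknottedness check.
#' @param max_retry retry cap (default 10).
#' @return An unknotted, largely unfolded [conformation()].
#' @export
denature <- function(native, ff, t_high = 6, t_eq = 1,
                     n_high_steps = 20000L, n_eq_steps = 5000L, seed = NULL,
                     max_overlap = 0.3, closure = closure_spec(n_closures = 30),
                     max_retry = 10L) {
  if (t_high <= t_eq) stop("t_high must exceed t_eq")
  if (n_high_steps < 1L)
    stop("n_high_steps must be >= 1 (otherwise the chain stays native)")
  start <- native$reference
  for (try in seq_len(max_retry)) {
    s1 <- child_seed(seed %||% sample.int(2^30, 1), try)
    hot <- run_mc(start, ff, move_set(pivot_enabled = TRUE),
                  n_moves = n_high_steps, temperature = t_high, seed = s1,
                  save_stride = max(1L, as.integer(n_high_steps)))
    cold <- run_mc(get_frame(hot, n_frames(hot)), ff, move_set(),
                   n_moves = n_eq_steps, temperature = t_eq,
                   seed = child_seed(s1, 1L),
                   save_stride = max(1L, as.integer(n_eq_steps)))
    cand <- get_frame(cold, n_frames(cold))
    ov <- native_overlap(cand, native)
    if (ov >= max_overlap) next
    ka <- classify_conformation(cand, spec = closure, scan = NULL,
                                seed = child_seed(s1, 2L))
    if (ka$global_state == "unknot") return(cand)
  }
  stop("denature: retry cap exceeded without an unknotted, unfolded draw")
}
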