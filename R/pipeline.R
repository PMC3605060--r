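# End-to-end orchestration: denature an ensemble, run many rMD folding
# attempts per start, flag knotting trajectories, DRP-select one per
# start, run all analyses; plus the equilibrium-knotting experiment
# comparing the native-only and with-non-native models.

#' Configuration of a folding campaign
#'
#' Defaults describe the desk-scale toy campaign: a 48-bead shallow
#' trefoil, 10 denatured starts with 5 rMD attempts each.
#'
#' @param n_starts number of denatured starting configurations.
#' @param n_attempts folding attempts per start.
#' @param engine `"mc"` (ratchet-biased crankshaft/Cartesian Monte Carlo,
#'   the default: the dynamics the reference CG folding studies used, and
#'   far faster at equal wall time) or `"langevin"` (the overdamped rMD
#'   integrator).
#' @param n_steps integration steps (`engine = "langevin"`) or attempted
#'   MC moves (`engine = "mc"`) per attempt.
#' @param dt Langevin time step (reduced units).
#' @param n_frames saved frames per trajectory.
#' @param temperature run temperature (units of reference temperature).
#' @param D per-bead diffusion coefficient.
#' @param k_R,beta_tilde ratchet constant and backtracking inverse
#'   temperature, see [ratchet_state()].
#' @param support collective-coordinate support of the bias (default
#'   `"all"`: penalizes non-native contacts too, which prevents the
#'   glassy compact traps the sparse toy otherwise falls into).
#' @param mode force-field mode, see [build_forcefield()].
#' @param native_eps,qc_scale,sig_ev stated-world force-field constants
#'   of the toy campaign (see the methods vignette): native well depth
#'   (kT), quasi-chemical scale, excluded-volume diameter (Angstrom).
#' @param success_overlap minimum native overlap a knotted trajectory must
#'   reach to count as successful (default 0.8).
#' @param rmsd_threshold RMSD (Angstrom) below which an unknotted final
#'   frame counts as a near-native unsuccessful trajectory (default 5).
#' @param knot_closures,knot_stride closure count and frame stride of the
#'   per-trajectory knot scans (reduced from the analysis default of 100
#'   closures to keep the campaign desk-scale; the voting logic is
#'   identical).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(n_starts = 10L, n_attempts = 5L,
                            engine = c("mc", "langevin"),
                            n_steps = 1500000L, dt = 0.01,
                            n_frames = 100L,
                            temperature = 1.1, D = 0.1, k_R = 0.1,
                            beta_tilde = 1, support = "all",
                            mode = "with_nonnative",
                            native_eps = 2, qc_scale = 0.5, sig_ev = 3,
                            success_overlap = 0.8, rmsd_threshold = 5,
                            knot_closures = 15L, knot_stride = 1L,
                            seed = 42L) {
  engine <- match.arg(engine)
  structure(as.list(environment()), class = "campaign_config")
}

#' Run a folding campaign on a native structure
#'
#' For each denatured start, runs `n_attempts` rMD trajectories; an
#' attempt is successful when some frame is globally knotted and the
#' trajectory reaches `success_overlap` native overlap.  One successful
#' path per start is retained by dominant-reaction-pathway selection, and
#' the retained ensemble is analysed (path-similarity distribution,
#' overlap at first knotting, RMSD-plane density projection, mechanism
#' census).
#'
#' @param native a [native_structure()] with `tail`, `threading_loop` and
#'   `sheet` regions (e.g. from [build_toy_native()]).
#' @param config a [campaign_config()].
#' @param ff optional pre-built force field (default built from `native`
#'   with `config$mode`).
#' @param verbose print per-stage progress.
#' @return list of class `campaign_result`: `manifest` (counts and
#'   seeds), `selected` (list of winning trajectories), `analysis`
#'   (sigma distribution, overlaps at first knot, density projection,
#'   mechanism census), `unsuccessful_near_native` (indices).
#' @export
run_folding_campaign <- function(native, config = campaign_config(),
                                 ff = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  ff <- ff %||% build_forcefield(
    native, mode = config$mode,
    params = ff_params(native_eps = config$native_eps,
                       sig_ev = config$sig_ev,
                       qc_matrix = quasichemical_matrix(config$qc_scale)))
  kcfg <- closure_spec(n_closures = config$knot_closures)
  state <- ratchet_state(k_R = config$k_R, beta_tilde = config$beta_tilde)
  n_attempted <- 0L; n_knotting <- 0L
  selected <- list(); first_knot <- integer(0)
  starts_with_success <- 0L
  unsuccessful <- list()
  for (s in seq_len(config$n_starts)) {
    seed_s <- child_seed(config$seed, s)
    start <- denature(native, ff, seed = seed_s)
    attempts <- list(); knotting <- list(); kframes <- integer(0)
    for (a in seq_len(config$n_attempts)) {
      seed_a <- child_seed(seed_s, 100L + a)
      if (config$engine == "mc") {
        tr <- run_mc(start, ff, move_set(), n_moves = config$n_steps,
                     temperature = config$temperature, seed = seed_a,
                     save_stride = max(1L, config$n_steps %/% config$n_frames),
                     bias = state, native = native, support = config$support)
      } else {
        tr <- run_rmd(start, native, ff, state, n_steps = config$n_steps,
                      dt = config$dt, temperature = config$temperature,
                      seed = seed_a,
                      save_stride = max(1L, config$n_steps %/% config$n_frames),
                      D = config$D, support = config$support)
      }
      n_attempted <- n_attempted + 1L
      attempts[[a]] <- tr
      ov <- max(vapply(seq_len(n_frames(tr)), function(k)
        native_overlap(tr$coords[, , k], native), numeric(1)))
      # the (costly) full knot scan only matters for candidate successes;
      # other trajectories just need a final-frame verdict
      kf <- NA_integer_
      if (ov >= config$success_overlap)
        kf <- first_knotting_event(tr, spec = kcfg,
                                   seed = child_seed(seed_a, 1L),
                                   stride = config$knot_stride)
      if (!is.na(kf)) {
        n_knotting <- n_knotting + 1L
        knotting[[length(knotting) + 1L]] <- tr
        kframes <- c(kframes, kf)
      } else {
        fin <- get_frame(tr, n_frames(tr))
        fin_rmsd <- kabsch_rmsd(fin, native$reference)
        if (fin_rmsd <= config$rmsd_threshold) {
          ka <- classify_conformation(fin, spec = kcfg, scan = NULL,
                                      seed = child_seed(seed_a, 2L))
          if (ka$global_state != "knotted")
            unsuccessful[[length(unsuccessful) + 1L]] <-
              c(start = s, attempt = a)
        }
      }
    }
    if (length(knotting)) {
      starts_with_success <- starts_with_success + 1L
      # effective diffusion coefficient for the path weights: match the
      # observed per-coordinate frame-to-frame MSD (for the MC engine the
      # move count is not a physical time; this calibrates the Brownian
      # reference dynamics the weights refer to)
      msd <- mean(vapply(knotting, function(tr) {
        nf <- n_frames(tr)
        mean((tr$coords[, , -1, drop = FALSE] -
              tr$coords[, , -nf, drop = FALSE])^2)
      }, numeric(1)))
      D_eff <- max(msd / (2 * knotting[[1]]$dt), 1e-12)
      win <- select_dominant(knotting, ff, D = D_eff,
                             temperature = config$temperature)
      selected[[length(selected) + 1L]] <- win
      first_knot <- c(first_knot, kframes[attr(win, "selected_index")])
    }
    if (verbose)
      message(sprintf("start %d/%d: %d/%d knotting attempts", s,
                      config$n_starts, length(knotting), config$n_attempts))
  }
  # analyses over selected paths
  analysis <- list()
  if (length(selected)) {
    recs <- lapply(seq_along(selected), function(i)
      path_record(selected[[i]], native, trajectory_id = i))
    analysis$sigma <- if (length(recs) >= 2L) sigma_distribution(recs) else NULL
    analysis$overlap_at_first_knot <- vapply(seq_along(selected), function(i)
      native_overlap(get_frame(selected[[i]], first_knot[i]), native),
      numeric(1))
    region <- native$regions$sheet %||% seq_len(min(10L, dim(selected[[1]]$coords)[1]))
    analysis$density <- density_projection(selected, native, region,
                                           knot_frames = first_knot)
    analysis$mechanisms <- vapply(seq_along(selected), function(i)
      classify_mechanism(selected[[i]], native, knot_cfg = kcfg,
                         seed = child_seed(config$seed, 5000L + i),
                         stride = config$knot_stride)$label, character(1))
    analysis$mechanism_census <- table(factor(
      analysis$mechanisms,
      levels = c("threading", "slipknot", "mousetrap", "unresolved")))
  }
  manifest <- list(
    config = config,
    n_attempted = n_attempted,
    n_knotting = n_knotting,
    n_failed = n_attempted - n_knotting,
    starts_with_success = starts_with_success,
    n_selected = length(selected),
    first_knot_frames = first_knot,
    n_unsuccessful_near_native = length(unsuccessful))
  structure(list(manifest = manifest, selected = selected,
                 analysis = analysis,
                 unsuccessful_near_native = unsuccessful),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<campaign_result> %d attempts, %d knotting successes",
                     " over %d starts; %d selected paths\n"),
              m$n_attempted, m$n_knotting, m$starts_with_success,
              m$n_selected))
  if (!is.null(x$analysis$mechanism_census)) {
    cat("mechanism census: ")
    print(x$analysis$mechanism_census)
  }
  invisible(x)
}

#' Equilibrium knotting probability of the two CG model variants
#'
#' For each model variant, runs `n_samples` INDEPENDENT Monte Carlo
#' replicates (local + pivot moves; pivots interconvert topology) of
#' `moves_per_sample` attempted moves each, every replicate equilibrated
#' from the native structure at the given temperature, and reports the
#' fraction of final configurations that are globally knotted with its
#' binomial standard error.  Independent replicates make the binomial
#' error valid, which a single long trajectory (with its strongly
#' correlated, hysteretic samples) does not.  The default temperature
#' sits just above the toy's folding transition, where the knotted
#' fraction is informative; at a fixed equilibration budget the
#' comparison between variants is matched and directional.
#'
#' @param native a [native_structure()].
#' @param modes model variants to compare.
#' @param n_samples independent replicates per variant.
#' @param moves_per_sample attempted MC moves per replicate.
#' @param temperature sampling temperature (units of the reference
#'   temperature; default 1.6, just above the toy's folding transition,
#'   where the knotted fraction is neither 0 nor 1 and the variant
#'   comparison is informative).
#' @param knot_closures closures per knot vote.
#' @param native_eps,qc_scale,sig_ev force-field constants, as in
#'   [campaign_config()].
#' @param seed master seed.
#' @return data.frame with one row per variant: `mode`, `n`, `knotted`,
#'   `fraction`, `se`.
#' @export
run_equilibrium_knotting <- function(native,
                                     modes = c("native_only", "with_nonnative"),
                                     n_samples = 24L,
                                     moves_per_sample = 60000L,
                                     temperature = 1.6,
                                     knot_closures = 15L,
                                     native_eps = 2, qc_scale = 0.5,
                                     sig_ev = 3, seed = 7L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  kcfg <- closure_spec(n_closures = knot_closures)
  pars <- ff_params(native_eps = native_eps, sig_ev = sig_ev,
                    qc_matrix = quasichemical_matrix(qc_scale))
  rows <- lapply(seq_along(modes), function(mi) {
    mode <- modes[mi]
    ff <- build_forcefield(native, mode = mode, params = pars)
    seed_m <- child_seed(seed, mi)
    knotted <- vapply(seq_len(n_samples), function(r) {
      tr <- run_mc(native$reference, ff, move_set(pivot_enabled = TRUE),
                   n_moves = moves_per_sample, temperature = temperature,
                   seed = child_seed(seed_m, r),
                   save_stride = as.integer(moves_per_sample))
      ka <- classify_conformation(get_frame(tr, n_frames(tr)), spec = kcfg,
                                  scan = NULL,
                                  seed = child_seed(seed_m, 100L + r))
      ka$global_state == "knotted"
    }, logical(1))
    n <- length(knotted); p <- mean(knotted)
    data.frame(mode = mode, n = n, knotted = sum(knotted), fraction = p,
               se = sqrt(p * (1 - p) / n))
  })
  do.call(rbind, rows)
}
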