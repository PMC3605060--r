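# A-posteriori dominant-reaction-pathway scoring: relative probability of
# each trial trajectory under the UNBIASED overdamped Langevin dynamics
# (discretized Onsager-Machlup action, Ito convention), and selection of
# the dominant path per initial condition.

#' Onsager-Machlup log-weight of a trajectory
#'
#' The relative log-probability of the path under unbiased overdamped
#' Langevin dynamics,
#' \deqn{\log w = -\sum_t \sum_i \frac{|\Delta x_{t,i} - (D_i \Delta t / k_B T)
#'   F_i(x_t)|^2}{4 D_i \Delta t},}
#' up to a path-independent additive constant.  Forces are the unbiased
#' physical forces evaluated at each step's starting frame; weights are
#' computed on saved frames with `dt` equal to the save interval, and are
#' only comparable among paths sharing endpoints, frame count and stride
#' (enforced by [select_dominant()]).
#'
#' @param t a [trajectory()] with at least 2 frames.
#' @param ff a [build_forcefield()] object.
#' @param D per-bead diffusion coefficient.
#' @param temperature temperature (units of reference temperature).
#' @return list of class `path_weight`: `log_weight`, `n_steps_scored`,
#'   `D`, `temperature`, `dt`, `n_frames`.
#' @export
path_log_weight <- function(t, ff, D = 0.1, temperature = 1) {
  stopifnot(inherits(t, "trajectory"))
  if (n_frames(t) < 2L) stop("need at least 2 frames to score a path")
  if (is.null(t$dt) || !is.finite(t$dt)) stop("trajectory dt is missing")
  n <- dim(t$coords)[1]
  if (n != ff$spec$n) stop("bead count mismatch")
  nf <- n_frames(t)
  fl <- matrix(0, nf, 3 * n)
  for (k in seq_len(nf)) fl[k, ] <- as.numeric(t(t$coords[, , k]))
  lw <- cpp_path_logweight(fl, ff$spec, D, t$dt, temperature)
  structure(list(log_weight = lw, n_steps_scored = nf - 1L, D = D,
                 temperature = temperature, dt = t$dt, n_frames = nf),
            class = "path_weight")
}

#' Select the dominant (highest-weight) path
#'
#' Among trial trajectories sharing one initial condition, returns the one
#' with the highest unbiased-dynamics log-weight; ties are broken by the
#' lowest trajectory seed.
#'
#' @param paths non-empty list of [trajectory()] objects sharing the same
#'   first frame (within `tol`), frame count and dt.
#' @param ff a [build_forcefield()] object.
#' @param D,temperature as in [path_log_weight()].
#' @param tol maximum coordinate deviation between start frames.
#' @return The winning trajectory, with attributes `log_weight` and
#'   `log_weights` (all candidates).
#' @export
select_dominant <- function(paths, ff, D = 0.1, temperature = 1, tol = 1e-6) {
  if (!length(paths)) stop("empty path set")
  x0 <- paths[[1]]$coords[, , 1]
  nf <- n_frames(paths[[1]]); dt <- paths[[1]]$dt
  for (p in paths) {
    if (max(abs(p$coords[, , 1] - x0)) > tol)
      stop("paths do not share the same initial condition")
    if (n_frames(p) != nf || !isTRUE(all.equal(p$dt, dt)))
      stop("paths differ in frame count or stride; weights not comparable")
  }
  lw <- vapply(paths, function(p)
    path_log_weight(p, ff, D, temperature)$log_weight, numeric(1))
  seeds <- vapply(paths, function(p)
    if (is.null(p$seed) || is.na(p$seed)) Inf else as.double(p$seed),
    numeric(1))
  best <- order(-lw, seeds)[1]
  out <- paths[[best]]
  attr(out, "log_weight") <- lw[best]
  attr(out, "log_weights") <- lw
  attr(out, "selected_index") <- best
  out
}

#' Tabular report of a dominant-path selection
#'
#' @inheritParams select_dominant
#' @return data.frame with one row per path: `path_id`, `seed`,
#'   `n_frames`, `log_weight`, `selected`.
#' @export
drp_report <- function(paths, ff, D = 0.1, temperature = 1, tol = 1e-6) {
  win <- select_dominant(paths, ff, D = D, temperature = temperature,
                         tol = tol)
  lw <- attr(win, "log_weights")
  data.frame(
    path_id = seq_along(paths),
    seed = vapply(paths, function(p)
      if (is.null(p$seed)) NA_integer_ else as.integer(p$seed), integer(1)),
    n_frames = vapply(paths, n_frames, integer(1)),
    log_weight = lw,
    selected = seq_along(paths) == attr(win, "selected_index"))
}
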