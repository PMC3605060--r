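# Pathway statistics and mechanism classification: contact-order matrices
# and the sigma similarity, overlap at first knotting, RMSD-plane density
# projections with knotting markers, threading/slipknot/mousetrap calls.

#' Contact-formation order matrix
#'
#' Encodes a folding mechanism as the binary order matrix
#' `M[i, j] = 1` iff contact i formed no later than contact j (ties give
#' both 1; contacts never formed are assigned frame `+Inf`, ranking after
#' all formed ones and tied among themselves).
#'
#' @param frames numeric vector of first-formation frames (NA = never).
#' @return Nc x Nc binary matrix.
#' @export
order_matrix <- function(frames) {
  f <- as.numeric(frames)
  f[is.na(f)] <- Inf
  if (sum(is.finite(f)) < 2L)
    stop("need at least 2 contacts with defined formation frames")
  M <- outer(f, f, `<=`)
  storage.mode(M) <- "integer"
  M
}

#' Per-trajectory path record
#'
#' @param t a [trajectory()].
#' @param native a [native_structure()].
#' @param trajectory_id identifier.
#' @param tol_factor contact tolerance, see [native_overlap()].
#' @return list of class `path_record`: `trajectory_id`,
#'   `formation_frames` (data.frame from [formation_times()]) and
#'   `order_matrix`.
#' @export
path_record <- function(t, native, trajectory_id = NA, tol_factor = 1.2) {
  ft <- formation_times(t, native, tol_factor)
  structure(list(trajectory_id = trajectory_id, formation_frames = ft,
                 order_matrix = order_matrix(ft$formation_frame)),
            class = "path_record")
}

#' Similarity of two folding mechanisms
#'
#' \deqn{\sigma(a, b) = 1 - \frac{\sum_{i \ne j} |M^a_{ij} - M^b_{ij}|}
#'   {N_c (N_c - 1)}} ranges from 0 (exactly reversed strict formation
#' order) to 1 (identical order); it depends only on the order of contact
#' formation, not its timing.
#'
#' @param a,b [path_record()]s over the same native contact set, or bare
#'   order matrices of equal dimension.
#' @return sigma in `[0, 1]`.
#' @export
path_similarity <- function(a, b) {
  Ma <- if (inherits(a, "path_record")) a$order_matrix else a
  Mb <- if (inherits(b, "path_record")) b$order_matrix else b
  if (!all(dim(Ma) == dim(Mb)))
    stop("path records are over different contact sets")
  if (inherits(a, "path_record") && inherits(b, "path_record") &&
      !identical(a$formation_frames[c("i", "j")],
                 b$formation_frames[c("i", "j")]))
    stop("path records are over different contact sets")
  nc <- nrow(Ma)
  1 - (sum(abs(Ma - Mb)) / (nc * (nc - 1)))
}

#' Distribution of pairwise path similarities
#'
#' @param paths list of >= 2 [path_record()]s.
#' @param breaks histogram breaks over `[0, 1]` (default 20 equal bins).
#' @return list: `sigma` (all `n(n-1)/2` pairwise values), `histogram`
#'   (density-normalized counts), `breaks`.
#' @export
sigma_distribution <- function(paths, breaks = seq(0, 1, by = 0.05)) {
  if (length(paths) < 2L) stop("need at least 2 paths")
  n <- length(paths)
  sig <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      sig <- c(sig, path_similarity(paths[[i]], paths[[j]]))
  h <- graphics::hist(sig, breaks = breaks, plot = FALSE)
  list(sigma = sig, histogram = h$density, breaks = breaks)
}

#' Native-contact overlap at the first knotting event
#'
#' @param t a [trajectory()].
#' @param native a [native_structure()].
#' @param knot_cfg a [closure_spec()].
#' @param seed RNG seed for the knot scan.
#' @param stride frame stride of the knot scan.
#' @return Overlap fraction at the first globally-knotted frame, or `NA`
#'   if the trajectory never knots.
#' @export
overlap_at_first_knot <- function(t, native, knot_cfg = closure_spec(),
                                  seed = NULL, stride = 1L) {
  k <- first_knotting_event(t, spec = knot_cfg, seed = seed, stride = stride)
  if (is.na(k)) return(NA_real_)
  native_overlap(get_frame(t, k), native)
}

#' Density projection on the (total RMSD, region RMSD) plane
#'
#' Bins every frame of every trajectory by its RMSD to the native
#' structure (x) and the RMSD of a region (e.g. the beta-sheet) to its
#' native geometry (y), in analogy with free-energy landscape plots;
#' the grid holds `log(1 + visits)`.
#'
#' @param paths list of [trajectory()]s.
#' @param native a [native_structure()].
#' @param region integer vector (>= 3 beads) defining the y-axis RMSD.
#' @param bins number of bins per axis (default 30).
#' @param knot_frames optional per-trajectory first-knot frame indices
#'   (NA allowed); marked points are returned in `knot_markers`.
#' @return list of class `density_projection`: `x_edges`, `y_edges`,
#'   `log_counts` (matrix), `knot_markers` (two-column matrix).
#' @export
density_projection <- function(paths, native, region, bins = 30,
                               knot_frames = NULL) {
  if (!length(paths)) stop("empty path set")
  if (length(region) < 3L) stop("region must contain at least 3 beads")
  ref <- native$reference
  xs <- ys <- numeric(0)
  markers <- NULL
  for (pi in seq_along(paths)) {
    t <- paths[[pi]]
    for (k in seq_len(n_frames(t))) {
      fr <- t$coords[, , k]
      xs <- c(xs, kabsch_rmsd(fr, ref))
      ys <- c(ys, kabsch_rmsd(fr, ref, subset = region))
    }
    if (!is.null(knot_frames) && !is.na(knot_frames[pi])) {
      fr <- t$coords[, , knot_frames[pi]]
      markers <- rbind(markers, c(kabsch_rmsd(fr, ref),
                                  kabsch_rmsd(fr, ref, subset = region)))
    }
  }
  xe <- seq(0, max(xs) * 1.0001 + 1e-9, length.out = bins + 1)
  ye <- seq(0, max(ys) * 1.0001 + 1e-9, length.out = bins + 1)
  cnt <- matrix(0, bins, bins)
  ix <- pmin(bins, findInterval(xs, xe, rightmost.closed = TRUE))
  iy <- pmin(bins, findInterval(ys, ye, rightmost.closed = TRUE))
  for (k in seq_along(ix)) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  structure(list(x_edges = xe, y_edges = ye, log_counts = log1p(cnt),
                 knot_markers = markers),
            class = "density_projection")
}

#' Classify the knotting mechanism of a trajectory
#'
#' Operational rules, applied at the first globally-knotted frame f with a
#' lookback window W (`max(lookback_min, lookback_frac * n_frames)`):
#' * **slipknot** - some frame in the window before f is slipknotted
#'   (a knotted subchain inside a globally-unknotted chain: the terminus
#'   entered hairpin-bent and straightened later);
#' * **mousetrap** - over the window the terminal segment stays put
#'   (mean displacement below `disp_threshold`) while the loop region
#'   moves more than the threshold (the loop swings over a stationary,
#'   already-docked terminus);
#' * **threading** - otherwise (the terminus passes through the open
#'   region).
#' Displacements are measured after whole-chain superposition of the
#' window's first frame onto frame f.  Requires `tail` and
#' `threading_loop` regions on the native structure.
#'
#' @param t a [trajectory()].
#' @param native a [native_structure()] with `tail` and `threading_loop`
#'   regions.
#' @param knot_cfg a [closure_spec()].
#' @param seed RNG seed for the knot scans.
#' @param scan subchain-length schedule for slipknot detection.
#' @param lookback_frac,lookback_min lookback window, as a fraction of the
#'   frame count and a floor (defaults 0.05 and 5 frames).
#' @param disp_threshold displacement threshold in Angstrom (default 7.6,
#'   twice the bead spacing).
#' @param stride frame stride of the first-knot scan.
#' @return list of class `mechanism_call`: `label` (`"threading" |
#'   "slipknot" | "mousetrap" | "unresolved"`) and `evidence`.
#' @export
classify_mechanism <- function(t, native, knot_cfg = closure_spec(),
                               seed = NULL, scan = c(20, 30, 40),
                               lookback_frac = 0.05, lookback_min = 5L,
                               disp_threshold = 7.6, stride = 1L) {
  f <- first_knotting_event(t, spec = knot_cfg, seed = seed, stride = stride)
  if (is.na(f)) {
    return(structure(list(label = "unresolved",
                          evidence = list(first_knot_frame = NA_integer_)),
                     class = "mechanism_call"))
  }
  W <- max(as.integer(lookback_min), ceiling(lookback_frac * n_frames(t)))
  f0 <- max(1L, f - W)
  slipknot_prior <- FALSE
  if (f > 1L) {
    for (k in seq(f - 1L, f0)) {
      ka <- classify_conformation(t$coords[, , k], spec = knot_cfg,
                                  scan = scan, seed = child_seed(seed, 7000L + k))
      if (ka$classification == "slipknotted") { slipknot_prior <- TRUE; break }
    }
  }
  tailr <- native$regions$tail
  loopr <- native$regions$threading_loop
  if (is.null(tailr) || is.null(loopr))
    stop("native structure needs 'tail' and 'threading_loop' regions")
  a <- t$coords[, , f0]; b <- t$coords[, , f]
  # superpose a onto b (whole chain), then region displacements
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  rot <- kabsch_rotation(cb, ca) # rotates ca onto cb
  disp <- sqrt(rowSums((ca %*% rot - cb)^2))
  tail_disp <- mean(disp[tailr]); loop_disp <- mean(disp[loopr])
  label <- if (slipknot_prior) "slipknot"
           else if (tail_disp < disp_threshold && loop_disp >= disp_threshold)
             "mousetrap"
           else "threading"
  structure(list(label = label,
                 evidence = list(first_knot_frame = f,
                                 slipknot_prior = slipknot_prior,
                                 tail_displacement = tail_disp,
                                 loop_displacement = loop_disp,
                                 window = c(f0, f))),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (first knot frame %s)\n", x$label,
              format(x$evidence$first_knot_frame)))
  invisible(x)
}
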