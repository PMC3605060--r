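# Synthetic inputs: parametric knotted curves, the open-chain shallow
# trefoil toy native, denatured coil ensembles, and scripted kinematic
# fixtures for the mechanism classifier.  Everything is generated in code;
# no external structure files are required.

# unit parametric curves ----------------------------------------------------

trefoil_curve <- function(t) {
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
}
# (2,3) torus knot on a fat torus: tunable main radius R and tube radius r
# control the strand-strand spacing, hence the native contact density of
# the toy chain sampled along it.
torus_trefoil_curve <- function(phi, R, r) {
  cbind((R + r * cos(3 * phi)) * cos(2 * phi),
        (R + r * cos(3 * phi)) * sin(2 * phi),
        r * sin(3 * phi))
}
figure_eight_curve <- function(t) {
  cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
}

#' Closed parametric knotted curves
#'
#' Polygonal closed curves of known knot type, used as exact oracles for
#' the knot detector: unknot (circle, Alexander determinant 1), trefoil
#' (determinant 3) and figure-eight knot (determinant 5).
#'
#' @param kind `"unknot"`, `"trefoil"` or `"figure_eight"`.
#' @param n_vertices number of polygon vertices (>= 3 for the unknot,
#'   >= 30 otherwise, so the polygonalization preserves the knot type).
#' @param scale overall scale factor.
#' @return `n_vertices` x 3 matrix of ring vertices.
#' @export
parametric_knot <- function(kind = c("unknot", "trefoil", "figure_eight"),
                            n_vertices = 60L, scale = 1) {
  kind <- match.arg(kind)
  n_vertices <- as.integer(n_vertices)
  min_n <- if (kind == "unknot") 3L else 30L
  if (n_vertices < min_n)
    stop(sprintf("%s needs at least %d vertices", kind, min_n))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  scale * switch(kind,
                 unknot = cbind(cos(t), sin(t), 0 * t),
                 trefoil = trefoil_curve(t),
                 figure_eight = figure_eight_curve(t))
}

# Resample a finely-discretized curve at equal arclength spacing.
resample_arclength <- function(pts, n_out, spacing = NULL) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- if (is.null(spacing)) seq(0, total, length.out = n_out)
            else seq(0, by = spacing, length.out = n_out)
  if (max(target) > total + 1e-9) stop("curve too short for requested beads")
  t(vapply(target, function(si) {
    k <- max(1L, findInterval(si, s, rightmost.closed = TRUE))
    k <- min(k, nrow(pts) - 1L)
    w <- (si - s[k]) / max(s[k + 1] - s[k], 1e-12)
    pts[k, ] * (1 - w) + pts[k + 1, ] * w
  }, numeric(3)))
}

#' Specification of the toy shallow-trefoil native structure
#'
#' @param n_beads chain length (default 48).
#' @param bead_spacing consecutive-bead distance in Angstrom (default 3.8,
#'   the C-alpha virtual bond length).
#' @param knot_depth number of C-terminal tail beads beyond the knotted
#'   core (default 8); must be >= 1 (a knot with no tail to thread cannot
#'   be built by threading).
#' @param n_tail_n straight N-terminal lead-in beads (default 4).
#' @param gap angular gap (radians of torus angle) left open in the
#'   parametric trefoil (default 0.45; smaller = deeper knot).
#' @param torus_R,torus_r main and tube radii of the fat-torus trefoil
#'   before rescaling (defaults 8 and 6: compact core, native contact
#'   density comparable to a small globular protein).
#' @param seed RNG seed for the structural jitter.
#' @return list of class `toy_native_spec`.
#' @export
toy_native_spec <- function(n_beads = 48L, bead_spacing = 3.8,
                            knot_depth = 8L, n_tail_n = 4L, gap = 0.45,
                            torus_R = 8, torus_r = 6, seed = 1L) {
  if (knot_depth < 1L) stop("knot_depth must be >= 1 (no tail to thread)")
  if (n_beads < 30L) stop("toy native needs at least 30 beads")
  structure(list(n_beads = as.integer(n_beads), bead_spacing = bead_spacing,
                 knot_depth = as.integer(knot_depth),
                 n_tail_n = as.integer(n_tail_n), gap = gap,
                 torus_R = torus_R, torus_r = torus_r,
                 seed = as.integer(seed)),
            class = "toy_native_spec")
}

#' Build the toy shallow-trefoil native structure
#'
#' Samples the knotted core along an open arc of the parametric trefoil
#' (scaled so beads sit at `bead_spacing`), prepends a short straight
#' N-terminal lead-in and appends a straight C-terminal tail of
#' `knot_depth` beads along the outward radial direction, giving a
#' shallow trefoil whose knot is removable by retracting the tail.  The
#' result is verified to be globally knotted with determinant 3.
#' Geometric annotations are attached as regions: `tail` (the C-terminal
#' threaded segment), `threading_loop` (the beads surrounding the tail's
#' crossing) and `sheet` (two early-pairing strands with large sequence
#' separation, mirroring an antiparallel beta-sheet), plus a hydrophobic
#' sequence pattern on the sheet strands.
#'
#' @param spec a [toy_native_spec()].
#' @param verify verify global knottedness (default TRUE).
#' @param closure a [closure_spec()] for the verification vote.
#' @return A [native_structure()] with regions and sequence set.
#' @export
build_toy_native <- function(spec = toy_native_spec(), verify = TRUE,
                             closure = closure_spec(n_closures = 40)) {
  stopifnot(inherits(spec, "toy_native_spec"))
  n <- spec$n_beads; d <- spec$knot_depth; ntn <- spec$n_tail_n
  n_core <- n - d - ntn
  if (n_core < 20L) stop("too few core beads for a trefoil arc")
  # The gap is centered at phi = 0, where the fat-torus trefoil reaches
  # its largest radius (R + r): opening the curve at an outer lobe (the
  # "surface") leaves a shallow knot, whereas opening a central threading
  # strand would destroy the open-chain knot altogether.
  tt <- seq(spec$gap / 2, 2 * pi - spec$gap / 2, length.out = 3000)
  fine <- torus_trefoil_curve(tt, spec$torus_R, spec$torus_r)
  seg <- sqrt(rowSums(diff(fine)^2))
  unit_len <- sum(seg)
  scale <- (n_core - 1) * spec$bead_spacing / unit_len
  core <- resample_arclength(fine * scale, n_core,
                             spacing = spec$bead_spacing)
  ctr <- colMeans(core)
  # N-terminal lead-in: straight, radially outward from the arc start
  dirN <- unitize(core[1, ] - ctr)
  leadin <- t(vapply(rev(seq_len(ntn)), function(k)
    core[1, ] + k * spec$bead_spacing * dirN, numeric(3)))
  # C-terminal tail: straight, radially outward from the arc end
  dirC <- unitize(core[n_core, ] - ctr)
  tail_beads <- t(vapply(seq_len(d), function(k)
    core[n_core, ] + k * spec$bead_spacing * dirC, numeric(3)))
  coords <- rbind(leadin, core, tail_beads)
  coords <- with_seed(spec$seed,
                      coords + matrix(stats::rnorm(length(coords), sd = 0.05),
                                      ncol = 3))
  # clash check (non-adjacent beads)
  dmat <- as.matrix(stats::dist(coords))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  if (min(dmat[sep >= 2]) < 3.2)
    stop("toy native has steric clashes; adjust gap or bead count")
  conf <- conformation(coords)
  # regions ------------------------------------------------------------
  tail_region <- (n - d + 1L):n
  # threaded segment: last few core beads + tail entry; the loop is the
  # set of mid-chain beads spatially close to the threaded segment.
  attach <- n - d
  dist_to_attach <- sqrt(rowSums(sweep(coords, 2, coords[attach, ])^2))
  cand <- which(dist_to_attach < 10 &
                seq_len(n) >= ntn + 2L & seq_len(n) <= attach - 6L)
  if (!length(cand)) cand <- (ntn + 8L):(ntn + 16L)
  loop_region <- max(min(cand), 1L):min(max(cand), attach - 6L)
  if (length(loop_region) > 16L) {
    mid <- round(mean(loop_region))
    loop_region <- max(min(loop_region), mid - 8L):min(max(loop_region), mid + 7L)
  }
  # sheet: the native contact with the largest sequence separation whose
  # partners both lie outside the tail
  params <- contact_map_params()
  nat0 <- native_structure(conf, params = params)
  nc <- nat0$native_contacts
  ok <- nc[, 2] <= attach
  pick <- nc[ok, , drop = FALSE]
  pick <- pick[which.max(pick[, 2] - pick[, 1]), ]
  sheet1 <- max(1L, pick[1] - 2L):min(n, pick[1] + 2L)
  sheet2 <- max(1L, pick[2] - 2L):min(n, pick[2] + 2L)
  # sequence: hydrophobic (L) sheet strands, alternating charges on a
  # neutral background
  seqv <- rep("A", n)
  seqv[seq(3L, n, by = 5L)] <- "K"
  seqv[seq(5L, n, by = 5L)] <- "E"
  seqv[c(sheet1, sheet2)] <- "L"
  regions <- list(tail = tail_region, threading_loop = loop_region,
                  sheet = sort(unique(c(sheet1, sheet2))),
                  sheet_strand_1 = sheet1, sheet_strand_2 = sheet2)
  nat <- native_structure(conf, params = params, regions = regions,
                          sequence = paste(seqv, collapse = ""))
  if (verify) {
    ka <- classify_conformation(conf, spec = closure, scan = NULL,
                                seed = child_seed(spec$seed, 99L))
    if (ka$classification != "globally_knotted" || ka$knot_determinant != 3L)
      stop("toy native failed knot verification (got ", ka$classification,
           ", det ", ka$knot_determinant, ")")
  }
  attr(nat, "toy_spec") <- spec
  nat
}

#' Denatured coil ensemble (self-avoiding random walks)
#'
#' Generates `n_chains` self-avoiding random walks with fixed bond length,
#' each verified globally unknotted under a stochastic-closure majority
#' vote; knotted draws (rare at these lengths) are resampled.
#'
#' @param n_chains number of chains.
#' @param n_beads beads per chain.
#' @param bead_spacing bond length (Angstrom).
#' @param seed RNG seed.
#' @param min_dist self-avoidance distance for non-adjacent beads
#'   (default 3.5 Angstrom).
#' @param closure a [closure_spec()] for the unknottedness check.
#' @return list of [conformation()]s.
#' @export
coil_ensemble <- function(n_chains, n_beads = 48L, bead_spacing = 3.8,
                          seed = NULL, min_dist = 3.5,
                          closure = closure_spec(n_closures = 20)) {
  stopifnot(n_chains >= 1L)
  out <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    s <- child_seed(seed %||% sample.int(2^30, 1), ch)
    out[[ch]] <- with_seed(s, {
      repeat {
        x <- saw_chain(n_beads, bead_spacing, min_dist)
        if (is.null(x)) next
        ka <- closure_vote(x, closure, seed = NULL)
        if (ka$det == 1L && ka$vote_fraction >= 0.6) break
      }
      conformation(x)
    })
  }
  out
}

# One self-avoiding walk attempt; NULL on dead end.  Uses current RNG.
saw_chain <- function(n_beads, b, min_dist) {
  x <- matrix(0, n_beads, 3)
  x[2, ] <- c(b, 0, 0)
  for (k in 3:n_beads) {
    placed <- FALSE
    for (try in 1:100) {
      d <- random_unit_vector()
      cand <- x[k - 1, ] + b * d
      prev <- x[1:(k - 2), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_dist) {
        x[k, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) return(NULL)
  }
  x
}

#' Scripted kinematic fixtures for the mechanism classifier
#'
#' Piecewise-rigid scripted motions (no dynamics) that end in the globally
#' knotted toy native and carry the geometric signature of one knotting
#' mechanism:
#' * `threading`: the straight tail translates from a pulled-out,
#'   unknotted pose through the open loop region into its native pose;
#' * `slipknot`: the tail first enters hairpin-bent (producing frames
#'   that are globally unknotted but contain a knotted subchain), then
#'   straightens into the native pose;
#' * `mousetrap`: the tail sits in its native (docked) pose throughout
#'   while the loop region crankshafts over it from an unknotted start.
#'
#' @param kind `"threading"`, `"slipknot"` or `"mousetrap"`.
#' @param n_frames number of frames (>= 10).
#' @param native optional toy [native_structure()] built by
#'   [build_toy_native()]; default builds one with default spec.
#' @return A [trajectory()] whose final frame is the toy native; attribute
#'   `native` carries the native structure used.
#' @export
kinematic_fixture <- function(kind = c("threading", "slipknot", "mousetrap"),
                              n_frames = 30L, native = NULL) {
  kind <- match.arg(kind)
  n_frames <- as.integer(n_frames)
  if (n_frames < 10L) stop("n_frames must be >= 10")
  native <- native %||% build_toy_native(verify = FALSE)
  spec <- attr(native, "toy_spec")
  x_nat <- native$reference$coords
  n <- nrow(x_nat)
  b <- spec$bead_spacing
  # the moving piece: the threaded C-terminal segment.  The knot of the
  # toy native completes a few beads before the straight tail starts, so
  # the mover must reach past the final passage (knot_depth + 6 beads);
  # verified below by requiring the pulled-out start to be unknotted.
  m <- spec$knot_depth + 6L
  vote <- function(xc) closure_vote(xc, closure_spec(n_closures = 20),
                                    seed = child_seed(spec$seed, 31L))
  pulled_pose <- function(m) {
    attach <- n - m
    ctr <- colMeans(x_nat[1:attach, ])
    u_out <- unitize(x_nat[attach, ] - ctr)
    t(vapply(seq_len(m), function(k)
      x_nat[attach, ] + k * b * u_out, numeric(3)))
  }
  if (kind %in% c("threading", "slipknot")) {
    ok <- FALSE
    for (mm in seq(m, m + 12L, by = 2L)) {
      start <- x_nat; start[(n - mm + 1L):n, ] <- pulled_pose(mm)
      v <- vote(start)
      if (v$det == 1L && v$vote_fraction >= 0.8) { m <- mm; ok <- TRUE; break }
    }
    if (!ok) stop("kinematic_fixture: could not build an unknotted start")
  }
  mover <- (n - m + 1L):n
  attach <- n - m
  pulled <- pulled_pose(m)
  frames <- array(rep(x_nat, n_frames), dim = c(n, 3, n_frames))
  lin <- function(a, bb, s) (1 - s) * a + s * bb
  if (kind == "threading") {
    for (j in seq_len(n_frames)) {
      s <- (j - 1) / (n_frames - 1)
      frames[mover, , j] <- lin(pulled, x_nat[mover, , drop = FALSE], s)
    }
  } else if (kind == "mousetrap") {
    loopr <- native$regions$threading_loop
    h1 <- min(loopr) - 1L; h2 <- max(loopr) + 1L
    axis <- x_nat[h2, ] - x_nat[h1, ]
    movers <- (h1 + 1L):(h2 - 1L)
    ok <- FALSE
    for (ang0 in c(2.7, -2.7, 2.2, -2.2, 1.7, -1.7)) {
      start <- x_nat
      start[movers, ] <- rotate_about_axis(x_nat[movers, , drop = FALSE],
                                           axis, ang0, origin = x_nat[h1, ])
      v <- vote(start)
      if (v$det == 1L && v$vote_fraction >= 0.8) { ok <- TRUE; break }
    }
    if (!ok) stop("kinematic_fixture: no unknotting loop rotation found")
    # the swing completes within the first quarter of the frames (the
    # mousetrap snap is fast), then the chain holds the native pose
    rot_frames <- max(5L, ceiling(0.2 * n_frames))
    for (j in seq_len(n_frames)) {
      s <- min(1, (j - 1) / (rot_frames - 1))
      frames[movers, , j] <- rotate_about_axis(
        x_nat[movers, , drop = FALSE], axis, (1 - s) * ang0,
        origin = x_nat[h1, ])
    }
  } else { # slipknot
    # hairpin pose: the leading part of the mover sits on its native
    # (threaded) path, the last beads double back out of the passage
    # along a laterally-offset retrace, so the chain up to the apex is
    # knotted while the full chain is not.
    n_back <- max(4L, m %/% 2L)
    n_in <- m - n_back
    hairpin <- matrix(0, m, 3)
    hairpin[seq_len(n_in), ] <- x_nat[attach + seq_len(n_in), , drop = FALSE]
    apex <- attach + n_in
    u_out <- unitize(x_nat[attach, ] - colMeans(x_nat[1:attach, ]))
    off <- 3 * unitize(pracma_cross(u_out, x_nat[apex, ] - x_nat[attach, ]))
    for (k in seq_len(n_back)) {
      src <- max(1L, apex - 2L * k)
      hairpin[n_in + k, ] <- x_nat[src, ] + off
    }
    a_frames <- ceiling(0.6 * n_frames)
    for (j in seq_len(n_frames)) {
      if (j <= a_frames) {
        s <- (j - 1) / (a_frames - 1)
        frames[mover, , j] <- lin(pulled, hairpin, s)
      } else {
        s <- (j - a_frames) / (n_frames - a_frames)
        frames[mover, , j] <- lin(hairpin, x_nat[mover, , drop = FALSE], s)
      }
    }
  }
  out <- trajectory(frames, dt = 1, seed = spec$seed)
  attr(out, "native") <- native
  attr(out, "mover") <- mover
  out
}
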