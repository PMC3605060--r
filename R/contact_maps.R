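# Smooth contact function, contact maps, the contact-map collective
# coordinate z(X), native overlap and contact formation times.

#' Parameters of the smooth contact map
#'
#' The contact function is the rational switching form
#' \deqn{C(r) = \frac{1 - (r/r_0)^p}{1 - (r/r_0)^q},}
#' which interpolates smoothly between 1 (r -> 0) and 0 (r -> infinity);
#' the removable singularity at r = r0 is evaluated by its limit p/q.
#'
#' @param r0 reference distance in Angstrom (default 7.5).
#' @param min_seq_sep minimum sequence separation |i - j| of counted pairs.
#' @param exponents integer pair (p, q) with p < q; default c(6, 10).
#' @param support_threshold pairs enter the collective-coordinate sum when
#'   their native (or, in `"all"` support mode, any) contact-function value
#'   exceeds this threshold (default 0.01).
#' @return An object of class `contact_map_params`.
#' @export
contact_map_params <- function(r0 = 7.5, min_seq_sep = 3L,
                               exponents = c(6L, 10L),
                               support_threshold = 0.01) {
  stopifnot_scalar(r0, "r0", positive = TRUE)
  min_seq_sep <- as.integer(min_seq_sep)
  if (min_seq_sep < 1L) stop("min_seq_sep must be >= 1")
  exponents <- as.integer(exponents)
  if (length(exponents) != 2L || any(exponents <= 0L) ||
      exponents[1] >= exponents[2])
    stop("exponents must be two positive integers (p, q) with p < q")
  structure(list(r0 = r0, min_seq_sep = min_seq_sep, exponents = exponents,
                 support_threshold = support_threshold),
            class = "contact_map_params")
}

#' Smooth contact function
#'
#' @param r distances (Angstrom), vectorized.
#' @param params a [contact_map_params()].
#' @return Values in `[0, 1]`, monotonically non-increasing in `r`.
#' @export
contact_value <- function(r, params = contact_map_params()) {
  if (any(r < 0)) stop("distances must be non-negative")
  p <- params$exponents[1]; q <- params$exponents[2]
  s <- r / params$r0
  out <- numeric(length(s))
  near <- abs(s - 1) < 1e-4
  # removable singularity: C -> p/q, with slope p(p - q) / (2 q) in s
  out[near] <- p / q + (p * (p - q)) / (2 * q) * (s[near] - 1)
  sp <- s[!near]
  out[!near] <- (1 - sp^p) / (1 - sp^q)
  dim(out) <- dim(r)
  out
}

#' Instantaneous smooth contact map of a conformation
#'
#' @param x a [conformation()] (or N x 3 matrix).
#' @param params a [contact_map_params()].
#' @return Symmetric N x N matrix of contact-function values, zero on the
#'   excluded near-diagonal band.
#' @export
contact_map <- function(x, params = contact_map_params()) {
  xc <- as_coords(x)
  n <- nrow(xc)
  dmat <- as.matrix(stats::dist(xc))
  cm <- contact_value(dmat, params)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  cm[sep < params$min_seq_sep] <- 0
  diag(cm) <- 0
  cm
}

# Pairs entering the collective-coordinate sum, as a 0-based integer matrix
# plus the native contact-function values.  support = "native": pairs whose
# native map value exceeds the support threshold (the default, giving a
# fixed sparse support); "all": every pair with |i - j| >= min_seq_sep.
cc_support_pairs <- function(native, support = c("native", "all")) {
  support <- match.arg(support)
  n <- nrow(native$reference$coords)
  p <- native$params
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  keep <- upper.tri(sep) & sep >= p$min_seq_sep
  if (support == "native") keep <- keep & native$native_map > p$support_threshold
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(i = as.integer(idx[, 1] - 1L), j = as.integer(idx[, 2] - 1L),
       cnat = native$native_map[idx])
}

#' Contact-map collective coordinate z(X)
#'
#' Squared distance between the instantaneous and native smooth contact
#' maps, summed over the (upper-triangle) support pairs:
#' \deqn{z(X) = \sum_{i<j} [C_{ij}(X) - C_{ij}(X_{native})]^2 .}
#'
#' @param x a [conformation()] with the same bead count as the native.
#' @param native a [native_structure()].
#' @param support `"native"` (default) restricts the sum to pairs in
#'   contact in the native map; `"all"` uses every pair with sufficient
#'   sequence separation.
#' @return Non-negative scalar; zero iff the instantaneous map equals the
#'   native map on the support.
#' @export
collective_coordinate <- function(x, native, support = c("native", "all")) {
  xc <- as_coords(x)
  if (nrow(xc) != nrow(native$reference$coords))
    stop("conformation and native structure differ in bead count")
  sp <- cc_support_pairs(native, match.arg(support))
  p <- native$params
  cpp_cc(xc, sp$i, sp$j, sp$cnat, p$r0, p$exponents[1], p$exponents[2], FALSE)$z
}

#' Fraction of native contacts formed (overlap)
#'
#' A native contact (i, j) counts as formed when the instantaneous bead
#' distance does not exceed `tol_factor` times its native distance.
#'
#' @param x a [conformation()].
#' @param native a [native_structure()].
#' @param tol_factor tolerance factor >= 1 (default 1.2, the standard
#'   Go-model convention).
#' @return Fraction in `[0, 1]`.
#' @export
native_overlap <- function(x, native, tol_factor = 1.2) {
  if (tol_factor < 1) stop("tol_factor must be >= 1")
  nc <- native$native_contacts
  if (!nrow(nc)) stop("native structure has an empty contact set")
  xc <- as_coords(x)
  ref <- native$reference$coords
  di <- sqrt(rowSums((xc[nc[, 1], , drop = FALSE] - xc[nc[, 2], , drop = FALSE])^2))
  dn <- sqrt(rowSums((ref[nc[, 1], , drop = FALSE] - ref[nc[, 2], , drop = FALSE])^2))
  mean(di <= tol_factor * dn)
}

#' Export a contact map as text
#'
#' @param map symmetric contact-map matrix (e.g. from [contact_map()]).
#' @param path output path.
#' @param format `"dense"` (whitespace-separated matrix) or `"sparse"`
#'   (TSV of `i`, `j`, `value` for the upper-triangle entries above
#'   `threshold`).
#' @param threshold sparse-export threshold (default 0.01).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "sparse"),
                              threshold = 0.01) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(format(map, digits = 6), path, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(map) & map > threshold, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], value = map[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(path)
}

#' First-formation frame of each native contact along a trajectory
#'
#' @param t a [trajectory()].
#' @param native a [native_structure()].
#' @param tol_factor contact tolerance as in [native_overlap()].
#' @return data.frame with columns `i`, `j` (1-based residue indices) and
#'   `formation_frame`: the first frame (1-based) where the contact
#'   predicate holds, `NA` if never formed.
#' @export
formation_times <- function(t, native, tol_factor = 1.2) {
  stopifnot(inherits(t, "trajectory"))
  if (n_frames(t) < 1L) stop("trajectory is empty")
  nc <- native$native_contacts
  ref <- native$reference$coords
  dn <- sqrt(rowSums((ref[nc[, 1], , drop = FALSE] - ref[nc[, 2], , drop = FALSE])^2))
  thr <- tol_factor * dn
  formed <- rep(NA_integer_, nrow(nc))
  for (k in seq_len(n_frames(t))) {
    open <- is.na(formed)
    if (!any(open)) break
    xc <- t$coords[, , k]
    di <- sqrt(rowSums((xc[nc[open, 1], , drop = FALSE] -
                        xc[nc[open, 2], , drop = FALSE])^2))
    hit <- di <= thr[open]
    formed[which(open)[hit]] <- k
  }
  data.frame(i = nc[, 1], j = nc[, 2], formation_frame = formed)
}
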