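# Internal helpers: seeded evaluation, small linear algebra, validation.

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + 9973 * as.double(k)) %% 2147483647L)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Uniform random unit vector (uses current RNG stream).
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det = +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rodrigues rotation of row-vectors `x` by angle about unit `axis` through
# `origin`.
rotate_about_axis <- function(x, axis, angle, origin = c(0, 0, 0)) {
  axis <- unitize(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(x, 2, origin) %*% t(R), 2, origin, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
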