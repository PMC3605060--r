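# drp_scoring: Onsager-Machlup weights and dominant-path selection

# A free-particle force field on 3 beads (no interactions at all).
free_ff <- function() {
  ref <- conformation(cbind(c(0, 3.8, 7.6), 0, 0))
  pars <- ff_params(kb = 0, ka = 0, kd1 = 0, kd3 = 0, eps_ev = 0,
                    qc_matrix = quasichemical_matrix(0))
  nat <- native_structure(ref, contact_cutoff = 0.1)
  build_forcefield(nat, mode = "native_only", params = pars)
}

lin_path <- function(from, to, nf) {
  arr <- array(0, dim = c(nrow(from), 3, nf))
  for (k in seq_len(nf)) {
    s <- (k - 1) / (nf - 1)
    arr[, , k] <- (1 - s) * from + s * to
  }
  arr
}

test_that("zero-force: the straight path maximizes the log-weight", {
  ff <- free_ff()
  from <- cbind(c(0, 3.8, 7.6), 0, 0)
  to <- from + 5
  straight <- trajectory(lin_path(from, to, 6), dt = 0.1, seed = 1L)
  lw_straight <- path_log_weight(straight, ff)$log_weight
  set.seed(7)
  for (k in 1:10) {
    jag <- straight
    mid <- jag$coords[, , 2:5] + array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
    jag$coords[, , 2:5] <- mid
    expect_lt(path_log_weight(jag, ff)$log_weight, lw_straight)
  }
  # identical trajectories score identically
  expect_equal(path_log_weight(straight, ff)$log_weight, lw_straight)
})

test_that("1-D harmonic well: argmax over a grid matches brute force", {
  # single mobile coordinate: bead 1 x-coordinate in a harmonic bond of
  # stiffness k to bead 2 (others pinned by zero force).  4 steps with
  # fixed endpoints; enumerate all 5^3 intermediate grid paths with an
  # independent textbook discretization of the OM action, and check that
  # path_log_weight ranks the same grid path highest.
  k <- 2; D <- 0.1; dt <- 0.05; Temp <- 1
  ref <- conformation(cbind(c(0, 5, 400), 0, 0))
  pars <- ff_params(kb = k, ka = 0, kd1 = 0, kd3 = 0, eps_ev = 0,
                    qc_matrix = quasichemical_matrix(0))
  nat <- native_structure(ref, contact_cutoff = 0.1)
  ff <- build_forcefield(nat, mode = "native_only", params = pars)
  # path endpoints: bead1 x from 0 to 2, all else fixed native
  grid <- seq(0, 2, length.out = 5)
  paths <- expand.grid(a = grid, b = grid, c = grid)
  # Independent closed-form oracle: the only moving coordinate is bead
  # 1's x; the harmonic bond E = k/2 (r - b0)^2 with r = x2 - x1, b0 = 5
  # exerts F1 = +k (r - b0) on bead 1 and the opposite F2 = -F1 on the
  # stationary bead 2, whose zero displacement also enters the action.
  # All other coordinates carry zero force throughout.
  om_oracle <- function(xs) {
    s <- 0
    for (t in 1:(length(xs) - 1)) {
      r <- 5 - xs[t]
      F1 <- k * (r - 5)
      dev1 <- xs[t + 1] - xs[t] - (D * dt / Temp) * F1
      dev2 <- 0 - (D * dt / Temp) * (-F1)
      s <- s - (dev1^2 + dev2^2) / (4 * D * dt)
    }
    s
  }
  oracle_scores <- apply(paths, 1, function(p) om_oracle(c(0, p, 2)))
  # package scores for the same paths (other beads immobile => their
  # contribution is a path-independent constant)
  pkg_scores <- apply(paths, 1, function(p) {
    arr <- array(rep(ref$coords, 5), dim = c(3, 3, 5))
    arr[1, 1, ] <- c(0, p, 2)
    path_log_weight(trajectory(arr, dt = dt), ff, D = D,
                    temperature = Temp)$log_weight
  })
  expect_equal(which.max(pkg_scores), which.max(oracle_scores))
  # and the two scores agree up to an additive constant
  d <- pkg_scores - oracle_scores
  expect_lt(max(d) - min(d), 1e-8)
})

test_that("drp_report tabulates weights and flags the winner", {
  ff <- free_ff()
  from <- cbind(c(0, 3.8, 7.6), 0, 0)
  straight <- trajectory(lin_path(from, from + 4, 5), dt = 0.1, seed = 5L)
  set.seed(3)
  arr <- lin_path(from, from + 4, 5)
  arr[, , 2:4] <- arr[, , 2:4] + array(rnorm(27), dim = c(3, 3, 3))
  jag <- trajectory(arr, dt = 0.1, seed = 9L)
  rep <- drp_report(list(jag, straight), ff)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$seed, c(9L, 5L))
  expect_true(rep$selected[2] && !rep$selected[1])
  expect_gt(rep$log_weight[2], rep$log_weight[1])
})

test_that("select_dominant picks the highest weight with seed tie-break", {
  ff <- free_ff()
  from <- cbind(c(0, 3.8, 7.6), 0, 0)
  to <- from + 4
  straight <- trajectory(lin_path(from, to, 5), dt = 0.1, seed = 5L)
  set.seed(1)
  mk_jag <- function(seed) {
    arr <- lin_path(from, to, 5)
    arr[, , 2:4] <- arr[, , 2:4] + array(rnorm(27), dim = c(3, 3, 3))
    trajectory(arr, dt = 0.1, seed = seed)
  }
  j1 <- mk_jag(9L); j2 <- mk_jag(2L)
  # singleton set
  expect_identical(select_dominant(list(j1), ff)$coords, j1$coords)
  win <- select_dominant(list(j1, straight, j2), ff)
  expect_identical(win$coords, straight$coords)
  # duplicate winner with higher seed: tie broken by the lower seed
  dup <- straight; dup$seed <- 99L
  win2 <- select_dominant(list(dup, straight, j1), ff)
  expect_equal(win2$seed, 5L)
  expect_error(select_dominant(list(), ff), "empty")
  # cross-stride comparisons are refused
  longer <- trajectory(lin_path(from, to, 7), dt = 0.1, seed = 1L)
  expect_error(select_dominant(list(straight, longer), ff),
               "frame count|stride")
  # different initial conditions are refused
  other <- trajectory(lin_path(from + 3, to, 5), dt = 0.1, seed = 1L)
  expect_error(select_dominant(list(straight, other), ff),
               "initial condition")
})
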