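# cg_forcefield: construction, energies, analytic forces

test_that("native_only zeroes non-native terms; modes agree when zeroed", {
  nat <- toy_native_cached()
  ff0 <- build_forcefield(nat, mode = "native_only")
  set.seed(2)
  x <- nat$reference$coords + matrix(rnorm(48 * 3, sd = 1), ncol = 3)
  e0 <- energy(x, ff0)
  expect_equal(e0$quasichemical, 0)
  expect_equal(e0$electrostatic, 0)
  # with_nonnative with zeroed matrix and charges == native_only exactly
  ffz <- build_forcefield(nat, sequence = strrep("G", 48),
                          mode = "with_nonnative",
                          params = ff_params(qc_matrix = quasichemical_matrix(0)))
  ez <- energy(x, ffz)
  expect_equal(ez$total, e0$total, tolerance = 1e-12)
})

test_that("energy breakdown components sum to the total", {
  nat <- toy_native_cached()
  ff <- toy_ff_cached()
  set.seed(3)
  x <- nat$reference$coords + matrix(rnorm(48 * 3, sd = 0.5), ncol = 3)
  e <- energy(x, ff)
  expect_equal(e$total,
               e$bonded + e$native + e$quasichemical + e$electrostatic +
                 e$excluded_volume,
               tolerance = 1e-9)
})

test_that("charged-pair electrostatics: closed form and sign pattern", {
  # two isolated charges at r = lambda_D: E = lB * qq * exp(-1) / lambda_D
  # (realized inside a 5-bead K/E chain stretched so only one charged
  # pair is within interaction range would be convoluted; instead check
  # the pair term through the full energy of KEKEK at two scalings)
  coords <- cbind(c(0, 10, 20, 30, 40), 0, 0)
  ref <- conformation(coords)
  nat <- native_structure(ref, contact_cutoff = 0.1) # no native contacts wanted
  expect_equal(nrow(nat$native_contacts), 0L)
  pars <- ff_params(kb = 0, ka = 0, kd1 = 0, kd3 = 0, eps_ev = 0,
                    qc_matrix = quasichemical_matrix(0))
  ffKE <- build_forcefield(nat, sequence = "KEKEK", mode = "with_nonnative",
                           params = pars)
  # hand-sum the Debye terms over the |i-j| >= 3 charged pairs
  qs <- c(1, -1, 1, -1, 1)
  hand <- 0
  for (i in 1:4) for (j in (i + 1):5) if (j - i >= 3) {
    r <- 10 * (j - i)
    hand <- hand + pars$lB * qs[i] * qs[j] * exp(-r / pars$lambdaD) / r
  }
  e <- energy(ref, ffKE)
  expect_equal(e$electrostatic, hand, tolerance = 1e-12)
  # alternating sign pattern: (1,4) attractive (K,E), (2,5) attractive,
  # (1,5)? no wait (1,5) is K,K repulsive; net dominated by nearest pairs
  expect_lt(e$electrostatic, 0)
  ffKK <- build_forcefield(nat, sequence = "KKKKK", mode = "with_nonnative",
                           params = pars)
  expect_gt(energy(ref, ffKK)$electrostatic, 0)
})

test_that("native wells sit at the native distances", {
  nat <- toy_native_cached()
  ff0 <- toy_ff_cached("native_only") # native_eps = 1.5
  e_ref <- energy(nat$reference, ff0)$native
  # stretching any single native pair by +1 A (moving the whole pair
  # geometry) cannot lower the native-well energy; check on a two-bead
  # isolated evaluation through the spec arrays instead: each well's
  # minimum is at sigma = native distance
  spec <- ff0$spec
  expect_equal(e_ref, -1.5 * length(spec$nat_i), tolerance = 1e-6)
  # single-well shape: E(sigma) < E(sigma + 1) and E(sigma) < E(sigma - 0.5)
  sig <- spec$nat_sig[1]
  well <- function(r) {
    s <- sig / r
    1.5 * (5 * s^12 - 6 * s^10)
  }
  expect_lt(well(sig), well(sig + 1))
  expect_lt(well(sig), well(sig - 0.5))
})

test_that("force is the exact gradient of the energy (FD oracle)", {
  nat <- toy_native_cached()
  ff <- toy_ff_cached()
  set.seed(4)
  x <- nat$reference$coords + matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  f <- force(x, ff)
  h <- 1e-5
  idx <- cbind(sample(48, 12, replace = TRUE), sample(3, 12, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; c <- idx[k, 2]
    xp <- x; xp[i, c] <- xp[i, c] + h
    xm <- x; xm[i, c] <- xm[i, c] - h
    num <- -(energy(xp, ff)$total - energy(xm, ff)$total) / (2 * h)
    expect_equal(f[i, c], num, tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("forces are translation invariant with zero net force", {
  nat <- toy_native_cached()
  ff <- toy_ff_cached()
  set.seed(5)
  x <- nat$reference$coords + matrix(rnorm(48 * 3, sd = 0.4), ncol = 3)
  f1 <- force(x, ff)
  f2 <- force(sweep(x, 2, c(7, -2, 3), `+`), ff)
  expect_equal(f1, f2, tolerance = 1e-8)
  expect_equal(colSums(f1), c(0, 0, 0), tolerance = 1e-8)
})

test_that("unknown amino-acid codes are rejected", {
  nat <- toy_native_cached()
  expect_error(build_forcefield(nat, sequence = strrep("Z", 48)),
               "unknown amino-acid")
})

test_that("quasi-chemical matrices round-trip through TSV", {
  m <- quasichemical_matrix(0.7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_quasichemical_matrix(m, f)
  m2 <- read_quasichemical_matrix(f)
  expect_equal(m2, m, tolerance = 1e-8)
  # asymmetric tables are rejected
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_quasichemical_matrix(bad, f2)
  expect_error(read_quasichemical_matrix(f2), "symmetric")
})

test_that("low-temperature MC under native_only stays near the reference", {
  nat <- toy_native_cached()
  ff0 <- toy_ff_cached("native_only")
  rms_at <- function(temp) {
    tr <- run_mc(nat$reference, ff0, move_set(), n_moves = 30000,
                 temperature = temp, seed = 5, save_stride = 3000)
    median(vapply(2:n_frames(tr), function(k)
      kabsch_rmsd(tr$coords[, , k], nat$reference), numeric(1)))
  }
  expect_lt(rms_at(0.2), rms_at(2.5))
  expect_lt(rms_at(0.2), 2)
})
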