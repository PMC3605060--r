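# path_analysis: order matrices, sigma similarity, density projections,
# mechanism classification

test_that("order_matrix encodes formation order with ties and never-formed", {
  expect_equal(order_matrix(c(0, 1, 2)),
               matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 1), 3, 3))
  expect_equal(order_matrix(c(3, 3, 3)), matrix(1L, 3, 3))
  # permutation case (2, 0, 1): hand-built
  M <- order_matrix(c(2, 0, 1))
  expect_equal(M, rbind(c(1, 0, 0), c(1, 1, 1), c(1, 0, 1)))
  # never-formed contacts rank last, tied among themselves
  M2 <- order_matrix(c(1, 2, NA, NA))
  expect_equal(M2, rbind(c(1, 1, 1, 1), c(0, 1, 1, 1),
                         c(0, 0, 1, 1), c(0, 0, 1, 1)))
  # fewer than 2 defined formation frames is an error
  expect_error(order_matrix(c(1, NA, NA)), "at least 2")
})

test_that("sigma endpoints, symmetry, and the hand-counted transposition", {
  id4 <- order_matrix(1:4)
  expect_equal(path_similarity(id4, id4), 1)
  rev4 <- order_matrix(4:1)
  expect_equal(path_similarity(id4, rev4), 0)
  # orders (1,2,3,4) vs (2,1,3,4): entries (1,2) and (2,1) differ ->
  # sigma = 1 - 2/12 = 5/6
  sw <- order_matrix(c(2, 1, 3, 4))
  expect_equal(path_similarity(id4, sw), 5 / 6)
  expect_equal(path_similarity(sw, id4), 5 / 6)
})

test_that("sigma is a similarity and 1 - sigma a metric on strict orders", {
  set.seed(6)
  perms <- replicate(12, sample(8), simplify = FALSE)
  Ms <- lapply(perms, order_matrix)
  for (a in Ms) expect_equal(path_similarity(a, a), 1)
  for (i in 1:11) for (j in (i + 1):12) {
    s <- path_similarity(Ms[[i]], Ms[[j]])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, path_similarity(Ms[[j]], Ms[[i]]))
  }
  # triangle inequality for d = 1 - sigma
  for (k in 1:30) {
    ijk <- sample(12, 3)
    d <- function(a, b) 1 - path_similarity(Ms[[a]], Ms[[b]])
    expect_lte(d(ijk[1], ijk[3]),
               d(ijk[1], ijk[2]) + d(ijk[2], ijk[3]) + 1e-12)
  }
})

test_that("sigma depends only on formation order, not timing", {
  set.seed(7)
  f1 <- sample(100, 10); f2 <- sample(100, 10)
  M <- function(f) order_matrix(f)
  s0 <- path_similarity(M(f1), M(f2))
  # strictly increasing reparameterizations leave sigma unchanged
  for (g in list(function(x) x^2, function(x) log(x + 1),
                 function(x) 3 * x + 7)) {
    expect_equal(path_similarity(M(g(f1)), M(g(f2))), s0)
  }
})

test_that("sigma_distribution covers all unordered pairs, mean near the
           permutation expectation", {
  set.seed(8)
  n <- 20; nc <- 10
  paths <- lapply(1:n, function(i) {
    structure(list(trajectory_id = i,
                   formation_frames = data.frame(i = 1:nc, j = 2:(nc + 1),
                                                 formation_frame = sample(nc)),
                   order_matrix = order_matrix(sample(nc))),
              class = "path_record")
  })
  sd1 <- sigma_distribution(paths)
  expect_equal(length(sd1$sigma), n * (n - 1) / 2)
  # Monte-Carlo oracle for the expected sigma of two random permutations
  set.seed(9)
  oracle <- mean(replicate(3000, path_similarity(order_matrix(sample(nc)),
                                                 order_matrix(sample(nc)))))
  se <- sd(sd1$sigma) / sqrt(length(sd1$sigma)) + 0.01
  expect_lt(abs(mean(sd1$sigma) - oracle), 3 * se + 0.02)
  expect_error(sigma_distribution(paths[1]), "at least 2")
})

test_that("overlap_at_first_knot returns the overlap at the event frame", {
  nat <- toy_native_cached()
  rod <- cbind(3.8 * (1:48), 0, 0)
  ref <- nat$reference$coords
  arr <- array(0, dim = c(48, 3, 3))
  arr[, , 1] <- rod; arr[, , 2] <- rod; arr[, , 3] <- ref
  tr <- trajectory(arr)
  ov <- overlap_at_first_knot(tr, nat, closure_spec(n_closures = 15),
                              seed = 2)
  expect_equal(ov, 1.0) # knots at its final, fully native frame
  tr0 <- trajectory(array(rep(rod, 2), dim = c(48, 3, 2)))
  expect_true(is.na(overlap_at_first_knot(tr0, nat,
                                          closure_spec(n_closures = 15),
                                          seed = 2)))
})

test_that("density_projection bins frames and places markers", {
  nat <- toy_native_cached()
  ref <- nat$reference$coords
  # frozen frame repeated k times -> a single bin holding k counts
  tr <- trajectory(array(rep(ref, 7), dim = c(48, 3, 7)))
  dp <- density_projection(list(tr), nat, region = nat$regions$sheet,
                           bins = 10)
  expect_equal(sum(expm1(dp$log_counts)), 7, tolerance = 1e-6)
  expect_equal(sum(dp$log_counts > 0), 1)
  # native-only trajectory: mass at (~0, ~0)
  expect_gt(dp$log_counts[1, 1], 0)
  # two-stage fixture: region forms first, then the rest
  set.seed(10)
  noise <- matrix(rnorm(48 * 3, sd = 6), ncol = 3)
  noise[nat$regions$sheet, ] <- 0 # region already native
  half <- ref + noise
  arr <- array(0, dim = c(48, 3, 4))
  arr[, , 1] <- ref + matrix(rnorm(48 * 3, sd = 6), ncol = 3)
  arr[, , 2] <- half; arr[, , 3] <- half; arr[, , 4] <- ref
  tr2 <- trajectory(arr)
  ys <- vapply(1:4, function(k)
    kabsch_rmsd(arr[, , k], ref, subset = nat$regions$sheet), numeric(1))
  xs <- vapply(1:4, function(k) kabsch_rmsd(arr[, , k], ref), numeric(1))
  # region RMSD collapses before the total does
  expect_lt(ys[2], 1e-6)
  expect_gt(xs[2], 1)
})

test_that("mechanism classifier labels all three kinematic fixtures", {
  nat <- toy_native_cached()
  kcfg <- closure_spec(n_closures = 20)
  fx_thread <- kinematic_fixture("threading", n_frames = 30, native = nat)
  fx_slip <- kinematic_fixture("slipknot", n_frames = 30, native = nat)
  fx_mouse <- kinematic_fixture("mousetrap", n_frames = 30, native = nat)
  mt <- classify_mechanism(fx_thread, nat, knot_cfg = kcfg, seed = 5)
  ms <- classify_mechanism(fx_slip, nat, knot_cfg = kcfg, seed = 5)
  mm <- classify_mechanism(fx_mouse, nat, knot_cfg = kcfg, seed = 5)
  expect_equal(mt$label, "threading")
  expect_equal(ms$label, "slipknot")
  expect_equal(mm$label, "mousetrap")
  # slipknot evidence: a slipknotted frame precedes the first global knot
  expect_true(ms$evidence$slipknot_prior)
  expect_false(mt$evidence$slipknot_prior)
  # determinism under fixed seed
  mt2 <- classify_mechanism(fx_thread, nat, knot_cfg = kcfg, seed = 5)
  expect_identical(mt$label, mt2$label)
  # no knotting event -> unresolved
  rod <- cbind(3.8 * (1:48), 0, 0)
  tr0 <- trajectory(array(rep(rod, 12), dim = c(48, 3, 12)))
  expect_equal(classify_mechanism(tr0, nat, knot_cfg = kcfg, seed = 1)$label,
               "unresolved")
})
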