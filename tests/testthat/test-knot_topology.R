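# knot_topology: Alexander determinants, stochastic closure, subchain
# scanning, first-knotting events.
#
# Oracle values: |Delta(-1)| = 1 (unknot), 3 (trefoil), 5 (figure-eight),
# 9 (trefoil # trefoil, by multiplicativity of the determinant under
# connect sum).  The trefoil value 3 is independently fixed by the
# textbook underpass presentation of the standard 3-crossing alternating
# diagram: each underpass k is spanned by the opposite arc, giving the
# 2x2 first minor [[1, 1], [-2, 1]] at t = -1, determinant 3 (checked
# below without any geometry).

test_that("underpass presentation of the standard trefoil diagram gives 3", {
  # hand-built Alexander matrix of the alternating 3-crossing diagram at
  # t = -1 (rows: -t, 1, t-1 -> 1, 1, -2 with over-arc i_k = k+2 mod 3)
  A <- rbind(c(1, 1, -2), c(-2, 1, 1), c(1, -2, 1))
  minor <- A[1:2, 1:2]
  expect_equal(abs(det(minor)), 3)
})

test_that("alexander_determinant reproduces knot-table values", {
  expect_equal(alexander_determinant(parametric_knot("unknot", 16)), 1L)
  expect_equal(alexander_determinant(parametric_knot("trefoil", 60)), 3L)
  expect_equal(alexander_determinant(parametric_knot("figure_eight", 80)), 5L)
})

test_that("determinant is invariant under projection, relabeling, rigid motion", {
  ring <- parametric_knot("trefoil", 60, scale = 5)
  set.seed(10)
  vals <- replicate(20, alexander_determinant(ring))
  expect_true(all(vals == 3L)) # 20 random generic projections
  # vertex relabeling (rotation of the cyclic order)
  shifted <- ring[c(25:60, 1:24), ]
  expect_equal(alexander_determinant(shifted), 3L)
  moved <- rigid_motion(ring, seed = 2)
  expect_equal(alexander_determinant(moved), 3L)
  # simplification must not change the value
  expect_equal(alexander_determinant(ring, simplify = FALSE), 3L)
})

test_that("determinant of a trefoil connect-sum is 9 (multiplicativity)", {
  a <- parametric_knot("trefoil", 60, scale = 3)
  b <- parametric_knot("trefoil", 60, scale = 3)
  # place the two rings far apart along x, open each at one vertex and
  # splice: a-path, bridge, b-path, bridge back
  b <- sweep(b, 2, c(30, 0, 0), `+`)
  ring <- rbind(a, b)
  expect_equal(alexander_determinant(ring), 9L)
})

test_that("stochastic closure honors the exit-angle constraint", {
  nat <- toy_native_cached()
  xc <- nat$reference$coords
  n <- nrow(xc)
  spec <- closure_spec()
  set.seed(3)
  for (k in 1:200) {
    ring <- stochastic_closure(xc, spec)
    # first closure vertex after the chain is the C-terminal stub
    stubC <- ring[n + 1, ] - xc[n, ]
    refC <- xc[n - spec$anchor_seq_dist, ] - xc[n, ]
    expect_lt(sum(stubC * refC), 0) # angle > 90 degrees
    stubN <- ring[nrow(ring), ] - xc[1, ]
    refN <- xc[1 + spec$anchor_seq_dist, ] - xc[1, ]
    expect_lt(sum(stubN * refN), 0)
  }
  # fixed seed gives an identical closure
  r1 <- stochastic_closure(xc, spec, seed = 5)
  r2 <- stochastic_closure(xc, spec, seed = 5)
  expect_identical(r1, r2)
  # closure arc stays outside the chain's bounding sphere
  ctr <- colMeans(xc)
  rad <- max(sqrt(rowSums(sweep(xc, 2, ctr)^2)))
  arcpts <- r1[(n + 2):(nrow(r1) - 1), , drop = FALSE]
  expect_true(all(sqrt(rowSums(sweep(arcpts, 2, ctr)^2)) > rad))
})

test_that("straight rods and open coils classify unknotted", {
  rod <- cbind(3.8 * (1:20), 0, 0)
  v <- knotfold:::closure_vote(rod, closure_spec(n_closures = 100), seed = 1)
  expect_equal(v$det, 1L)
  expect_equal(v$vote_fraction, 1)
})

test_that("classification: toy native knotted, ring trefoil unanimous", {
  nat <- toy_native_cached()
  ka <- classify_conformation(nat$reference,
                              spec = closure_spec(n_closures = 50),
                              scan = NULL, seed = 3)
  expect_equal(ka$classification, "globally_knotted")
  expect_equal(ka$knot_determinant, 3L)
  expect_gte(ka$vote_fraction, 0.9)
  ring <- parametric_knot("trefoil", 60, scale = 5)
  for (s in c(1, 17, 123)) {
    kr <- classify_conformation(ring, spec = closure_spec(n_closures = 20),
                                scan = NULL, seed = s)
    expect_equal(kr$classification, "globally_knotted")
    expect_equal(kr$vote_fraction, 1)
  }
})

test_that("subchain scan finds a shallow span and flags slipknots", {
  nat <- toy_native_cached()
  ka <- classify_conformation(nat$reference,
                              spec = closure_spec(n_closures = 20),
                              scan = c(20, 30, 40), seed = 2,
                              scan_stride = 2L)
  expect_equal(ka$classification, "globally_knotted")
  expect_false(is.null(ka$knotted_span))
  # the span leaves at least knot_depth tail beads outside the core
  spec <- attr(nat, "toy_spec")
  expect_lte(ka$knotted_span["end"], spec$n_beads - spec$knot_depth)
  # hairpin-bent slipknot fixture: a mid-trajectory frame of the slipknot
  # kinematic fixture is slipknotted
  fx <- kinematic_fixture("slipknot", n_frames = 20, native = nat)
  a_frames <- ceiling(0.6 * 20)
  kah <- classify_conformation(fx$coords[, , a_frames],
                               spec = closure_spec(n_closures = 20),
                               scan = c(20, 30, 40), seed = 4,
                               scan_stride = 2L)
  expect_equal(kah$classification, "slipknotted")
  expect_equal(kah$global_state, "unknot")
  expect_false(is.null(kah$knotted_span))
})

test_that("first_knotting_event finds the earliest knotted frame", {
  nat <- toy_native_cached()
  rod <- cbind(3.8 * (1:48), 0, 0)
  ref <- nat$reference$coords
  # all-unknotted trajectory
  tr0 <- trajectory(array(rep(rod, 3), dim = c(48, 3, 3)))
  expect_true(is.na(first_knotting_event(tr0, closure_spec(n_closures = 15),
                                         seed = 1)))
  # unknotted then knotted from frame 3 onward
  arr <- array(0, dim = c(48, 3, 4))
  arr[, , 1] <- rod; arr[, , 2] <- rod; arr[, , 3] <- ref; arr[, , 4] <- ref
  expect_equal(first_knotting_event(trajectory(arr),
                                    closure_spec(n_closures = 15), seed = 1),
               3L)
})

test_that("verdicts are deterministic under a fixed seed", {
  nat <- toy_native_cached()
  k1 <- classify_conformation(nat$reference, closure_spec(n_closures = 30),
                              scan = NULL, seed = 11)
  k2 <- classify_conformation(nat$reference, closure_spec(n_closures = 30),
                              scan = NULL, seed = 11)
  expect_identical(k1, k2)
})
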