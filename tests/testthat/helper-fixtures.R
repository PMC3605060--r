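# Shared fixtures, built once per test run.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

toy_native_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_toy_native()
    val
  }
})

toy_ff_cached <- local({
  val <- NULL
  function(mode = "with_nonnative") {
    if (is.null(val)) val <<- list()
    if (is.null(val[[mode]]))
      val[[mode]] <<- build_forcefield(toy_native_cached(), mode = mode,
                                       params = ff_params(native_eps = 1.5))
    val[[mode]]
  }
})

# small square toy conformation used by geometry tests
square_conf <- function(side = 3.8) {
  conformation(rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0),
                     c(0, side, 0)))
}

# an arbitrary rotation + translation
rigid_motion <- function(x, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(x %*% q, 2, c(5, -3, 11), `+`)
}
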