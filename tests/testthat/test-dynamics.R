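test_that("fitness is interaction benefit plus environmental offset", {
  A0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- fcpModel(A0, c(0.3, 0.5), 0.5)
  expect_equal(communityFitness(m, c(0.9, 0.1)), c(0.3, 0.5))
  expect_equal(communityFitness(m, c(0.1, 0.9)), c(0.3, 0.5))

  A1 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m1 <- fcpModel(A1, c(0, 0), 0.5)
  expect_equal(communityFitness(m1, c(0.25, 0.75)), c(0.75, 0.25))

  # at a vertex e_i the fitness of species j is the interaction column A[j, i]
  m3 <- randomModel(4, 0.5, 1)
  f <- communityFitness(m3, c(0, 1, 0, 0))
  expect_equal(f, unname(modelInteraction(m3)[, 2]) + modelOffsets(m3))

  expect_error(communityFitness(m, c(1, 0, 0)), "does not match")
})

test_that("compositional derivatives sum to zero on the simplex", {
  for (seed in 1:5) {
    m <- randomModel(5, c(0.3, 0.6, 0.9, 0.5, 0.7)[seed], seed)
    x <- randomSimplex(5, seed + 10)
    d <- fcpDerivatives(m, x, N = 500)
    expect_equal(sum(d$dx), 0, tolerance = 1e-12)
  }
  expect_error(fcpDerivatives(randomModel(3, 0.5, 1), randomSimplex(3, 1), N = -1),
               "positive")
})

test_that("c = 1 reduces to the classical replicator equation", {
  for (seed in 1:6) {
    m <- randomModel(3, 1, seed)
    x <- randomSimplex(3, seed + 20)
    d <- fcpDerivatives(m, x, N = 1)
    f <- communityFitness(m, x)
    expect_equal(d$dx, x * (f - sum(f * x)), tolerance = 1e-12)

    # equal fitness means no compositional motion in the classical limit
    mflat <- fcpModel(matrix(0, 3, 3, dimnames = dimnames(modelInteraction(m))),
                      rep(0.4, 3), 1)
    expect_equal(fcpDerivatives(mflat, x, N = 10)$dx, rep(0, 3))
  }
})

test_that("sub-exponential growth equalises a community with equal fitness", {
  # at c < 1 the rare-species advantage drives a flat-fitness community to
  # the uniform composition (only the uniform point is at rest)
  A0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m <- fcpModel(A0, rep(0.5, 3), 0.5)
  expect_equal(max(abs(fcpDerivatives(m, rep(1 / 3, 3), N = 10)$dx)), 0,
               tolerance = 1e-12)
  x <- steadyState(m, c(0.7, 0.2, 0.1))
  expect_equal(unname(x), rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("two-species classical endpoint matches the closed-form solution", {
  A0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- fcpModel(A0, c(0.6, 0.4), 1)
  tr <- integrateFCP(m, c(0.5, 0.5), tMax = 200, tol = 1e-10)
  tEnd <- tr@times[length(tr@times)]
  closed <- 0.5 * exp(0.6 * tr@times) /
    (0.5 * exp(0.6 * tr@times) + 0.5 * exp(0.4 * tr@times))
  expect_equal(tr@x[, 1], closed, tolerance = 1e-6)
  expect_equal(unname(tr@x[nrow(tr@x), ]), c(1, 0), tolerance = 1e-6)
})

test_that("trajectories conserve the simplex and stay non-negative", {
  for (seed in 1:6) {
    cs <- c(0.2, 0.5, 0.9, 0.2, 0.5, 0.9)[seed]
    m <- randomModel(4, cs, seed + 40)
    tr <- integrateFCP(m, randomSimplex(4, seed), tMax = 100)
    expect_true(max(abs(rowSums(tr@x) - 1)) < 1e-7)
    expect_true(min(tr@x) >= -1e-12)
    expect_true(all(diff(tr@times) > 0))
  }
})

test_that("classical trajectories match an independent replicator integrator", {
  for (seed in 1:5) {
    m <- randomModel(3, 1, seed + 60)
    x0 <- randomSimplex(3, seed + 70)
    tr <- integrateFCP(m, x0, N0 = 1, tMax = 50, tol = 1e-12)
    ref <- classicReplicator(modelInteraction(m), modelOffsets(m), x0, tr@times)
    expect_equal(unname(tr@x), ref, tolerance = 1e-6)
  }
})

test_that("final composition is insensitive to N0 and d", {
  m <- randomModel(9, 0.5, 7)
  x0 <- randomSimplex(9, 8)
  ends <- lapply(c(1, 1e3, 1e6), function(n0)
    integrateFCP(m, x0, N0 = n0, tMax = 300)@x |> tail(1))
  expect_lt(max(abs(ends[[1]] - ends[[3]])), 1e-3)
  expect_lt(max(abs(ends[[2]] - ends[[3]])), 1e-3)

  endsD <- lapply(c(0.001, 0.1, 1), function(dd) {
    md <- fcpModel(modelInteraction(m), modelOffsets(m), growthIndex(m), d = dd)
    tail(integrateFCP(md, x0, tMax = 300)@x, 1)
  })
  expect_lt(max(abs(endsD[[1]] - endsD[[3]])), 1e-2)
})

test_that("steady state solvers agree and respect permutation equivariance", {
  for (seed in 1:4) {
    m <- randomModel(5, c(0.2, 0.5, 0.9, 0.6)[seed], seed + 80)
    x0 <- rep(0.2, 5)
    xf <- steadyState(m, x0, method = "fixedpoint")
    xo <- steadyState(m, x0, method = "ode")
    expect_equal(xf, xo, tolerance = 1e-5)
    expect_equal(sum(xf), 1, tolerance = 1e-12)

    # relabeling species permutes the steady state correspondingly
    set.seed(seed)
    perm <- sample(5)
    A <- modelInteraction(m)
    mp <- fcpModel(A[perm, perm], modelOffsets(m)[perm], growthIndex(m))
    expect_equal(unname(steadyState(mp, x0)), unname(xf[perm]), tolerance = 1e-8)
  }
})

test_that("constructor rejects the super-exponential regime and bad shapes", {
  A0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(fcpModel(A0, c(0, 0), 1.2), "growth index")
  expect_error(fcpModel(A0, c(0, 0), 0), "growth index")
  expect_error(fcpModel(A0, c(0, 0, 0), 0.5), "dimensions")
  expect_error(fcpModel(A0, c(0, 0), 0.5, d = -1), "death rate")
  expect_error(integrateFCP(fcpModel(A0, c(0, 0), 0.5), c(0.7, 0.7)), "simplex")
})
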