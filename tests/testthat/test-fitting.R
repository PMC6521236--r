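test_that("Bray-Curtis similarity matches hand arithmetic and vegan", {
  expect_equal(brayCurtis(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 0)
  expect_equal(brayCurtis(c(0.6, 0.4), c(0.4, 0.6)), 0.8)
  expect_error(brayCurtis(c(1, 0), c(0.5, 0.3, 0.2)), "length")

  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    x <- randomSimplex(6, seed)
    y <- randomSimplex(6, seed + 50)
    ref <- 1 - as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
    expect_equal(brayCurtis(x, y), ref, tolerance = 1e-12)
  }
})

test_that("canonical offsets reproduce the observed composition exactly", {
  for (seed in 1:4) {
    m <- randomModel(6, 0.55, seed)
    xobs <- steadyState(m, rep(1 / 6, 6))
    for (cc in c(0.3, 0.5, 0.7)) {
      h <- canonicalOffsets(xobs, cc, modelInteraction(m))
      mm <- fcpModel(modelInteraction(m), h, cc)
      expect_equal(unname(steadyState(mm, rep(1 / 6, 6))), unname(xobs),
                   tolerance = 1e-9)
    }
  }
})

test_that("multi-start fitting recovers the observed composition", {
  m <- randomModel(6, 0.45, 3)
  xobs <- steadyState(m, rep(1 / 6, 6))
  fit <- fitSample(modelInteraction(m), xobs, nStarts = 5, seed = 11)
  expect_gte(fit@bc[1], 0.99)
  expect_lt(fit@objective[1], 1e-8)
  expect_false(is.unsorted(fit@objective))

  # seeded determinism: the full fit set is bit-identical on rerun
  fit2 <- fitSample(modelInteraction(m), xobs, nStarts = 5, seed = 11)
  expect_identical(fit@h, fit2@h)
  expect_identical(fit@objective, fit2@objective)

  # best-of-n objective is non-increasing in n under the same seed stream
  fit10 <- fitSample(modelInteraction(m), xobs, nStarts = 10, seed = 11)
  expect_lte(fit10@objective[1], fit@objective[1])
})

test_that("all well-converged starts agree on one composition", {
  m <- randomModel(5, 0.5, 9)
  xobs <- steadyState(m, rep(0.2, 5))
  fit <- fitSample(modelInteraction(m), xobs, nStarts = 20, seed = 2)
  modal <- fit@composition[1, ]
  good <- fit@objective < 1e-6
  expect_gte(sum(good), 2)
  agree <- apply(fit@composition[good, , drop = FALSE], 1,
                 function(x) brayCurtis(x, modal) >= 0.99)
  expect_true(all(agree))
})

test_that("zero penalty reproduces ordinary least squares exactly", {
  w <- tinyWorld()
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  ids <- rownames(X)
  fits <- setNames(lapply(ids, function(s)
    fitSample(A, X[s, ], nStarts = 2, sampleId = s, seed = 4)), ids)
  em <- fitEnvMap(fits, w$env, A, penalty = 0, growthIndex = 0.5,
                  profileScales = FALSE)

  # weighted normal-equations oracle on the same response; extinct species
  # are excluded from their sample's rows, matching the fit's survival mask
  E <- envValues(w$env)[ids, ]
  Z <- scale(E)
  Y <- X^(1 - 0.5) - X %*% t(A)
  D <- cbind(1, Z)
  W <- (X > 1e-8) * 1
  for (i in seq_len(ncol(X))) {
    Dw <- D * W[, i]
    beta <- solve(t(Dw) %*% D, t(Dw) %*% Y[, i])
    expect_equal(unname(envCoefficients(em)[i, ]), unname(beta[-1]),
                 tolerance = 1e-6)
    expect_equal(unname(em@intercept[i]), unname(beta[1]), tolerance = 1e-6)
  }
})

test_that("a huge penalty shrinks every coefficient to exactly zero", {
  w <- tinyWorld()
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  ids <- rownames(X)
  fits <- setNames(lapply(ids, function(s)
    fitSample(A, X[s, ], nStarts = 2, sampleId = s, seed = 4)), ids)
  em <- fitEnvMap(fits, w$env, A, penalty = 1e4, growthIndex = 0.5,
                  profileScales = FALSE)
  expect_true(all(envCoefficients(em) == 0))
  Y <- X^(1 - 0.5) - X %*% t(A)
  W <- (X > 1e-8) * 1
  ybar <- colSums(Y * W) / colSums(W)   # intercept is the surviving-row mean
  expect_equal(unname(em@intercept), unname(ybar), tolerance = 1e-6)
})

test_that("cross-validated Lasso recovers the active factor support", {
  w <- simulateWorld(nSpecies = 7, nCogs = 150, nPlanted = 10,
                     nSamples = 17, nFactors = 13, nActive = 3, seed = 5)
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  ids <- rownames(X)
  fits <- setNames(lapply(ids, function(s)
    fitSample(A, X[s, ], nStarts = 4, sampleId = s, seed = 6)), ids)
  em <- suppressWarnings(fitEnvMap(fits, w$env, A, penalty = "cv", seed = 7))
  recovered <- colnames(envCoefficients(em))[colSums(abs(envCoefficients(em))) > 0]
  sens <- mean(w$truth$activeFactors %in% recovered)
  expect_gte(sens, 2 / 3)

  # the dominant planted factor carries the largest influence
  infl <- envInfluence(em)
  expect_equal(names(which.max(infl)), w$truth$activeFactors[1])
})

test_that("environment influence aggregates coefficients as percentages", {
  em <- new("EnvMap",
            B = matrix(c(0, 0, 2, 0, 0, 0), 2, 3,
                       dimnames = list(c("a", "b"), c("f1", "f2", "f3"))),
            intercept = c(0, 0), factorMeans = c(f1 = 0, f2 = 0, f3 = 0),
            factorSds = c(f1 = 1, f2 = 1, f3 = 1), lambda = c(0, 0),
            c = 0.5, scales = 1)
  infl <- envInfluence(em)
  expect_equal(unname(infl), c(0, 100, 0))

  em@B <- matrix(c(1, 1, -2, 0, 0, 0), 2, 3,
                 dimnames = dimnames(em@B))
  expect_equal(unname(envInfluence(em)), c(50, 50, 0))

  em@B[] <- 0
  expect_warning(infl0 <- envInfluence(em), "uniform")
  expect_equal(unname(infl0), rep(100 / 3, 3))
})

test_that("predictions ignore factors with zero coefficients", {
  w <- tinyWorld()
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  ids <- rownames(X)
  fits <- setNames(lapply(ids, function(s)
    fitSample(A, X[s, ], nStarts = 2, sampleId = s, seed = 4)), ids)
  em <- fitEnvMap(fits, w$env, A, penalty = 0.05, growthIndex = 0.5)
  em@B[, 4:5] <- 0   # force a sparse map: last two factors inactive
  e1 <- envValues(w$env)[1, ]
  e2 <- e1
  e2[4:5] <- e2[4:5] + 100
  expect_equal(predictComposition(A, em, e1), predictComposition(A, em, e2))
  expect_error(predictComposition(A, em, e1[-1]), "missing factors")
})

test_that("a perfect prediction report has unit R2 and identity regression", {
  X <- t(replicate(4, randomSimplex(5)))
  dimnames(X) <- list(sprintf("S%02d", 1:4), sprintf("sp%02d", 1:5))
  obs <- as.vector(X)
  prd <- as.vector(X)
  fit <- lm(prd ~ obs)
  rep <- new("PredictionReport", observed = X, predicted = X,
             bc = rep(1, 4), r2 = suppressWarnings(summary(fit)$r.squared),
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  expect_equal(rep@r2, 1)
  expect_equal(rep@slope, 1)
  expect_equal(rep@intercept, 0)
})

test_that("cross-validation is deterministic and beats its noisy counterpart", {
  w <- tinyWorld()
  r1 <- suppressWarnings(crossValidate(w$profiles, w$abundance, w$env,
                                       folds = 2, nStarts = 3, seed = 9))
  r2 <- suppressWarnings(crossValidate(w$profiles, w$abundance, w$env,
                                       folds = 2, nStarts = 3, seed = 9))
  expect_identical(r1@predicted, r2@predicted)
  expect_identical(r1@bc, r2@bc)
})

test_that("noiseless observations predict better than noisy ones", {
  clean <- simulateWorld(seed = 17)
  noisy <- simulateWorld(obsNoiseSd = 0.3, seed = 17)
  hold <- list(sampleIds(clean$abundance)[1:5])
  rC <- suppressWarnings(crossValidate(clean$profiles, clean$abundance,
                                       clean$env, folds = hold,
                                       nStarts = 4, seed = 9))
  rN <- suppressWarnings(crossValidate(noisy$profiles, noisy$abundance,
                                       noisy$env, folds = hold,
                                       nStarts = 4, seed = 9))
  expect_gt(mean(rC@bc), mean(rN@bc))
})

test_that("model JSON round-trips the prediction state", {
  w <- tinyWorld()
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  ids <- rownames(X)[1:4]
  fits <- setNames(lapply(ids, function(s)
    fitSample(A, X[s, ], nStarts = 2, sampleId = s, seed = 4)), ids)
  em <- fitEnvMap(fits, w$env, A, penalty = 0.05, growthIndex = 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(em, A, f, seed = 42L)
  back <- readModelJSON(f)
  expect_equal(back$A, A)
  expect_equal(back$envMap@B, em@B)
  expect_equal(back$envMap@c, em@c)
  e <- envValues(w$env)[5, ]
  expect_equal(predictComposition(back$A, back$envMap, e),
               predictComposition(A, em, e))
})
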