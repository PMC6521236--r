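test_that("perturbation null is seeded and degenerates gracefully", {
  m <- randomModel(5, 0.5, 1)
  n1 <- perturbationNull(m, nPerturb = 50, noiseSd = 0.01, seed = 3)
  n2 <- perturbationNull(m, nPerturb = 50, noiseSd = 0.01, seed = 3)
  expect_identical(n1@bcSamples, n2@bcSamples)
  expect_false(n1@degenerate)
  expect_true(n1@threshold < 1 && n1@threshold > 0)

  # vanishing disturbances: null collapses onto BC = 1, threshold reported
  # as 1 and flagged degenerate (the t test has no resolution)
  n0 <- perturbationNull(m, nPerturb = 50, noiseSd = 1e-12, seed = 3)
  expect_true(n0@degenerate)
  expect_equal(n0@threshold, 1)
  expect_true(all(n0@bcSamples > 1 - 1e-9))

  expect_error(perturbationNull(m, noiseSd = 0), "positive")
})

test_that("knockout zeroes exactly the group's columns", {
  w <- tinyWorld()
  g <- dedupeProfiles(w$profiles)
  id <- groupIds(g)[5]
  ko <- knockoutProfile(w$profiles, g, id)
  cogs <- groupMembers(g, id)
  expect_true(all(hitCounts(ko)[, cogs] == 0))
  others <- setdiff(cogIds(w$profiles), cogs)
  expect_identical(hitCounts(ko)[, others], hitCounts(w$profiles)[, others])

  # after knockout the group's profile vector is gone (collapsed to zero)
  g2 <- dedupeProfiles(ko)
  prof <- g@profiles[id, ]
  expect_false(any(apply(g2@profiles[rowSums(g2@profiles) > 0, , drop = FALSE],
                         1, identical, prof)))
  expect_error(knockoutProfile(w$profiles, g, "P9999"), "unknown")
})

test_that("knocking out an all-zero COG leaves the interaction matrix intact", {
  cnt <- cbind(hitCounts(randomProfiles(5, 20, 2)), COGZERO = 0)
  pr <- FunctionalProfiles(cnt)
  g <- dedupeProfiles(pr)
  zid <- groupIds(g)[vapply(g@members, function(m) "COGZERO" %in% m, TRUE)]
  ko <- knockoutProfile(pr, g, zid)
  expect_identical(interactionMatrix(ko), interactionMatrix(pr))
})

test_that("a single-species COG knockout only touches that species' row", {
  cnt <- hitCounts(randomProfiles(6, 30, 4))
  cnt[, "COG0007"] <- 0
  cnt[3, "COG0007"] <- 50
  pr <- FunctionalProfiles(cnt)
  g <- dedupeProfiles(pr)
  id <- groupIds(g)[vapply(g@members, function(m) "COG0007" %in% m, TRUE)]
  S0 <- functionalSimilarity(pr)
  S1 <- functionalSimilarity(knockoutProfile(pr, g, id))
  changed <- which(abs(S1 - S0) > 1e-12, arr.ind = TRUE)
  expect_true(all(changed[, 1] == 3 | changed[, 2] == 3))
  # full-recomputation oracle agrees with the screen's internal route
  expect_equal(1 - S1 - diag(diag(1 - S1)),
               fcpcomm:::.knockout_A(hitCounts(pr), groupMembers(g, id)))
})

test_that("the screen flags planted structure-shaping genes and is consistent", {
  w <- tinyWorld(3)
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  fits <- fitSample(A, X[1, ], nStarts = 10, sampleId = rownames(X)[1], seed = 5)
  best <- fcpModel(A, fits@h[1, ], fits@c[1])
  null <- perturbationNull(best, nPerturb = 200, seed = 6)
  css <- screenCSS(w$profiles, fits, null, nParamGroups = 8)
  tab <- cssTable(css)

  # internal consistency: probability is the mean of per-parameter-group calls
  expect_equal(tab$probability, unname(rowMeans(css@indicators)))
  expect_false(is.unsorted(rev(tab$probability)))

  # planted high-copy pairs should be called; the bulk background should not
  g <- dedupeProfiles(w$profiles)
  pg <- vapply(w$planted, function(cg)
    groupIds(g)[vapply(g@members, function(m) cg %in% m, TRUE)][1], character(1))
  called <- tab$profileId[tab$probability >= 0.5]
  expect_gte(mean(pg %in% called), 0.5)
  expect_gte(mean(!setdiff(tab$profileId, pg) %in% called), 0.9)

  # determinism of the whole screen
  css2 <- screenCSS(w$profiles, fits, null, nParamGroups = 8)
  expect_identical(cssTable(css2), tab)

  # a degenerate null calls nothing
  null0 <- perturbationNull(best, nPerturb = 50, noiseSd = 1e-12, seed = 6)
  css0 <- screenCSS(w$profiles, fits, null0, nParamGroups = 4)
  expect_length(cssCogs(css0), 0)
})

test_that("stricter significance never enlarges the CSS set", {
  # with the one-sided t threshold, lowering alpha lowers the threshold and
  # can only drop calls
  m <- randomModel(5, 0.5, 11)
  n <- perturbationNull(m, nPerturb = 300, noiseSd = 0.01, seed = 2)
  thr <- vapply(c(0.01, 0.05, 0.2), function(a)
    mean(n@bcSamples) - qt(1 - a, length(n@bcSamples) - 1) * sd(n@bcSamples),
    numeric(1))
  expect_false(is.unsorted(thr))

  w <- tinyWorld(3)
  A <- interactionMatrix(w$profiles)
  X <- abundances(w$abundance)
  fits <- fitSample(A, X[1, ], nStarts = 6, sampleId = "s", seed = 5)
  best <- fcpModel(A, fits@h[1, ], fits@c[1])
  sizes <- vapply(c(0.01, 0.05, 0.2), function(a) {
    nn <- perturbationNull(best, nPerturb = 200, alpha = a, seed = 6)
    sum(cssTable(screenCSS(w$profiles, fits, nn, nParamGroups = 4))$probability >= 0.5)
  }, numeric(1))
  expect_false(is.unsorted(sizes))
})

test_that("category enrichment matches a brute-force hypergeometric oracle", {
  cogs <- sprintf("COG%04d", 1:20)
  catmap <- CogCategoryMap(setNames(c(rep("X", 5), rep("J", 10), rep("C", 5)), cogs))
  css <- cogs[1:5]   # exactly the X category
  rep <- enrichmentTest(css, cogs, catmap)
  tab <- enrichmentTable(rep)
  pX <- tab$p[tab$category == "X"]

  # brute force: enumerate all 5-subsets of the 20 COGs, two-sided exact test
  # by summing configurations no more probable than the observed one
  combos <- combn(20, 5)
  overlaps <- colSums(matrix(combos %in% 1:5, nrow = 5))
  probTab <- table(overlaps) / ncol(combos)
  pObs <- probTab[["5"]]
  oracle <- sum(probTab[probTab <= pObs + 1e-12])
  expect_equal(pX, oracle, tolerance = 1e-10)

  # css == background: every category has odds ratio 1 and p = 1
  repAll <- enrichmentTest(cogs, cogs, catmap)
  expect_true(all(enrichmentTable(repAll)$p == 1))

  # categories with no background members are skipped
  expect_false("K" %in% tab$category)
  expect_error(enrichmentTest(css, character(0), catmap), "empty")
  expect_error(enrichmentTest(c(css, "COG9999"), cogs, catmap), "subset")
})

test_that("overlap permutation test matches the hypergeometric tail", {
  u <- sprintf("g%02d", 1:20)
  res <- overlapPermutationTest(u, u, u, nPerm = 100, seed = 1)
  expect_equal(res$p, 1)
  res0 <- overlapPermutationTest(u[1:3], u[10:12], u, nPerm = 100, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)

  a <- u[1:5]
  b <- u[c(1:4, 10)]
  res4 <- overlapPermutationTest(a, b, u, nPerm = 10000, seed = 7)
  expect_equal(res4$observed, 4)
  exact <- phyper(3, 5, 15, 5, lower.tail = FALSE)   # P(overlap >= 4)
  expect_lt(abs(res4$p - exact), 3 * sqrt(exact * (1 - exact) / 10000) + 2e-4)

  expect_error(overlapPermutationTest(c(a, "zz"), b, u), "subsets")
})
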