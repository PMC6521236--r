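# Shared fixtures, built in code. Worlds are cached per (size, seed) so the
# generator runs once per suite.

.world_cache <- new.env(parent = emptyenv())

# small world for fast unit tests
tinyWorld <- function(seed = 1L) {
  key <- paste0("tiny", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- simulateWorld(nSpecies = 5L, nCogs = 60L,
                                         nPlanted = 6L, nSamples = 10L,
                                         nFactors = 5L, nActive = 2L,
                                         seed = seed)
  .world_cache[[key]]
}

# random valid profile table (counts only, no planted structure)
randomProfiles <- function(nSpecies, nCogs, seed) {
  set.seed(seed)
  cnt <- matrix(rpois(nSpecies * nCogs, 3) + rbinom(nSpecies * nCogs, 1, 0.5),
                nSpecies, nCogs,
                dimnames = list(sprintf("sp%02d", seq_len(nSpecies)),
                                sprintf("COG%04d", seq_len(nCogs))))
  cnt[rowSums(cnt) == 0, 1] <- 1
  FunctionalProfiles(cnt)
}

# random model with interaction structure resembling 1 - Pearson
randomModel <- function(nSpecies, c, seed, hRange = c(0.2, 1)) {
  set.seed(seed)
  M <- matrix(rnorm(nSpecies * 40), nSpecies)
  A <- 1 - cor(t(M))
  diag(A) <- 0
  dimnames(A) <- list(sprintf("sp%02d", seq_len(nSpecies)),
                      sprintf("sp%02d", seq_len(nSpecies)))
  fcpModel(A, runif(nSpecies, hRange[1], hRange[2]), c)
}

randomSimplex <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rgamma(n, 1)
  x / sum(x)
}

# classical replicator integrator (c = 1), independent of the package's
# right-hand side: dx_i = x_i (f_i - fbar)
classicReplicator <- function(A, h, x0, times) {
  rhs <- function(t, x, p) {
    f <- as.vector(p$A %*% x) + p$h
    list(x * (f - sum(f * x)))
  }
  out <- deSolve::ode(x0, times, rhs, list(A = A, h = h),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}
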