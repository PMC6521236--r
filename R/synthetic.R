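# Synthetic community worlds with known ground truth: profile tables with
# planted structure-shaping COGs, correlated environments with a sparse true
# environment map, and forward-simulated compositions.

#' @include AllClasses.R dynamics.R fitting.R interaction.R
NULL

.default_factor_names <- function(n) {
  base <- c("Flow", "pH", "Temp", "Cond", "Fe2", "FeT", "Cu", "As", "Zn",
            "Ca", "SO4", "NO3", "NO2")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("Fac%02d", seq_len(n - length(base))))
}

#' Simulate a species-by-COG profile table with planted CSS genes
#'
#' Background hit counts follow a negative binomial whose per-COG base rate
#' is Gamma distributed (most COGs at 0-5 copies, as in real genomes) and
#' whose presence pattern is shared within taxon blocks, giving allied
#' species positively correlated count vectors and therefore realistic
#' similarity structure. Planted structure-shaping COGs emulate high-copy
#' mobile elements: each is present in a single species pair at large copy
#' number, so it dominates that pair's covariance and its removal measurably
#' shifts the similarity matrix. A few columns are duplicated under new ids
#' so that profile deduplication is exercised.
#'
#' @param nSpecies number of species (default 9).
#' @param nCogs number of COGs (default 300).
#' @param nPlanted number of planted structure-shaping COGs (default 30;
#'   must be below \code{nCogs}).
#' @param nBlocks number of taxon blocks (default 3).
#' @param nDuplicated number of duplicated background columns (default 8).
#' @param seed RNG seed.
#' @return list with \code{profiles} (a \code{\link{FunctionalProfiles}})
#'   and \code{planted} (character vector of planted COG ids).
#' @export
simulateProfiles <- function(nSpecies = 9L, nCogs = 300L, nPlanted = 30L,
                             nBlocks = 3L, nDuplicated = 8L, seed = 1L) {
  if (nPlanted >= nCogs) stop("nPlanted must be smaller than nCogs")
  if (nSpecies < 2L || nCogs < 2L) stop("need at least 2 species and 2 COGs")
  set.seed(seed)
  blocks <- rep_len(seq_len(nBlocks), nSpecies)
  lam <- stats::rgamma(nCogs, 2, 2)
  up <- matrix(stats::rbinom(nBlocks * nCogs, 1, 0.5), nBlocks, nCogs)
  cnt <- matrix(0, nSpecies, nCogs)
  for (i in seq_len(nSpecies)) {
    mu <- lam * (0.2 + 1.8 * up[blocks[i], ])
    cnt[i, ] <- stats::rnbinom(nCogs, mu = mu, size = 5)
  }
  pairs <- t(utils::combn(nSpecies, 2))
  pairs <- pairs[sample(nrow(pairs), nPlanted, replace = nPlanted > nrow(pairs)), ,
                 drop = FALSE]
  planted <- sample(nCogs, nPlanted)
  for (j in seq_len(nPlanted)) {
    cnt[, planted[j]] <- 0
    cnt[pairs[j, ], planted[j]] <- stats::rpois(2, 60) + 25
  }
  # guard against an (unlikely) all-zero species row
  empty <- rowSums(cnt) == 0
  if (any(empty)) cnt[empty, sample(setdiff(seq_len(nCogs), planted), 1)] <- 1
  if (nDuplicated > 0) {
    src <- sample(setdiff(seq_len(nCogs), planted), nDuplicated)
    cnt <- cbind(cnt, cnt[, src, drop = FALSE])
  }
  rownames(cnt) <- sprintf("sp%02d", seq_len(nSpecies))
  colnames(cnt) <- sprintf("COG%04d", seq_len(ncol(cnt)))
  list(profiles = FunctionalProfiles(cnt),
       planted = colnames(cnt)[planted])
}

#' Simulate environmental factors and the true model parameters
#'
#' Factors are correlated Gaussians in natural-looking units; the first two
#' factors are given high mutual correlation (emulating the tight
#' pH-temperature coupling seen in acid drainage sites). The true
#' environment map B has exactly \code{nActive} nonzero factor columns, with
#' the first active factor dominant (double weight), and the true growth
#' index is drawn uniformly from (0.3, 0.8).
#'
#' @param nSamples number of samples (default 17).
#' @param nFactors number of factors (default 13).
#' @param nActive number of factors with nonzero effect (default 3).
#' @param effectSize coefficient scale for active factors (default 0.3, in
#'   standardised-factor fitness units).
#' @param nSpecies number of species the map addresses (default 9).
#' @param seed RNG seed.
#' @return list with \code{env} (an \code{\link{EnvironmentTable}}),
#'   \code{B} (true species-by-factor map on standardised factors),
#'   \code{activeFactors}, \code{c} (true growth index) and \code{d}.
#' @export
simulateEnvironment <- function(nSamples = 17L, nFactors = 13L, nActive = 3L,
                                effectSize = 0.3, nSpecies = 9L, seed = 1L) {
  if (nActive > nFactors) stop("nActive must not exceed nFactors")
  set.seed(seed)
  fac <- .default_factor_names(nFactors)
  E <- matrix(stats::rnorm(nSamples * nFactors), nSamples, nFactors)
  if (nFactors >= 2)   # couple the first two factors (r ~ 0.85)
    E[, 2] <- 0.85 * E[, 1] + sqrt(1 - 0.85^2) * E[, 2]
  # natural-looking units: shift/scale each factor
  scl <- stats::runif(nFactors, 0.5, 20)
  ctr <- stats::runif(nFactors, 1, 40)
  E <- sweep(sweep(E, 2, scl, "*"), 2, ctr, "+")
  dimnames(E) <- list(sprintf("S%02d", seq_len(nSamples)), fac)

  active <- seq_len(nActive)
  B <- matrix(0, nSpecies, nFactors,
              dimnames = list(sprintf("sp%02d", seq_len(nSpecies)), fac))
  for (k in active) {
    w <- if (k == active[1]) 2 else 1
    B[, k] <- stats::rnorm(nSpecies, 0, effectSize * w)
  }
  list(env = EnvironmentTable(E), B = B, activeFactors = fac[active],
       c = stats::runif(1, 0.3, 0.8), d = 0.1)
}

#' Forward-simulate compositions from a true model
#'
#' For every sample: standardise its environment row over the table, form
#' the true offsets \code{h = B z(e)}, solve the dynamics to steady state
#' from a uniform start, then (optionally) apply logistic-normal observation
#' noise — Gaussian jitter of the log abundances followed by renormalisation,
#' which respects the simplex.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} (interaction matrix is
#'   built from it).
#' @param env an \code{\link{EnvironmentTable}}.
#' @param truth list with \code{B}, \code{c} (and optionally \code{d}), as
#'   from \code{\link{simulateEnvironment}}.
#' @param obsNoiseSd logistic-normal observation noise (default 0,
#'   noiseless).
#' @param seed RNG seed (used only when \code{obsNoiseSd > 0}).
#' @return an \code{\link{AbundanceTable}} of steady-state compositions.
#' @export
simulateAbundances <- function(profiles, env, truth, obsNoiseSd = 0, seed = 1L) {
  A <- interactionMatrix(profiles)
  E <- envValues(env)
  mu <- colMeans(E, na.rm = TRUE)
  sds <- apply(E, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds) | sds == 0] <- 1
  Z <- .standardise_env(E, mu, sds)
  d <- if (is.null(truth$d)) 0.1 else truth$d
  num <- nrow(A)
  x0 <- rep(1 / num, num)
  X <- matrix(NA_real_, nrow(E), num, dimnames = list(rownames(E), rownames(A)))
  for (s in seq_len(nrow(E))) {
    h <- as.vector(truth$B %*% Z[s, ])
    x <- tryCatch(.steady(A, h, truth$c, d, x0),
                  error = function(e) stop("integration failed for sample ",
                                           rownames(E)[s], ": ", conditionMessage(e)))
    X[s, ] <- x
  }
  if (obsNoiseSd > 0) {
    set.seed(seed)
    lx <- log(pmax(X, 1e-12)) +
      matrix(stats::rnorm(length(X), 0, obsNoiseSd), nrow(X))
    X <- exp(lx)
    X <- X / rowSums(X)
  }
  AbundanceTable(X)
}

#' Generate a complete synthetic world
#'
#' Bundles \code{\link{simulateProfiles}}, \code{\link{simulateEnvironment}}
#' and \code{\link{simulateAbundances}} into one reproducible object holding
#' the three data tables, the full ground truth, and the planted
#' structure-shaping COG ids. Regenerating with the same seed reproduces the
#' identical world.
#'
#' @param nSpecies,nCogs,nPlanted,nSamples,nFactors,nActive,effectSize
#'   generator settings, see the component functions.
#' @param obsNoiseSd observation noise (default 0).
#' @param seed master seed; component seeds are derived from it.
#' @return list with \code{profiles}, \code{env}, \code{abundance},
#'   \code{truth} (B, activeFactors, c, d), \code{planted} and \code{seed}.
#' @export
simulateWorld <- function(nSpecies = 9L, nCogs = 300L, nPlanted = 30L,
                          nSamples = 17L, nFactors = 13L, nActive = 3L,
                          effectSize = 0.3, obsNoiseSd = 0, seed = 1L) {
  pr <- simulateProfiles(nSpecies, nCogs, nPlanted, seed = deriveSeed(seed, "profiles"))
  envt <- simulateEnvironment(nSamples, nFactors, nActive, effectSize,
                              nSpecies = nSpecies,
                              seed = deriveSeed(seed, "environment"))
  ab <- simulateAbundances(pr$profiles, envt$env,
                           truth = envt[c("B", "c", "d")],
                           obsNoiseSd = obsNoiseSd,
                           seed = deriveSeed(seed, "noise"))
  list(profiles = pr$profiles, env = envt$env, abundance = ab,
       truth = list(B = envt$B, activeFactors = envt$activeFactors,
                    c = envt$c, d = envt$d),
       planted = pr$planted, seed = seed)
}
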