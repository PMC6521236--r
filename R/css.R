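# Community-structure-shaping (CSS) gene screen: perturbation null,
# in-silico knockouts per unique hit-number profile, aggregation over
# retained parameter groups, and the downstream enrichment / overlap tests.

#' @include AllClasses.R dynamics.R fitting.R interaction.R
NULL

#' Perturbation null distribution for knockout significance
#'
#' Builds the null against which knockout effects are judged: each replicate
#' multiplies every off-diagonal interaction entry by \code{(1 + eps)} with
#' \code{eps ~ Normal(0, noiseSd^2)} (symmetrised), recomputes the steady
#' state, and records the Bray-Curtis similarity to the unperturbed baseline.
#' The significance threshold is the one-sided lower Student-t bound
#' \code{mean(BC) - t(1 - alpha, n - 1) * sd(BC)}: a knockout whose
#' similarity falls below it changed the community more than small random
#' disturbances do. When the null has (numerically) zero spread the t test
#' has no resolution; the null is flagged degenerate and no knockout can be
#' called significant.
#'
#' @param model an \code{\link{FCPModel}} (typically the best fit of a
#'   sample).
#' @param x0 initial composition for the dynamics (default uniform).
#' @param nPerturb number of disturbances (default 10000).
#' @param noiseSd disturbance standard deviation (default 0.01, "small"
#'   relative to interaction entries of order 1).
#' @param alpha one-sided significance level (default 0.05).
#' @param seed RNG seed.
#' @return a \code{\link{PerturbationNull}}.
#' @export
perturbationNull <- function(model, x0 = NULL, nPerturb = 10000L,
                             noiseSd = 0.01, alpha = 0.05, seed = 1L) {
  if (noiseSd <= 0) stop("noiseSd must be positive")
  A <- model@A
  num <- nrow(A)
  if (is.null(x0)) x0 <- rep(1 / num, num)
  base <- .steady(A, model@h, model@c, model@d, x0)
  set.seed(seed)
  bcs <- vapply(seq_len(nPerturb), function(i) {
    E <- matrix(stats::rnorm(num * num, 0, noiseSd), num)
    E <- (E + t(E)) / 2
    Ap <- A * (1 + E)
    diag(Ap) <- 0
    xp <- .steady(Ap, model@h, model@c, model@d, x0)
    max(0, min(1, brayCurtis(xp, base)))
  }, numeric(1))
  sdv <- stats::sd(bcs)
  degenerate <- sdv < 1e-9 || (1 - mean(bcs)) < 1e-9
  thr <- if (degenerate) 1 else
    max(0, min(1, mean(bcs) - stats::qt(1 - alpha, nPerturb - 1L) * sdv))
  new("PerturbationNull", bcSamples = bcs, noiseSd = noiseSd, alpha = alpha,
      threshold = thr, degenerate = degenerate, seed = as.integer(seed))
}

#' In-silico knockout of a profile group
#'
#' Returns a copy of the profile table in which the hit counts of every COG
#' in the group are set to zero in every genome: the gene family is absent
#' from the community. Only the count columns change; similarity and
#' predictions are recomputed downstream.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object.
#' @param groups a \code{\link{ProfileGroups}} from
#'   \code{\link{dedupeProfiles}}.
#' @param id the group id to knock out.
#' @return a \code{\link{FunctionalProfiles}} with the group's columns
#'   zeroed.
#' @export
knockoutProfile <- function(profiles, groups, id) {
  cogs <- groupMembers(groups, id)
  cnt <- hitCounts(profiles)
  cnt[, cogs] <- 0
  FunctionalProfiles(cnt)
}

# knockout similarity on the raw count matrix (same pairwise double-zero
# exclusion as functionalSimilarity, warnings silenced)
.knockout_A <- function(cnt, cogs) {
  cnt[, cogs] <- 0
  S <- .pearson_pairwise(cnt)
  attr(S, "flat") <- NULL
  A <- 1 - S
  diag(A) <- 0
  A
}

#' Screen all profile groups for community-structure-shaping genes
#'
#' For every unique hit-number profile and every retained parameter group
#' (the best multi-start fits of the sample): knock the profile's COGs out,
#' rebuild the interaction matrix, recompute the steady state under that
#' parameter group's (h, c), and compare to the group's own baseline by
#' Bray-Curtis. A profile is CSS under a parameter group when its knockout
#' similarity falls below the perturbation-null threshold; its CSS
#' probability is the fraction of parameter groups flagging it. The fitted
#' offsets and growth index are retained at knockout: losing a gene changes
#' the functional similarity structure, not the environment.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object.
#' @param fits a \code{\link{SampleFitSet}} for the sample being screened.
#' @param null a \code{\link{PerturbationNull}} built on the same sample.
#' @param x0 initial composition for the dynamics (default uniform).
#' @param nParamGroups number of best-objective fits to retain (default 50;
#'   fewer with a warning when not enough starts converged).
#' @param catmap optional \code{\link{CogCategoryMap}} for annotation.
#' @return a \code{\link{CSSResult}} sorted by probability (descending, ties
#'   by group id).
#' @export
screenCSS <- function(profiles, fits, null, x0 = NULL, nParamGroups = 50L,
                      catmap = NULL) {
  cnt <- hitCounts(profiles)
  num <- nrow(cnt)
  if (is.null(x0)) x0 <- rep(1 / num, num)
  groups <- dedupeProfiles(profiles)
  ng <- length(groups@ids)
  np <- min(nParamGroups, length(fits@c))
  if (np < nParamGroups)
    warning("only ", np, " converged fits available (requested ",
            nParamGroups, ")")
  H <- fits@h[seq_len(np), , drop = FALSE]
  cs <- fits@c[seq_len(np)]

  A0 <- .knockout_A(cnt, character(0))
  baselines <- lapply(seq_len(np), function(p)
    .steady(A0, H[p, ], cs[p], 0.1, x0))

  ind <- matrix(FALSE, ng, np)
  meanBC <- numeric(ng)
  for (g in seq_len(ng)) {
    Ag <- .knockout_A(cnt, groups@members[[g]])
    if (max(abs(Ag - A0)) == 0) {
      # knockout leaves the similarity structure untouched (e.g. all-zero
      # counts): BC is exactly 1, never CSS
      meanBC[g] <- 1
      next
    }
    bcs <- vapply(seq_len(np), function(p) {
      xk <- .steady(Ag, H[p, ], cs[p], 0.1, x0)
      max(0, min(1, brayCurtis(xk, baselines[[p]])))
    }, numeric(1))
    meanBC[g] <- mean(bcs)
    if (!null@degenerate) ind[g, ] <- bcs < null@threshold
  }

  prob <- rowMeans(ind)
  members <- vapply(groups@members, paste, character(1), collapse = ",")
  cats <- if (is.null(catmap)) rep("", ng) else
    vapply(groups@members, function(m)
      paste(sort(unique(unlist(strsplit(cogCategories(catmap, m), "")))),
            collapse = ""), character(1))
  tab <- data.frame(profileId = groups@ids, memberCogs = members,
                    probability = prob, meanKnockoutBC = meanBC,
                    categories = cats, stringsAsFactors = FALSE)
  ord <- order(-tab$probability, tab$profileId)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  new("CSSResult", table = tab, indicators = ind[ord, , drop = FALSE],
      threshold = null@threshold)
}

#' Screen every sample and assemble the community-wide CSS catalog
#'
#' Runs the full per-sample workflow — multi-start fit, perturbation null,
#' knockout screen — for each requested sample and assembles the catalog of
#' community-structure-shaping genes across samples. A profile group enters
#' the catalog when its knockout moves the predicted composition beyond the
#' null threshold in at least one sample: a gene can only shape the
#' structure of communities in which the species carrying it are actually
#' present, so per-sample calls are complementary.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object.
#' @param abundance an \code{\link{AbundanceTable}}.
#' @param samples sample ids to screen (default: all).
#' @param nStarts random starts per sample fit (default 60).
#' @param nPerturb disturbances per null (default 10000).
#' @param nParamGroups retained parameter groups (default 50).
#' @param noiseSd,alpha null settings, see \code{\link{perturbationNull}}.
#' @param catmap optional \code{\link{CogCategoryMap}}.
#' @param seed master seed; per-sample seeds are derived from it.
#' @return list with \code{perSample} (named list of \code{\link{CSSResult}}),
#'   \code{catalog} (profile groups called in at least one sample),
#'   \code{callRates} (fraction of groups called per sample) and
#'   \code{probabilities} (group-by-sample CSS probability matrix).
#' @export
screenAllSamples <- function(profiles, abundance, samples = NULL,
                             nStarts = 60L, nPerturb = 10000L,
                             nParamGroups = 50L, noiseSd = 0.01,
                             alpha = 0.05, catmap = NULL, seed = 1L) {
  A <- interactionMatrix(profiles)
  X <- abundances(abundance)[, rownames(A), drop = FALSE]
  if (is.null(samples)) samples <- rownames(X)
  if (!all(samples %in% rownames(X)))
    stop("unknown samples: ", paste(setdiff(samples, rownames(X)), collapse = ", "))
  groups <- dedupeProfiles(profiles)
  perSample <- list()
  probs <- matrix(NA_real_, length(groupIds(groups)), length(samples),
                  dimnames = list(groupIds(groups), samples))
  for (s in samples) {
    fits <- fitSample(A, X[s, ], nStarts = nStarts, sampleId = s,
                      seed = deriveSeed(seed, paste0("fit:", s)))
    best <- fcpModel(A, fits@h[1L, ], fits@c[1L])
    null <- perturbationNull(best, nPerturb = nPerturb, noiseSd = noiseSd,
                             alpha = alpha,
                             seed = deriveSeed(seed, paste0("null:", s)))
    css <- screenCSS(profiles, fits, null, nParamGroups = nParamGroups,
                     catmap = catmap)
    perSample[[s]] <- css
    tab <- cssTable(css)
    probs[tab$profileId, s] <- tab$probability
  }
  called <- lapply(perSample, function(css) {
    tab <- cssTable(css)
    tab$profileId[tab$probability >= 0.5]
  })
  list(perSample = perSample,
       catalog = sort(unique(unlist(called))),
       callRates = vapply(called, length, 1L) / length(groupIds(groups)),
       probabilities = probs)
}

#' COGs called CSS at a probability cutoff
#'
#' @param css a \code{\link{CSSResult}}.
#' @param cutoff minimum CSS probability (default 0.5).
#' @return character vector of member COG ids of all groups at or above the
#'   cutoff.
#' @export
cssCogs <- function(css, cutoff = 0.5) {
  sel <- css@table$probability >= cutoff & css@table$probability > 0
  unlist(strsplit(css@table$memberCogs[sel], ",", fixed = TRUE), use.names = FALSE)
}

#' Functional-category enrichment of a gene set
#'
#' For each one-letter COG category, tests whether membership in the query
#' set (e.g. the CSS genes) is associated with membership in the category by
#' a two-sided Fisher's exact test on the 2x2 table over the background set.
#' A COG with several categories counts once in each. Raw p values are
#' reported together with Benjamini-Hochberg adjusted ones; categories with
#' no background members are skipped.
#'
#' @param css character vector of query COG ids (subset of background).
#' @param background character vector of background COG ids.
#' @param catmap a \code{\link{CogCategoryMap}}.
#' @return an \code{\link{EnrichmentReport}}.
#' @export
enrichmentTest <- function(css, background, catmap) {
  if (!length(background)) stop("background set is empty")
  if (!all(css %in% background)) stop("css must be a subset of background")
  css <- unique(css)
  background <- unique(background)
  cats <- cogCategories(catmap, background)
  has <- function(letter) names(cats)[grepl(letter, cats, fixed = TRUE)]
  rows <- lapply(COG_CATEGORY_ALPHABET, function(letter) {
    inCat <- has(letter)
    if (!length(inCat)) return(NULL)
    a <- sum(css %in% inCat)
    b <- length(css) - a
    cc <- length(inCat) - a
    d <- length(background) - length(css) - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "two.sided")
    data.frame(category = letter, cssInCat = a, cssNotInCat = b,
               bgInCat = cc, bgNotInCat = d,
               oddsRatio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  skipped <- COG_CATEGORY_ALPHABET[vapply(rows, is.null, logical(1))]
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) stop("no category has background members")
  tab$pAdj <- stats::p.adjust(tab$p, method = "BH")
  rownames(tab) <- NULL
  rep <- new("EnrichmentReport", table = tab)
  if (length(skipped))
    attr(rep, "skipped") <- skipped
  rep
}

#' Permutation test for the overlap of two gene sets
#'
#' Draws \code{nPerm} random sets of the size of \code{setA} from the
#' universe and counts how often their overlap with \code{setB} reaches the
#' observed one; the empirical p value uses add-one smoothing,
#' \code{(count + 1) / (nPerm + 1)}.
#'
#' @param setA,setB character vectors, both subsets of \code{universe}.
#' @param universe character vector of all candidate ids.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with \code{observed} (overlap size) and \code{p}.
#' @export
overlapPermutationTest <- function(setA, setB, universe, nPerm = 10000L,
                                   seed = 1L) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  if (length(setA) > length(universe)) stop("set larger than universe")
  obs <- length(intersect(setA, setB))
  set.seed(seed)
  hits <- sum(vapply(seq_len(nPerm), function(i) {
    length(intersect(sample(universe, length(setA)), setB)) >= obs
  }, logical(1)))
  list(observed = obs, p = (hits + 1) / (nPerm + 1))
}
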