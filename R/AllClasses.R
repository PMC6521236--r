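# S4 containers for the community model: functional-gene profiles, sample
# metadata, model parameters, trajectories and screening results.

#' @include AllGenerics.R
NULL

COG_CATEGORY_ALPHABET <- c("J", "K", "L", "V", "T", "M", "N", "U", "O", "X",
                           "C", "G", "E", "F", "H", "I", "P", "R", "S")

#' Species-by-COG functional gene profiles
#'
#' Holds the hit numbers of every COG (cluster of orthologous groups, a family
#' of homologous genes) in every species' genome or bin. These count vectors
#' are the raw material for the functional similarity matrix: two species are
#' functionally similar when their COG count vectors are correlated.
#'
#' @slot counts non-negative integer matrix, species in rows, COGs in columns,
#'   with unique dimnames.
#' @export
setClass("FunctionalProfiles", representation(counts = "matrix"))

setValidity("FunctionalProfiles", function(object) {
  cnt <- object@counts
  if (!is.numeric(cnt)) return("counts must be numeric")
  if (nrow(cnt) < 2L || ncol(cnt) < 2L)
    return("need at least 2 species and 2 COGs")
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    return("counts must carry species and COG ids as dimnames")
  if (anyDuplicated(rownames(cnt)))
    return(paste("duplicate species ids:",
                 paste(unique(rownames(cnt)[duplicated(rownames(cnt))]), collapse = ", ")))
  if (anyDuplicated(colnames(cnt)))
    return(paste("duplicate COG ids:",
                 paste(unique(colnames(cnt)[duplicated(colnames(cnt))]), collapse = ", ")))
  if (anyNA(cnt)) return("counts contain missing values")
  if (any(cnt < 0)) return("counts must be non-negative")
  if (max(abs(cnt - round(cnt))) > 1e-8) return("counts must be integer-valued")
  TRUE
})

#' Construct a FunctionalProfiles object
#'
#' @param counts species-by-COG matrix of non-negative integer hit numbers
#'   with species ids as rownames and COG ids as colnames.
#' @return a validated \code{FunctionalProfiles} object.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("spA", "spB"), c("COG0001", "COG0002")))
#' FunctionalProfiles(m)
#' @export
FunctionalProfiles <- function(counts) {
  storage.mode(counts) <- "double"
  new("FunctionalProfiles", counts = counts)
}

#' Sample-by-factor environmental measurements
#'
#' Raw (unstandardised) measurements of environmental factors, one row per
#' sample. Missing measurements are stored as \code{NA}; standardisation and
#' imputation happen at model-fitting time so the raw data stay inspectable.
#'
#' @slot values numeric matrix, samples in rows, factors in columns; may
#'   contain \code{NA}.
#' @export
setClass("EnvironmentTable", representation(values = "matrix"))

setValidity("EnvironmentTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample ids and factor names as dimnames")
  if (anyDuplicated(rownames(v))) return("duplicate sample ids")
  if (anyDuplicated(colnames(v))) return("duplicate factor names")
  bad <- rowMeans(is.na(v)) > 0.5
  if (any(bad))
    return(paste("samples with more than half of factors missing:",
                 paste(rownames(v)[bad], collapse = ", ")))
  TRUE
})

#' Construct an EnvironmentTable
#'
#' @param values numeric sample-by-factor matrix (NA allowed, but every
#'   retained sample must have more than half of its factors measured).
#' @return an \code{EnvironmentTable}.
#' @export
EnvironmentTable <- function(values) {
  storage.mode(values) <- "double"
  new("EnvironmentTable", values = values)
}

#' Sample-by-species relative abundances
#'
#' Community compositions on the simplex: every row is a sample whose species
#' relative abundances sum to one.
#'
#' @slot x numeric matrix in [0, 1], rows summing to 1 within 1e-6.
#' @export
setClass("AbundanceTable", representation(x = "matrix"))

setValidity("AbundanceTable", function(object) {
  x <- object@x
  if (!is.numeric(x)) return("abundances must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("abundances must carry sample and species ids as dimnames")
  if (anyDuplicated(rownames(x))) return("duplicate sample ids")
  if (anyDuplicated(colnames(x))) return("duplicate species ids")
  if (anyNA(x)) return("abundances contain missing values")
  if (any(x < 0) || any(x > 1)) return("abundances must lie in [0, 1]")
  if (any(abs(rowSums(x) - 1) > 1e-6))
    return("every row must sum to 1 within 1e-6")
  TRUE
})

#' Construct an AbundanceTable
#'
#' @param x numeric sample-by-species matrix of relative abundances; rows must
#'   sum to 1 within 1e-6.
#' @return an \code{AbundanceTable}.
#' @export
AbundanceTable <- function(x) {
  storage.mode(x) <- "double"
  new("AbundanceTable", x = x)
}

#' COG-to-functional-category map
#'
#' Maps each COG id to one or more one-letter functional categories (J, K, L,
#' V, T, M, N, U, O, X, C, G, E, F, H, I, P, R, S), stored as a concatenated
#' string per COG (e.g. \code{"KT"}).
#'
#' @slot categories named character vector, names are COG ids, values are
#'   strings of category letters.
#' @export
setClass("CogCategoryMap", representation(categories = "character"))

setValidity("CogCategoryMap", function(object) {
  m <- object@categories
  if (is.null(names(m)) || anyDuplicated(names(m)))
    return("categories must be named by unique COG ids")
  letters_used <- unique(unlist(strsplit(m, "")))
  bad <- setdiff(letters_used, COG_CATEGORY_ALPHABET)
  if (length(bad))
    return(paste("unknown category letters:", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a CogCategoryMap
#'
#' @param categories named character vector mapping COG ids to concatenated
#'   one-letter category strings.
#' @return a \code{CogCategoryMap}.
#' @export
CogCategoryMap <- function(categories) new("CogCategoryMap", categories = categories)

#' Replicator-dynamics community model with variable population size
#'
#' Parameters of the dynamics: the interaction matrix \code{A} (pairwise
#' benefit from functional dissimilarity, \code{A = 1 - S} with S the Pearson
#' similarity of COG count vectors), the environmental fitness offsets
#' \code{h}, the growth index \code{c} (sub-exponential growth, 0 < c < 1;
#' c = 1 is admitted as the classical replicator limit), and the death rate
#' \code{d}. The fitness of species i at composition x is
#' \code{f_i = (A x)_i + h_i}.
#'
#' @slot A symmetric interaction matrix with zero diagonal, species ids as
#'   dimnames.
#' @slot h numeric vector of per-species environmental fitness offsets.
#' @slot c growth index in (0, 1].
#' @slot d death rate, > 0 (affects only total population size, not
#'   composition).
#' @export
setClass("FCPModel",
         representation(A = "matrix", h = "numeric", c = "numeric", d = "numeric"))

setValidity("FCPModel", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("A must be square")
  if (nrow(A) != length(object@h)) return("dimensions of A and h must agree")
  if (is.null(rownames(A))) return("A must carry species ids as dimnames")
  if (max(abs(A - t(A))) > 1e-8) return("A must be symmetric")
  if (max(abs(diag(A))) > 1e-12) return("A must have zero diagonal")
  if (length(object@c) != 1 || object@c <= 0 || object@c > 1)
    return("growth index c must lie in (0, 1]")
  if (length(object@d) != 1 || object@d <= 0) return("death rate d must be > 0")
  TRUE
})

#' Construct an FCPModel
#'
#' @param A symmetric interaction matrix (zero diagonal) with species ids as
#'   dimnames.
#' @param h numeric vector of environmental fitness offsets, one per species.
#' @param c growth index in (0, 1]; values below 1 give the sub-exponential
#'   regime of oligotrophic communities.
#' @param d death rate (> 0); the composition dynamics are invariant to it.
#' @return an \code{FCPModel}.
#' @export
fcpModel <- function(A, h, c, d = 0.1) {
  if (is.null(names(h))) names(h) <- rownames(A)
  new("FCPModel", A = A, h = as.numeric(h), c = c, d = d)
}

#' Community trajectory
#'
#' Time course of the community composition x (on the simplex) and the total
#' population size N under the replicator dynamics.
#'
#' @slot times strictly increasing time points.
#' @slot x matrix of compositions, one row per time point.
#' @slot N population sizes at the stored times.
#' @slot converged whether the composition reached the steady-state tolerance
#'   before \code{tMax}.
#' @slot tConverged time at which convergence was detected (NA if not).
#' @export
setClass("Trajectory",
         representation(times = "numeric", x = "matrix", N = "numeric",
                        converged = "logical", tConverged = "numeric"))

setValidity("Trajectory", function(object) {
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (length(object@times) != nrow(object@x)) return("times/x length mismatch")
  if (length(object@times) != length(object@N)) return("times/N length mismatch")
  if (max(abs(rowSums(object@x) - 1)) > 1e-6)
    return("stored compositions must lie on the simplex")
  TRUE
})

#' Per-sample multi-start fit of the community model
#'
#' Results of fitting the environmental offsets h and growth index c to one
#' observed composition from many random initial values, sorted by final loss.
#' Reported h values are in the canonical gauge (see the methods vignette):
#' the fitness scale is not identifiable from a composition, so h is reported
#' with the fitness vector normalised to \code{sum(f^(1/(1-c))) == 1}.
#'
#' @slot sampleId sample label.
#' @slot h matrix of fitted offsets, one row per retained start.
#' @slot c fitted growth indices, one per retained start.
#' @slot objective final sum-of-squares loss per start.
#' @slot bc Bray-Curtis similarity of fitted vs observed composition.
#' @slot composition fitted steady-state compositions, one row per start.
#' @slot nStarts number of random starts requested.
#' @slot seed RNG seed used for the starts.
#' @export
setClass("SampleFitSet",
         representation(sampleId = "character", h = "matrix", c = "numeric",
                        objective = "numeric", bc = "numeric",
                        composition = "matrix", nStarts = "integer",
                        seed = "integer"))

setValidity("SampleFitSet", function(object) {
  if (any(object@c <= 0 | object@c >= 1)) return("fitted c must lie in (0, 1)")
  if (any(object@bc < 0 | object@bc > 1)) return("bc must lie in [0, 1]")
  if (is.unsorted(object@objective)) return("fits must be sorted by objective")
  TRUE
})

#' Environment-to-fitness map learned by Lasso
#'
#' Sparse linear map from standardised environmental factors to the
#' per-species fitness offsets: \code{h = B z(e) + intercept}, where z uses
#' the training-set means and standard deviations. Carries the consensus
#' growth index used at prediction time and the per-sample fitness scales
#' profiled out during fitting.
#'
#' @slot B species-by-factor coefficient matrix (exact zeros allowed).
#' @slot intercept per-species intercept.
#' @slot factorMeans,factorSds training-set standardisation constants.
#' @slot lambda regularisation weight used per species.
#' @slot c consensus growth index.
#' @slot scales per-training-sample fitness scales (profiled; diagnostics).
#' @export
setClass("EnvMap",
         representation(B = "matrix", intercept = "numeric",
                        factorMeans = "numeric", factorSds = "numeric",
                        lambda = "numeric", c = "numeric", scales = "numeric"))

setValidity("EnvMap", function(object) {
  if (nrow(object@B) != length(object@intercept))
    return("B rows and intercept length must agree")
  if (ncol(object@B) != length(object@factorMeans))
    return("B columns and factor constants must agree")
  if (object@c <= 0 || object@c >= 1) return("consensus c must lie in (0, 1)")
  TRUE
})

#' Held-out prediction report
#'
#' Observed and predicted compositions for validation samples together with
#' the summary statistics used to judge the model: per-sample Bray-Curtis
#' similarity, and the pooled predicted-vs-observed linear regression over all
#' species-sample pairs.
#'
#' @slot observed,predicted sample-by-species composition matrices.
#' @slot bc per-sample Bray-Curtis similarities.
#' @slot r2,slope,intercept pooled regression of predicted on observed.
#' @export
setClass("PredictionReport",
         representation(observed = "matrix", predicted = "matrix",
                        bc = "numeric", r2 = "numeric", slope = "numeric",
                        intercept = "numeric"))

setValidity("PredictionReport", function(object) {
  if (!all(dim(object@observed) == dim(object@predicted)))
    return("observed/predicted dimensions must agree")
  if (any(object@bc < 0 | object@bc > 1)) return("bc must lie in [0, 1]")
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  TRUE
})

#' Perturbation null distribution for the knockout screen
#'
#' Bray-Curtis similarities between the baseline steady state and steady
#' states under small stochastic disturbances of the interaction matrix,
#' with the one-sided Student-t threshold below which a knockout is called a
#' significant change. A null with numerically zero spread is flagged
#' degenerate: the t test has no resolution and no knockout can be declared
#' significant (threshold reported as 1).
#'
#' @slot bcSamples null Bray-Curtis similarities, one per disturbance.
#' @slot noiseSd standard deviation of the multiplicative disturbance.
#' @slot alpha one-sided significance level.
#' @slot threshold similarity threshold (calls require BC < threshold).
#' @slot degenerate whether the null had no usable spread.
#' @slot seed RNG seed.
#' @export
setClass("PerturbationNull",
         representation(bcSamples = "numeric", noiseSd = "numeric",
                        alpha = "numeric", threshold = "numeric",
                        degenerate = "logical", seed = "integer"))

setValidity("PerturbationNull", function(object) {
  if (any(object@bcSamples < -1e-12 | object@bcSamples > 1 + 1e-12))
    return("bcSamples must lie in [0, 1]")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  TRUE
})

#' Unique hit-number profile groups
#'
#' COGs whose hit-number vectors across species are identical are
#' indistinguishable to the similarity matrix; they are screened as one unit.
#' Groups are ordered lexicographically by profile vector.
#'
#' @slot profiles group-by-species matrix of hit numbers (one row per unique
#'   profile).
#' @slot members list of COG id vectors, one per group.
#' @slot ids group identifiers.
#' @export
setClass("ProfileGroups",
         representation(profiles = "matrix", members = "list", ids = "character"))

setValidity("ProfileGroups", function(object) {
  if (nrow(object@profiles) != length(object@members))
    return("profiles/members length mismatch")
  if (length(object@ids) != length(object@members))
    return("ids/members length mismatch")
  if (anyDuplicated(unlist(object@members)))
    return("a COG may belong to only one group")
  TRUE
})

#' Result of the community-structure-shaping gene screen
#'
#' Per unique hit-number profile group: the fraction of retained parameter
#' groups under which its in-silico knockout moved the predicted composition
#' beyond the perturbation-null threshold (the CSS probability), the mean
#' knockout Bray-Curtis similarity, member COGs and category annotations.
#'
#' @slot table data.frame sorted by probability (descending, ties by group
#'   id) with columns profileId, memberCogs, probability, meanKnockoutBC,
#'   categories.
#' @slot indicators logical matrix, groups x parameter groups.
#' @slot threshold the null threshold used.
#' @export
setClass("CSSResult",
         representation(table = "data.frame", indicators = "matrix",
                        threshold = "numeric"))

setValidity("CSSResult", function(object) {
  p <- object@table$probability
  if (any(p < 0 | p > 1)) return("probability must lie in [0, 1]")
  if (nrow(object@table) != nrow(object@indicators))
    return("table/indicators row mismatch")
  if (max(abs(sort(p, decreasing = TRUE) - p)) > 0)
    return("table must be sorted by probability (descending)")
  TRUE
})

#' COG-category enrichment report
#'
#' Two-by-two Fisher's exact test per functional category: membership in the
#' CSS set versus membership in the category, over a background COG set.
#' Benjamini-Hochberg adjusted p values are reported alongside the raw ones.
#'
#' @slot table data.frame with one row per category: counts, odds ratio,
#'   p value and BH-adjusted p value.
#' @export
setClass("EnrichmentReport", representation(table = "data.frame"))

# ---- accessors ----------------------------------------------------------

#' @describeIn speciesIds species of a profile table
#' @export
setMethod("speciesIds", "FunctionalProfiles", function(object) rownames(object@counts))

#' @describeIn speciesIds species of an abundance table
#' @export
setMethod("speciesIds", "AbundanceTable", function(object) colnames(object@x))

#' @describeIn speciesIds species of a model
#' @export
setMethod("speciesIds", "FCPModel", function(object) rownames(object@A))

#' @describeIn sampleIds samples of an environment table
#' @export
setMethod("sampleIds", "EnvironmentTable", function(object) rownames(object@values))

#' @describeIn sampleIds samples of an abundance table
#' @export
setMethod("sampleIds", "AbundanceTable", function(object) rownames(object@x))

#' @describeIn cogIds COGs of a profile table
#' @export
setMethod("cogIds", "FunctionalProfiles", function(object) colnames(object@counts))

#' @describeIn hitCounts counts of a profile table
#' @export
setMethod("hitCounts", "FunctionalProfiles", function(object) object@counts)

#' Environmental measurement matrix
#'
#' @param object an \code{EnvironmentTable}.
#' @return numeric sample-by-factor matrix (raw units, NA for missing).
#' @export
envValues <- function(object) object@values

#' Missingness mask of an environment table
#'
#' @param object an \code{EnvironmentTable}.
#' @return logical matrix, TRUE where a measurement is missing.
#' @export
missingMask <- function(object) is.na(object@values)

#' Relative abundance matrix
#'
#' @param object an \code{AbundanceTable}.
#' @return numeric sample-by-species matrix on the simplex.
#' @export
abundances <- function(object) object@x

#' Categories of a set of COGs
#'
#' @param object a \code{CogCategoryMap}.
#' @param cogs COG ids to look up (default: all mapped COGs).
#' @return named character vector of concatenated category letters; unmapped
#'   COGs get \code{""}.
#' @export
cogCategories <- function(object, cogs = NULL) {
  if (is.null(cogs)) return(object@categories)
  out <- object@categories[cogs]
  out[is.na(out)] <- ""
  names(out) <- cogs
  out
}

#' Interaction matrix of a model
#'
#' @param object an \code{FCPModel}.
#' @return the symmetric interaction matrix A.
#' @export
modelInteraction <- function(object) object@A

#' Environmental offsets of a model
#' @param object an \code{FCPModel}.
#' @return numeric vector h.
#' @export
modelOffsets <- function(object) object@h

#' Growth index of a model
#' @param object an \code{FCPModel}.
#' @return the growth index c.
#' @export
growthIndex <- function(object) object@c

#' Screening table of a CSS result
#' @param object a \code{CSSResult}.
#' @return the sorted per-profile-group data.frame.
#' @export
cssTable <- function(object) object@table

#' Enrichment table
#' @param object an \code{EnrichmentReport}.
#' @return per-category data.frame.
#' @export
enrichmentTable <- function(object) object@table

#' Coefficients of an environment map
#' @param object an \code{EnvMap}.
#' @return species-by-factor coefficient matrix B.
#' @export
envCoefficients <- function(object) object@B

# ---- show methods -------------------------------------------------------

setMethod("show", "FunctionalProfiles", function(object) {
  cat("FunctionalProfiles:", nrow(object@counts), "species x",
      ncol(object@counts), "COGs\n")
  cat("  species:", paste(utils::head(rownames(object@counts), 4), collapse = ", "),
      if (nrow(object@counts) > 4) "...\n" else "\n")
})

setMethod("show", "EnvironmentTable", function(object) {
  cat("EnvironmentTable:", nrow(object@values), "samples x",
      ncol(object@values), "factors;",
      sum(is.na(object@values)), "missing cells\n")
})

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object@x), "samples x", ncol(object@x), "species\n")
})

setMethod("show", "FCPModel", function(object) {
  cat("FCPModel:", nrow(object@A), "species; c =", format(object@c),
      "; d =", format(object@d), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points,",
      ncol(object@x), "species;",
      if (object@converged) paste("converged at t =", format(object@tConverged))
      else "not converged", "\n")
})

setMethod("show", "SampleFitSet", function(object) {
  cat("SampleFitSet for", object@sampleId, ":", length(object@c),
      "retained fits of", object@nStarts, "starts\n")
  cat("  best objective:", format(object@objective[1], digits = 4),
      "; best BC:", format(object@bc[1], digits = 4), "\n")
})

setMethod("show", "EnvMap", function(object) {
  cat("EnvMap:", nrow(object@B), "species x", ncol(object@B), "factors;",
      sum(object@B != 0), "nonzero coefficients; c =", format(object@c), "\n")
})

setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport:", nrow(object@observed), "samples\n")
  cat(sprintf("  Bray-Curtis = %.4f +/- %.4f; R2 = %.4f; y = %.3fx + %.4f\n",
              mean(object@bc), stats::sd(object@bc), object@r2,
              object@slope, object@intercept))
})

setMethod("show", "PerturbationNull", function(object) {
  cat("PerturbationNull:", length(object@bcSamples), "disturbances; noiseSd =",
      format(object@noiseSd), "; threshold =", format(object@threshold, digits = 6),
      if (object@degenerate) "(degenerate)" else "", "\n")
})

setMethod("show", "ProfileGroups", function(object) {
  cat("ProfileGroups:", length(object@ids), "unique profiles over",
      length(unlist(object@members)), "COGs\n")
})

setMethod("show", "CSSResult", function(object) {
  cat("CSSResult:", nrow(object@table), "profile groups;",
      sum(object@table$probability >= 0.5), "with probability >= 0.5\n")
})

setMethod("show", "EnrichmentReport", function(object) {
  cat("EnrichmentReport:", nrow(object@table), "categories;",
      sum(object@table$p < 0.05), "with raw p < 0.05\n")
})
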