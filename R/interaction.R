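# Functional similarity and interaction matrices, and deduplication of COGs
# into unique hit-number profiles.

#' @include AllClasses.R
NULL

#' Pairwise functional similarity between species
#'
#' Computes the Pearson correlation coefficient between the COG hit-count
#' vectors of every pair of species. A high correlation means two genomes use
#' functional genes similarly; environmental filtering pushes cooccurring
#' species towards such similarity, while competition pushes them apart.
#'
#' Correlations are computed on raw counts by default; Pearson is location
#' and scale invariant, so per-genome totals largely cancel. The alternative
#' \code{normalize = "proportion"} correlates per-species COG frequencies
#' instead, for sensitivity analysis.
#'
#' Each pair is correlated only over the COGs present in at least one of the
#' two genomes (double-zero exclusion, the standard treatment of shared
#' absences in community ecology): a gene family observed in neither genome
#' says nothing about their functional relationship. This makes the
#' similarity invariant to padding the table with unobserved COGs, and an
#' in-silico knockout of a COG can only change the rows and columns of the
#' species that actually carry it.
#'
#' A pair whose masked count vectors have zero variance (all counts
#' identical) has no defined correlation; such entries are set to 0
#' (neutral) with a warning rather than propagating NaN.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object.
#' @param normalize \code{"none"} (raw counts, default) or
#'   \code{"proportion"}.
#' @return symmetric similarity matrix S with unit diagonal, entries in
#'   [-1, 1], species ids as dimnames.
#' @export
functionalSimilarity <- function(profiles, normalize = c("none", "proportion")) {
  normalize <- match.arg(normalize)
  cnt <- hitCounts(profiles)
  present <- cnt > 0
  if (normalize == "proportion") {
    tot <- rowSums(cnt)
    tot[tot == 0] <- 1
    cnt <- cnt / tot
  }
  S <- .pearson_pairwise(cnt, present)
  if (length(attr(S, "flat")))
    warning("pairs with zero-variance count vectors (similarity set to 0), ",
            "involving: ", paste(attr(S, "flat"), collapse = ", "))
  attr(S, "flat") <- NULL
  S
}

# Pearson over the union support of each pair; undefined (zero-variance)
# pairs get 0 and are reported via the "flat" attribute
.pearson_pairwise <- function(cnt, present = cnt > 0) {
  n <- nrow(cnt)
  S <- diag(1, n)
  dimnames(S) <- list(rownames(cnt), rownames(cnt))
  flat <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mask <- present[i, ] | present[j, ]
      if (sum(mask) >= 2) {
        r <- suppressWarnings(stats::cor(cnt[i, mask], cnt[j, mask]))
      } else r <- NA_real_
      if (is.na(r)) {
        flat <- c(flat, rownames(cnt)[c(i, j)])
        r <- 0
      }
      S[i, j] <- S[j, i] <- r
    }
  }
  attr(S, "flat") <- unique(flat)
  S
}

#' Interaction (dissimilarity-benefit) matrix
#'
#' \code{A = L - S}, where L is the all-ones matrix and S the functional
#' similarity: the benefit two species draw from functional cooperation grows
#' with their dissimilarity, while functionally identical species gain little
#' from each other because they compete for the same resources. Entries lie
#' in [0, 2] with an exactly zero diagonal.
#'
#' @param S a similarity matrix from \code{\link{functionalSimilarity}}, or a
#'   \code{\link{FunctionalProfiles}} object (similarity computed first).
#' @param ... passed to \code{functionalSimilarity} when \code{S} is a
#'   profile table.
#' @return symmetric interaction matrix A.
#' @export
interactionMatrix <- function(S, ...) {
  if (methods::is(S, "FunctionalProfiles")) S <- functionalSimilarity(S, ...)
  A <- 1 - S
  diag(A) <- 0
  A
}

#' Group COGs by identical hit-number profile
#'
#' Two COGs with the same integer vector of hit numbers across all species
#' are indistinguishable to the similarity matrix, so the knockout screen
#' works in units of unique profiles. Grouping uses exact integer equality;
#' groups are ordered lexicographically by profile vector and named
#' \code{P0001, P0002, ...}.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object.
#' @return a \code{\link{ProfileGroups}} object.
#' @export
dedupeProfiles <- function(profiles) {
  cnt <- hitCounts(profiles)
  key <- apply(cnt, 2, paste, collapse = "\r")
  groups <- split(colnames(cnt), key)
  prof <- do.call(rbind, lapply(strsplit(names(groups), "\r", fixed = TRUE), as.numeric))
  ord <- do.call(order, as.data.frame(prof))
  prof <- prof[ord, , drop = FALSE]
  groups <- groups[ord]
  ids <- sprintf("P%04d", seq_along(groups))
  rownames(prof) <- ids
  colnames(prof) <- rownames(cnt)
  new("ProfileGroups", profiles = prof, members = unname(groups), ids = ids)
}

#' Members of a profile group
#'
#' @param groups a \code{\link{ProfileGroups}} object.
#' @param id a group id (e.g. \code{"P0007"}).
#' @return character vector of member COG ids.
#' @export
groupMembers <- function(groups, id) {
  i <- match(id, groups@ids)
  if (is.na(i)) stop("unknown profile group: ", id)
  groups@members[[i]]
}

#' Ids of all profile groups
#' @param groups a \code{\link{ProfileGroups}} object.
#' @return character vector of group ids.
#' @export
groupIds <- function(groups) groups@ids
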