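# Readers and writers for the tab-separated interchange formats. All tables
# are UTF-8 TSV with a mandatory header row; the first column holds row ids.

#' @include AllClasses.R
NULL

.read_tsv_matrix <- function(path, what) {
  if (!file.exists(path)) stop("cannot read ", what, ": no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "ND", ""))
  if (ncol(df) < 2) stop(what, ": expected an id column plus data columns")
  ids <- as.character(df[[1]])
  cn <- colnames(df)[-1]   # data.frame subsetting would de-duplicate names
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- cn
  if (!is.numeric(m)) {
    # locate the offending cell for a useful error
    for (j in seq_len(ncol(m))) {
      v <- suppressWarnings(as.numeric(df[[j + 1]]))
      bad <- which(is.na(v) & !is.na(df[[j + 1]]))
      if (length(bad))
        stop(what, ": malformed numeric cell at row '", ids[bad[1]],
             "', column '", colnames(m)[j], "': '", df[bad[1], j + 1], "'")
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  m
}

.check_unique <- function(ids, what) {
  if (anyDuplicated(ids))
    stop("duplicate ", what, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
}

#' Read a species-by-COG hit-count table
#'
#' Expects a tab-separated file with a header row of COG ids and a first
#' column of species labels. Row and column order are preserved. Species whose
#' count vector is all zero are rejected: their Pearson correlation with any
#' other species is undefined, and failing fast beats silent imputation.
#'
#' @param path path to the TSV file.
#' @return a validated \code{\link{FunctionalProfiles}} object.
#' @export
readProfileTable <- function(path) {
  m <- .read_tsv_matrix(path, "profile table")
  .check_unique(rownames(m), "species ids")
  .check_unique(colnames(m), "COG ids")
  if (anyNA(m)) stop("profile table: missing values are not allowed")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("profile table: species with all-zero counts: ",
         paste(rownames(m)[zero], collapse = ", "))
  FunctionalProfiles(m)
}

#' Read a sample-by-environmental-factor table
#'
#' Values are stored raw (unstandardised); blank, \code{NA} and \code{ND}
#' cells become missing values. Samples with more than half of their factors
#' missing are dropped with a warning, mirroring the usual sample filter for
#' sparsely measured sites.
#'
#' @param path path to the TSV file.
#' @return an \code{\link{EnvironmentTable}}.
#' @export
readEnvTable <- function(path) {
  m <- .read_tsv_matrix(path, "environment table")
  .check_unique(rownames(m), "sample ids")
  .check_unique(colnames(m), "factor names")
  bad <- rowMeans(is.na(m)) > 0.5
  if (any(bad)) {
    warning("dropping ", sum(bad), " sample(s) with more than half of factors missing: ",
            paste(rownames(m)[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  EnvironmentTable(m)
}

#' Read a sample-by-species relative-abundance table
#'
#' Rows are renormalised to sum exactly to one (observed compositions often
#' exclude a small unassigned fraction); the original row sums are reported
#' via a message when the deviation exceeds 1e-6. Negative entries are an
#' error.
#'
#' @param path path to the TSV file.
#' @return an \code{\link{AbundanceTable}}.
#' @export
readAbundanceTable <- function(path) {
  m <- .read_tsv_matrix(path, "abundance table")
  .check_unique(rownames(m), "sample ids")
  .check_unique(colnames(m), "species ids")
  if (anyNA(m)) stop("abundance table: missing values are not allowed")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("abundance table: negative abundance at row '", rownames(m)[bad[1]],
         "', column '", colnames(m)[bad[2]], "'")
  }
  s <- rowSums(m)
  if (any(s <= 0)) stop("abundance table: a sample row sums to zero")
  off <- abs(s - 1) > 1e-6
  if (any(off))
    message("renormalising ", sum(off), " row(s); original sums: ",
            paste(sprintf("%s=%.4f", rownames(m)[off], s[off]), collapse = ", "))
  AbundanceTable(m / s)
}

#' Read a COG-to-category map
#'
#' Two-column TSV: COG id, concatenated one-letter functional categories
#' (e.g. \code{"KT"}).
#'
#' @param path path to the TSV file.
#' @return a \code{\link{CogCategoryMap}}.
#' @export
readCogCategoryMap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("category map: expected two columns (cog_id, categories)")
  .check_unique(df[[1]], "COG ids")
  m <- df[[2]]
  names(m) <- df[[1]]
  CogCategoryMap(m)
}

# fixed float format: 6 significant digits, byte-stable across runs
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

.write_tsv <- function(df, path, idName = NULL, ids = NULL) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  if (!is.null(ids)) df <- cbind(stats::setNames(data.frame(ids, stringsAsFactors = FALSE), idName), df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

.matrix_to_df <- function(m) as.data.frame(m, check.names = FALSE, stringsAsFactors = FALSE)

#' @describeIn writeResults species-by-COG counts as TSV
#' @export
setMethod("writeResults", "FunctionalProfiles", function(object, path) {
  .write_tsv(.matrix_to_df(object@counts), path, "species_id", rownames(object@counts))
})

#' @describeIn writeResults sample-by-factor values as TSV (NA for missing)
#' @export
setMethod("writeResults", "EnvironmentTable", function(object, path) {
  .write_tsv(.matrix_to_df(object@values), path, "sample_id", rownames(object@values))
})

#' @describeIn writeResults sample-by-species abundances as TSV
#' @export
setMethod("writeResults", "AbundanceTable", function(object, path) {
  .write_tsv(.matrix_to_df(object@x), path, "sample_id", rownames(object@x))
})

#' @describeIn writeResults square similarity/interaction matrix as TSV
#' @export
setMethod("writeResults", "matrix", function(object, path) {
  .write_tsv(.matrix_to_df(object), path, "id", rownames(object))
})

#' @describeIn writeResults long-format trajectory (time, species, x, N)
#' @export
setMethod("writeResults", "Trajectory", function(object, path) {
  sp <- colnames(object@x)
  df <- data.frame(
    time = rep(object@times, times = length(sp)),
    species = rep(sp, each = length(object@times)),
    x = as.vector(object@x),
    N = rep(object@N, times = length(sp)),
    stringsAsFactors = FALSE)
  .write_tsv(df, path)
})

#' @describeIn writeResults observed and predicted compositions per sample
#' @export
setMethod("writeResults", "PredictionReport", function(object, path) {
  sp <- colnames(object@observed)
  sm <- rownames(object@observed)
  df <- data.frame(
    sample_id = rep(sm, each = length(sp)),
    species = rep(sp, times = length(sm)),
    observed = as.vector(t(object@observed)),
    predicted = as.vector(t(object@predicted)),
    stringsAsFactors = FALSE)
  .write_tsv(df, path)
})

#' @describeIn writeResults per-profile-group CSS screen as TSV
#' @export
setMethod("writeResults", "CSSResult", function(object, path) {
  .write_tsv(object@table, path)
})

#' @describeIn writeResults per-category enrichment as TSV
#' @export
setMethod("writeResults", "EnrichmentReport", function(object, path) {
  .write_tsv(object@table, path)
})

#' @describeIn writeResults category map as two-column TSV
#' @export
setMethod("writeResults", "CogCategoryMap", function(object, path) {
  df <- data.frame(cog_id = names(object@categories),
                   categories = unname(object@categories),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
})

#' @describeIn writeResults any plain data.frame as TSV
#' @export
setMethod("writeResults", "data.frame", function(object, path) {
  .write_tsv(object, path)
})
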