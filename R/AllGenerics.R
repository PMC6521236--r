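#' Species identifiers of an object
#'
#' @param object a \code{FunctionalProfiles}, \code{AbundanceTable} or
#'   \code{FCPModel}.
#' @return character vector of taxon labels, in stored order.
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' Sample identifiers of an object
#'
#' @param object an \code{EnvironmentTable} or \code{AbundanceTable}.
#' @return character vector of sample labels.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' COG identifiers of a profile table
#'
#' @param object a \code{FunctionalProfiles} object.
#' @return character vector of COG ids, in stored column order.
#' @export
setGeneric("cogIds", function(object) standardGeneric("cogIds"))

#' Hit-count matrix of a profile table
#'
#' @param object a \code{FunctionalProfiles} object.
#' @return integer matrix, species in rows, COGs in columns.
#' @export
setGeneric("hitCounts", function(object) standardGeneric("hitCounts"))

#' Write a result object to a deterministic plain-text file
#'
#' All tabular objects are written as UTF-8 tab-separated files with a header
#' row; floating point values are rounded to 6 significant digits so that the
#' same object always produces byte-identical output.
#'
#' @param object the object to serialise.
#' @param path output file path.
#' @return invisibly, the path written.
#' @export
setGeneric("writeResults", function(object, path) standardGeneric("writeResults"))
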