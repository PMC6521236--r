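# Run configuration, seed derivation, and provenance manifests shared by
# every command.

#' Default run configuration
#'
#' All tunables in one flat list: dynamics tolerances, fitting bounds and
#' start counts, screening settings, and the master seed from which every
#' stochastic operation derives its own seed. Values given as arguments
#' override the defaults; unknown keys are an error so typos fail loudly.
#'
#' @param ... named overrides of the defaults.
#' @return named list with a \code{configHash} attribute.
#' @export
fcpConfig <- function(...) {
  cfg <- list(
    seed = 1L,            # master seed
    nStarts = 100L,       # random starts per sample fit
    cBounds = c(0.05, 0.95),
    hBound = 10,          # box bound on offsets
    tol = 1e-8,           # steady-state tolerance for integration
    tMax = 500,           # integration horizon
    d = 0.1,              # death rate
    N0 = 1000,            # initial population size
    penalty = "cv",       # Lasso penalty or "cv"
    growthIndex = "profile",  # consensus-c rule: profile | median | numeric
    nParamGroups = 50L,   # parameter groups retained for the CSS screen
    nPerturb = 10000L,    # disturbances per perturbation null
    noiseSd = 0.01,       # disturbance sd
    alpha = 0.05,         # one-sided significance level
    folds = 5L,           # cross-validation folds
    similarityNormalize = "none")  # none | proportion
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  attr(cfg, "configHash") <- configHash(cfg)
  cfg
}

#' Stable hash of a configuration
#'
#' Small FNV-1a hash over the deparsed key-sorted configuration; stable
#' across sessions, used to stamp manifests.
#'
#' @param cfg a configuration list.
#' @return 8-character hexadecimal string.
#' @export
configHash <- function(cfg) {
  attr(cfg, "configHash") <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Every stochastic operation gets its own seed, computed from the master
#' seed and a short label, so that independent steps draw independent
#' streams while the whole run stays reproducible from one integer.
#'
#' @param seed master seed (integer).
#' @param label short string naming the consumer.
#' @return integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 69069 + b) %% 2147483647
  as.integer(h + 1)
}

#' Read a flat YAML configuration file
#'
#' @param path YAML file with a flat key-value mapping.
#' @return configuration list (validated against the known keys).
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(fcpConfig, vals)
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list from \code{\link{fcpConfig}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeConfig <- function(cfg, path) {
  attr(cfg, "configHash") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records input-file checksums, the configuration (with hash), seeds,
#' package version and wall time next to every command's outputs, so any
#' result can be traced to its exact inputs.
#'
#' @param path manifest path (JSON).
#' @param command command name.
#' @param inputs named character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @param cfg configuration list.
#' @param elapsed elapsed wall time in seconds.
#' @return invisibly, the path.
#' @export
writeManifest <- function(path, command, inputs, outputs, cfg, elapsed) {
  sums <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list()
  attrless <- cfg
  attr(attrless, "configHash") <- NULL
  obj <- list(command = command,
              package = "fcpcomm",
              version = as.character(utils::packageVersion("fcpcomm")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              inputs = sums,
              outputs = as.list(outputs),
              config = attrless,
              configHash = configHash(cfg),
              seed = cfg$seed,
              elapsedSeconds = round(elapsed, 3))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
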