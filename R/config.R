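#' @title Run configuration for the amplicon pipeline
#'
#' @description
#' Holds every tunable threshold of the pipeline: the mean-quality and length
#' filters, the OTU clustering identity, the taxonomic-assignment thresholds
#' (identity, query coverage, e-value), the read-merging constraints, and the
#' random seed. All identity/coverage values are fractions in (0, 1].
#'
#' @slot minQual Phred threshold for the per-read quality filter (default 30).
#' @slot minLen Minimum read length in bases after trimming (default 100);
#'   reads of exactly `minLen` are kept.
#' @slot otuIdentity OTU clustering identity threshold (default 0.98).
#' @slot minAssignIdentity Assignment identity threshold, strict `>` (default 0.98).
#' @slot minAssignCoverage Assignment query-coverage threshold, strict `>`
#'   (default 0.98).
#' @slot maxEvalue Assignment e-value threshold, strict `<` (default 1e-50).
#' @slot mergeMinOverlap Minimum ungapped overlap for read merging, in bases
#'   (default 20).
#' @slot mergeMaxMismatchFrac Maximum mismatch fraction tolerated in the
#'   merge overlap (default 0.1).
#' @slot qualMode Quality-filter semantics: `"mean"` (mean Phred, the
#'   default), `"min"` (per-base minimum), or `"ee"` (expected errors).
#' @slot maxExpectedErrors Expected-error cutoff used when `qualMode == "ee"`
#'   (default 1.0).
#' @slot seed Integer random seed.
#'
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig", slots = c(
  minQual = "numeric",
  minLen = "numeric",
  otuIdentity = "numeric",
  minAssignIdentity = "numeric",
  minAssignCoverage = "numeric",
  maxEvalue = "numeric",
  mergeMinOverlap = "numeric",
  mergeMaxMismatchFrac = "numeric",
  qualMode = "character",
  maxExpectedErrors = "numeric",
  seed = "numeric"
))

setValidity("RunConfig", function(object) {
  errs <- character()
  fr <- c(otuIdentity = object@otuIdentity,
          minAssignIdentity = object@minAssignIdentity,
          minAssignCoverage = object@minAssignCoverage)
  bad <- fr <= 0 | fr > 1
  if (any(bad)) {
    errs <- c(errs, paste0(names(fr)[bad], " must be in (0, 1]"))
  }
  if (object@mergeMaxMismatchFrac < 0 || object@mergeMaxMismatchFrac > 1) {
    errs <- c(errs, "mergeMaxMismatchFrac must be in [0, 1]")
  }
  nonneg <- c(minQual = object@minQual, minLen = object@minLen,
              maxEvalue = object@maxEvalue,
              mergeMinOverlap = object@mergeMinOverlap,
              maxExpectedErrors = object@maxExpectedErrors)
  if (any(nonneg < 0)) {
    errs <- c(errs, paste0(names(nonneg)[nonneg < 0], " must be non-negative"))
  }
  if (!object@qualMode %in% c("mean", "min", "ee")) {
    errs <- c(errs, "qualMode must be one of 'mean', 'min', 'ee'")
  }
  if (length(errs)) errs else TRUE
})

#' Create a run configuration
#'
#' @param minQual,minLen,otuIdentity,minAssignIdentity,minAssignCoverage
#'   See the [RunConfig-class] slots.
#' @param maxEvalue,mergeMinOverlap,mergeMaxMismatchFrac,qualMode
#'   See the [RunConfig-class] slots.
#' @param maxExpectedErrors,seed See the [RunConfig-class] slots.
#' @return A validated [RunConfig-class] object.
#' @examples
#' runConfig(minQual = 25, seed = 42)
#' @export
runConfig <- function(minQual = 30, minLen = 100, otuIdentity = 0.98,
                      minAssignIdentity = 0.98, minAssignCoverage = 0.98,
                      maxEvalue = 1e-50, mergeMinOverlap = 20,
                      mergeMaxMismatchFrac = 0.1, qualMode = "mean",
                      maxExpectedErrors = 1.0, seed = 1L) {
  new("RunConfig", minQual = minQual, minLen = minLen,
      otuIdentity = otuIdentity, minAssignIdentity = minAssignIdentity,
      minAssignCoverage = minAssignCoverage, maxEvalue = maxEvalue,
      mergeMinOverlap = mergeMinOverlap,
      mergeMaxMismatchFrac = mergeMaxMismatchFrac, qualMode = qualMode,
      maxExpectedErrors = maxExpectedErrors, seed = as.numeric(seed))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; '#' starts a comment; unknown keys are an
#' error. Keys are the [runConfig()] argument names. Values override the
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A [RunConfig-class] object.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(runConfig))) stop("unknown config key: ", key)
    args[[key]] <- if (key == "qualMode") val else as.numeric(val)
  }
  do.call(runConfig, args)
}

#' @describeIn runConfig Display a configuration.
#' @param object A `RunConfig` object.
#' @export
setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  for (sl in slotNames(object)) {
    cat(sprintf("  %-22s %s\n", sl, format(slot(object, sl))))
  }
  invisible(NULL)
})
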