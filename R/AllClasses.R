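#' @import methods
#' @importFrom stats density approx isoreg runif rnorm setNames
#' @importFrom utils read.delim write.table
NULL

## Tag vocabularies shared across the package. Charge states above +3 are
## collapsed into "gt3" and tryptic status is full/half/non, giving the
## 12 validation subgroups.
.chargeClasses <- c("1", "2", "3", "gt3")
.trypticStatuses <- c("full", "half", "non")
.histoneFamilies <- c("H2A", "H2B", "H3", "H4", "H1", "variant", "other")
.speciesTags <- c("celegans", "mouse", "synthetic")
.aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Charge and tryptic-status vocabularies
#'
#' Constants used throughout the package: the four charge classes
#' (\code{"1"}, \code{"2"}, \code{"3"}, \code{"gt3"}) and the three tryptic
#' statuses (\code{"full"}, \code{"half"}, \code{"non"}) whose cross product
#' defines the 12 PSM validation subgroups.
#'
#' @return A character vector of tags.
#' @export
chargeClasses <- function() .chargeClasses

#' @rdname chargeClasses
#' @export
trypticStatuses <- function() .trypticStatuses

#' Per-subgroup PSM validation model
#'
#' Holds, for each of the 12 charge-by-tryptic-status subgroups, a linear
#' discriminant over (XCorr, DeltaCN, |DeltaMass ppm|), kernel density
#' estimates of the projected scores for direct (target-matched) and decoy
#' PSMs, the decoy/direct mixture weight, and the isotonicised posterior
#' probability curve. Subgroups with fewer than \code{nMin} members per class
#' fall back to a pooled model fitted on all PSMs.
#'
#' @slot subgroups Named list (keys \code{"<charge>:<tryptic>"}); each element
#'   is either a fit (see Details) or \code{NULL} when the pooled fallback is
#'   used for that subgroup.
#' @slot pooled The pooled fallback fit.
#' @slot decoyPrefix Protein id prefix identifying decoy records.
#' @slot nMin Minimum per-class PSM count required for a subgroup-specific fit.
#'
#' A fit is a list with elements \code{weights} (the discriminant 3-vector),
#' \code{grid}, \code{densDirect}, \code{densDecoy}, \code{prob} (posterior on
#' the grid, nondecreasing), \code{piIncorrect}, \code{nDirect}, \code{nDecoy}.
#'
#' @seealso [fitValidationModel()], [scoreProbability()]
#' @export
setClass("ValidationModel",
  representation(subgroups = "list", pooled = "list",
                 decoyPrefix = "character", nMin = "numeric"))

setValidity("ValidationModel", function(object) {
  msg <- character(0)
  checkFit <- function(fit, label) {
    out <- character(0)
    if (!is.finite(fit$piIncorrect) || fit$piIncorrect < 0 || fit$piIncorrect > 1)
      out <- c(out, sprintf("%s: piIncorrect must lie in [0,1]", label))
    dx <- diff(fit$grid)
    for (dens in c("densDirect", "densDecoy")) {
      y <- fit[[dens]]
      area <- sum((y[-1] + y[-length(y)]) / 2 * dx)
      if (abs(area - 1) > 1e-3)
        out <- c(out, sprintf("%s: %s integrates to %.5f on its grid", label, dens, area))
    }
    if (is.unsorted(fit$prob))
      out <- c(out, sprintf("%s: posterior curve is not nondecreasing", label))
    out
  }
  msg <- c(msg, checkFit(object@pooled, "pooled"))
  for (key in names(object@subgroups)) {
    fit <- object@subgroups[[key]]
    if (!is.null(fit)) msg <- c(msg, checkFit(fit, key))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ValidationModel Compact display of fitted subgroups.
#' @param object A \code{ValidationModel}.
#' @export
setMethod("show", "ValidationModel", function(object) {
  own <- sum(!vapply(object@subgroups, is.null, logical(1)))
  cat("ValidationModel:", own, "of", length(object@subgroups),
      "subgroups with dedicated fits;",
      length(object@subgroups) - own, "using the pooled fallback\n")
  cat(sprintf("  pooled pi_incorrect = %.4f (direct n = %d, decoy n = %d)\n",
              object@pooled$piIncorrect, object@pooled$nDirect,
              object@pooled$nDecoy))
  invisible(object)
})

#' Accessors for ValidationModel
#'
#' @param model A [ValidationModel-class] object.
#' @return \code{modelSubgroups()} returns the named list of subgroup fits
#'   (\code{NULL} entries use the pooled fallback); \code{pooledFit()} the
#'   pooled fit; \code{fallbackUsed()} a named logical vector over subgroups.
#' @export
modelSubgroups <- function(model) model@subgroups

#' @rdname modelSubgroups
#' @export
pooledFit <- function(model) model@pooled

#' @rdname modelSubgroups
#' @export
fallbackUsed <- function(model)
  vapply(model@subgroups, is.null, logical(1))

#' Histone PTM occurrence census
#'
#' Occurrence counts of census-countable modifications (ac, me1, me2, me3)
#' indexed by histone family, residue site in the query species' post-Met
#' numbering, the corresponding reference-species site where a cross-species
#' pairing is available, PTM type, and sample. Ubiquitination (masked by the
#' iodoacetamide adduct), phosphorylation, fixed carbamidomethylation and
#' residue-inconsistent assignments are kept separately in the flagged table
#' rather than counted.
#'
#' @slot counts data.frame with columns \code{histone_family},
#'   \code{protein_id}, \code{ce_site}, \code{ref_site}, \code{ptm_type},
#'   \code{sample}, \code{occurrences}.
#' @slot flagged data.frame with the same site columns plus \code{reason}.
#' @export
setClass("CensusTable",
  representation(counts = "data.frame", flagged = "data.frame"))

.censusCols <- c("histone_family", "protein_id", "ce_site", "ref_site",
                 "ptm_type", "sample", "occurrences")
.countablePTMs <- c("ac", "me1", "me2", "me3")

setValidity("CensusTable", function(object) {
  msg <- character(0)
  if (!all(.censusCols %in% names(object@counts)))
    msg <- c(msg, "counts is missing required columns")
  else {
    occ <- object@counts$occurrences
    if (length(occ) && (any(occ < 0) || any(occ != round(occ))))
      msg <- c(msg, "occurrences must be nonnegative integers")
    if (length(occ) && !all(object@counts$ptm_type %in% .countablePTMs))
      msg <- c(msg, "counts may only contain census-countable PTM types (ac/me1/me2/me3)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CensusTable Summary of counted and flagged occurrences.
#' @param object A \code{CensusTable}.
#' @export
setMethod("show", "CensusTable", function(object) {
  cts <- object@counts
  cat("CensusTable:", sum(cts$occurrences), "counted occurrences at",
      nrow(unique(cts[c("histone_family", "ce_site", "ptm_type")])),
      "distinct marks across", length(unique(cts$sample)), "sample(s)\n")
  if (nrow(object@flagged))
    cat("  flagged (excluded):", sum(object@flagged$occurrences),
        "occurrences [", paste(unique(object@flagged$reason), collapse = ", "),
        "]\n")
  invisible(object)
})

#' Accessors for CensusTable
#'
#' @param census A [CensusTable-class] object.
#' @return \code{censusCounts()} the counted-occurrence data.frame;
#'   \code{flaggedModifications()} the excluded/flagged data.frame.
#' @export
censusCounts <- function(census) census@counts

#' @rdname censusCounts
#' @export
flaggedModifications <- function(census) census@flagged
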