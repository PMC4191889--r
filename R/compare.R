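## Round half-up (the convention of the printed percentages), avoiding R's
## round-half-to-even.
.roundHalfUp <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Modified-spectrum fraction of a sample
#'
#' Percentage of histone spectra that carry a counted PTM:
#' \code{100 * ptm_spectra / total_spectra}, rounded half-up to one decimal
#' to match the reporting precision.
#'
#' @param ptm_spectra Number of PTM-bearing histone spectra.
#' @param total_spectra Total histone spectra (> 0).
#' @param digits Decimal places (default 1); \code{NULL} for no rounding.
#' @return Percentage.
#' @examples
#' modifiedFraction(127, 7190)  # 1.8
#' modifiedFraction(253, 5998)  # 4.2
#' @export
modifiedFraction <- function(ptm_spectra, total_spectra, digits = 1) {
  if (total_spectra <= 0) stop("total_spectra must be positive")
  if (ptm_spectra < 0 || ptm_spectra > total_spectra)
    stop("ptm_spectra must lie in [0, total_spectra]")
  x <- 100 * ptm_spectra / total_spectra
  if (is.null(digits)) x else .roundHalfUp(x, digits)
}

#' Fold ratio of two modified fractions
#'
#' Ratio of two (unrounded) percentages, rounded half-up to one decimal.
#' Reported as embryo/sperm in the pipeline, so values above 1 mean the
#' sperm sample is depleted of PTMs relative to embryos.
#'
#' @param frac_a,frac_b Unrounded percentages; \code{frac_b} must be > 0.
#' @param digits Decimal places (default 1); \code{NULL} for no rounding.
#' @return Ratio.
#' @export
foldRatio <- function(frac_a, frac_b, digits = 1) {
  if (any(frac_b <= 0)) stop("denominator fraction must be positive")
  x <- frac_a / frac_b
  if (is.null(digits)) x else .roundHalfUp(x, digits)
}

#' Variant enrichment between two samples
#'
#' Flags histone variants as sample-specific when their spectral count is
#' positive in one sample and zero in the other; otherwise reports the ratio
#' of family-normalised proportions.
#'
#' @param counts_a,counts_b Named numeric vectors of per-variant spectral
#'   counts in the two samples (same names).
#' @param total_a,total_b Family-total spectral counts in each sample (> 0).
#' @param labels Length-2 character, the two sample labels.
#' @return data.frame with per-variant counts, proportions, the a/b
#'   proportion ratio (NA when undefined) and a \code{flag} column
#'   (\code{"<label>-specific"}, \code{"absent"} or \code{"none"}).
#' @export
variantEnrichment <- function(counts_a, counts_b, total_a, total_b,
                              labels = c("a", "b")) {
  stopifnot(total_a > 0, total_b > 0,
            identical(names(counts_a), names(counts_b)))
  propA <- counts_a / total_a
  propB <- counts_b / total_b
  flag <- rep("none", length(counts_a))
  flag[counts_a > 0 & counts_b == 0] <- paste0(labels[1], "-specific")
  flag[counts_b > 0 & counts_a == 0] <- paste0(labels[2], "-specific")
  flag[counts_a == 0 & counts_b == 0] <- "absent"
  ratio <- ifelse(flag == "none", propA / propB, NA_real_)
  data.frame(variant = names(counts_a),
             count_a = unname(counts_a), count_b = unname(counts_b),
             prop_a = unname(propA), prop_b = unname(propB),
             ratio = unname(ratio), flag = flag, stringsAsFactors = FALSE)
}

#' Summarise one sample
#'
#' Collects the per-sample comparative statistics: totals, modified
#' fraction and distinct-mark count.
#'
#' @param sample Sample label.
#' @param total_spectra Total histone spectra in the sample.
#' @param ptm_spectra PTM-bearing histone spectra in the sample.
#' @param census Optional [CensusTable-class] for the distinct-mark count.
#' @return One-row data.frame.
#' @export
sampleSummary <- function(sample, total_spectra, ptm_spectra, census = NULL) {
  data.frame(sample = sample,
             total_histone_spectra = total_spectra,
             ptm_histone_spectra = ptm_spectra,
             modified_fraction_percent = modifiedFraction(ptm_spectra,
                                                          total_spectra),
             distinct_marks = if (is.null(census)) NA_integer_
                              else distinctMarks(census, sample),
             stringsAsFactors = FALSE)
}
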