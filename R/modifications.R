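#' Differential modification mass table
#'
#' The fixed table of modification mass deltas used to assign PTM types to
#' search-reported mass shifts: acetylation (+42.0106 Da, K),
#' mono/di/tri-methylation (+14.0157 / +28.0314 / +42.0471 Da, K and R),
#' phosphorylation (+79.9663 Da, S/T/Y), ubiquitination (+114.042927 Da, K;
#' indistinguishable from the iodoacetamide lysine adduct and therefore not
#' counted in the census) and the fixed cysteine carbamidomethylation
#' (+57.02146 Da). Acetylation and tri-methylation are separated by
#' 0.0365 Da, which the default 0.005 Da tolerance resolves cleanly.
#'
#' @return data.frame with columns \code{ptm_type}, \code{delta} (Da),
#'   \code{residues} (comma-joined allowed amino acids) and
#'   \code{counted_in_census}.
#' @export
modificationTable <- function() {
  data.frame(
    ptm_type = c("ac", "me1", "me2", "me3", "ph", "ub", "carbamidomethyl"),
    delta = c(42.0106, 14.0157, 28.0314, 42.0471, 79.9663, 114.042927,
              57.02146),
    residues = c("K", "K,R", "K,R", "K,R", "S,T,Y", "K", "C"),
    counted_in_census = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Assign a PTM type from a mass delta and residue
#'
#' Matches an observed modification mass delta against the fixed modification
#' table, requiring both the delta (within \code{tolerance}) and the modified
#' residue to be consistent with the PTM type.
#'
#' @param delta_mass Observed modification mass shift in Da.
#' @param residue_letter Single amino-acid letter carrying the modification.
#' @param tolerance Matching tolerance in Da (> 0); default 0.005.
#' @return One-row data.frame (a row of [modificationTable()]).
#'   Errors if no type matches or if the tolerance windows of several types
#'   overlap the observed delta.
#' @examples
#' annotateMod(42.0106, "K")$ptm_type   # "ac"
#' annotateMod(42.0471, "K")$ptm_type   # "me3"
#' @export
annotateMod <- function(delta_mass, residue_letter, tolerance = 0.005) {
  stopifnot(length(delta_mass) == 1, length(residue_letter) == 1)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive mass in Da")
  tab <- modificationTable()
  hitDelta <- abs(tab$delta - delta_mass) <= tolerance
  if (sum(hitDelta) > 1)
    stop(sprintf("ambiguous modification: delta %+0.4f Da matches %s within %g Da",
                 delta_mass, paste(tab$ptm_type[hitDelta], collapse = " and "),
                 tolerance))
  hit <- hitDelta & vapply(strsplit(tab$residues, ","), function(rs)
    residue_letter %in% rs, logical(1))
  if (!any(hit))
    stop(sprintf("no modification type matches delta %+0.4f Da on residue %s",
                 delta_mass, residue_letter))
  tab[hit, , drop = FALSE]
}

## Vectorised, non-throwing annotation used by the census: returns ptm_type
## plus a status distinguishing residue conflicts from unknown deltas.
.annotateModStatus <- function(delta_mass, residue_letter, tolerance = 0.005) {
  tab <- modificationTable()
  allowed <- strsplit(tab$residues, ",")
  n <- length(delta_mass)
  ptm <- rep(NA_character_, n)
  status <- rep("unannotated", n)
  for (i in seq_len(n)) {
    hitDelta <- which(abs(tab$delta - delta_mass[i]) <= tolerance)
    if (length(hitDelta) == 0L) next
    if (length(hitDelta) > 1L) { status[i] <- "ambiguous"; next }
    ptm[i] <- tab$ptm_type[hitDelta]
    if (!(residue_letter[i] %in% allowed[[hitDelta]])) {
      status[i] <- "residue_conflict"
    } else if (!tab$counted_in_census[hitDelta] || ptm[i] == "ph") {
      ## ub is mass-degenerate with the alkylation artifact and
      ## carbamidomethylation is a fixed chemical modification; phospho sites
      ## are censused separately because no enrichment chemistry backs them.
      status[i] <- "excluded"
    } else {
      status[i] <- "counted"
    }
  }
  data.frame(ptm_type = ptm, status = status, stringsAsFactors = FALSE)
}
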