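#' Assign PSMs to charge-by-tryptic-status subgroups
#'
#' Search results are grouped by charge state (+1, +2, +3, greater than +3)
#' and tryptic status (fully, half, non-tryptic), yielding 12 distinct
#' subgroups that are modelled separately during validation.
#'
#' @param charge_class Character vector of charge tags
#'   (\code{chargeClasses()}), or a PSM data.frame holding
#'   \code{charge_class} and \code{tryptic_status} columns.
#' @param tryptic_status Character vector of tryptic tags; ignored when a
#'   data.frame is supplied.
#' @return Character vector of subgroup keys \code{"<charge>:<tryptic>"}.
#' @export
assignSubgroup <- function(charge_class, tryptic_status) {
  if (is.data.frame(charge_class)) {
    tryptic_status <- charge_class$tryptic_status
    charge_class <- charge_class$charge_class
  }
  charge_class <- as.character(charge_class)
  tryptic_status <- as.character(tryptic_status)
  bad <- !(charge_class %in% .chargeClasses)
  if (any(bad))
    stop("unknown charge_class tag '", charge_class[which(bad)[1]],
         "'; expected one of ", paste(.chargeClasses, collapse = ", "))
  bad <- !(tryptic_status %in% .trypticStatuses)
  if (any(bad))
    stop("unknown tryptic_status tag '", tryptic_status[which(bad)[1]],
         "'; expected one of ", paste(.trypticStatuses, collapse = ", "))
  paste(charge_class, tryptic_status, sep = ":")
}

## TRUE where every matched protein id carries the decoy prefix.
.psmIsDecoy <- function(protein_ids, decoy_prefix = "Reverse_") {
  vapply(strsplit(protein_ids, ",", fixed = TRUE), function(ids)
    length(ids) > 0 && all(startsWith(ids, decoy_prefix)), logical(1))
}

## Fit one two-class linear discriminant + KDE posterior on a PSM subset.
## X: n x 3 matrix (xcorr, deltacn, |delta_mass_ppm|); isDecoy: logical.
.fitSubgroup <- function(X, isDecoy) {
  nDec <- sum(isDecoy); nDir <- sum(!isDecoy)
  if (nDec < 2L || nDir < 2L) return(NULL)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) return(NULL)
  fit <- tryCatch(
    MASS::lda(X[, keep, drop = FALSE], grouping = factor(isDecoy)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  w <- numeric(ncol(X))
  w[keep] <- fit$scaling[, 1]
  s <- drop(X %*% w)
  ## orient so higher score means more direct-like
  if (mean(s[!isDecoy]) < mean(s[isDecoy])) { w <- -w; s <- -s }
  bwDir <- stats::bw.nrd0(s[!isDecoy])
  bwDec <- stats::bw.nrd0(s[isDecoy])
  bw <- max(bwDir, bwDec, 1e-6)
  grid <- seq(min(s) - 4 * bw, max(s) + 4 * bw, length.out = 512)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
  dDir <- density(s[!isDecoy], bw = max(bwDir, 1e-6), n = 512,
                  from = grid[1], to = grid[512])$y
  dDec <- density(s[isDecoy], bw = max(bwDec, 1e-6), n = 512,
                  from = grid[1], to = grid[512])$y
  ## renormalise on the evaluation grid so each density integrates to 1 there
  dDir <- dDir / trapz(dDir)
  dDec <- dDec / trapz(dDec)
  piInc <- min(1, nDec / nDir)
  ## Posterior that a direct PSM at score s is a correct match. The direct
  ## KDE estimates the observed direct mixture; pi_incorrect rescales the
  ## decoy KDE into its incorrect component. Raw KDE ratios can wiggle, so
  ## monotonicity in s is enforced by isotonic regression along the grid
  ## (before clipping: clipping first would bias the null upward).
  post <- 1 - piInc * dDec / pmax(dDir, 1e-12)
  post <- pmin(1, pmax(0, isoreg(grid, post)$yf))
  post <- cummax(post)  # squash float-level wiggles left by isoreg
  list(weights = w, grid = grid, densDirect = dDir, densDecoy = dDec,
       prob = post, piIncorrect = piInc, nDirect = nDir, nDecoy = nDec)
}

#' Fit the per-subgroup validation model
#'
#' Splits PSMs into the 12 charge-by-tryptic subgroups and, in each subgroup
#' with at least \code{n_min} direct and \code{n_min} decoy members, fits a
#' two-class linear discriminant (pooled covariance) on
#' (XCorr, DeltaCN, |DeltaMass ppm|) followed by Gaussian-kernel density
#' estimates (Silverman bandwidth, 512-point grid spanning the observed
#' scores) of the projected scores for the direct and decoy classes. The
#' decoy/direct count ratio, capped at 1, serves as the incorrect-match
#' mixture weight. Subgroups below \code{n_min} fall back to a pooled model
#' fitted on all PSMs.
#'
#' @param psms PSM data.frame (see [simulatePSMs()] for the schema).
#' @param decoy_prefix Id prefix identifying decoy protein matches.
#' @param n_min Minimum per-class PSM count for a subgroup-specific fit.
#' @return A [ValidationModel-class] object.
#' @export
fitValidationModel <- function(psms, decoy_prefix = "Reverse_", n_min = 50) {
  isDecoy <- .psmIsDecoy(psms$protein_ids, decoy_prefix)
  if (!any(isDecoy))
    stop("no decoy PSMs: the validation model cannot be calibrated")
  if (all(isDecoy))
    stop("no direct PSMs: nothing to validate")
  X <- cbind(psms$xcorr, psms$deltacn, abs(psms$delta_mass_ppm))
  pooled <- .fitSubgroup(X, isDecoy)
  if (is.null(pooled))
    stop("pooled model could not be fitted (need >= 2 PSMs per class with score variance)")
  keys <- assignSubgroup(psms)
  allKeys <- as.vector(outer(.chargeClasses, .trypticStatuses, paste, sep = ":"))
  subgroups <- setNames(vector("list", length(allKeys)), allKeys)
  for (key in allKeys) {
    sel <- keys == key
    if (sum(sel & isDecoy) >= n_min && sum(sel & !isDecoy) >= n_min)
      subgroups[[key]] <- .fitSubgroup(X[sel, , drop = FALSE], isDecoy[sel])
  }
  new("ValidationModel", subgroups = subgroups, pooled = pooled,
      decoyPrefix = decoy_prefix, nMin = n_min)
}

## Fit used for a subgroup key (dedicated or pooled fallback).
.fitFor <- function(model, key) {
  fit <- model@subgroups[[key]]
  if (is.null(fit)) model@pooled else fit
}

#' Discriminant scores under a validation model
#'
#' Projects PSM score triples onto each PSM's subgroup discriminant axis
#' (pooled fallback where the subgroup has no dedicated fit). Exposed mainly
#' so that the monotonicity of [scoreProbability()] in the discriminant
#' score can be examined.
#'
#' @param model A fitted [ValidationModel-class].
#' @param psms PSM data.frame.
#' @return Numeric vector of discriminant scores.
#' @export
discriminantScores <- function(model, psms) {
  X <- cbind(psms$xcorr, psms$deltacn, abs(psms$delta_mass_ppm))
  keys <- assignSubgroup(psms)
  s <- numeric(nrow(psms))
  for (key in unique(keys)) {
    fit <- .fitFor(model, key)
    sel <- keys == key
    s[sel] <- drop(X[sel, , drop = FALSE] %*% fit$weights)
  }
  s
}

#' Posterior peptide probabilities
#'
#' Evaluates, for each PSM, the posterior probability that it is a correct
#' match: \code{clip(1 - pi_incorrect * f_decoy(s) / f_direct(s), 0, 1)}
#' interpolated from the fitted subgroup's isotonicised grid curve, where
#' \code{s} is the discriminant score and \code{f_direct} is the kernel
#' density of the observed (mixture) direct scores. Scores outside the grid
#' take the boundary value, so a score above every observed decoy score maps
#' to a probability near 1.
#'
#' @inheritParams discriminantScores
#' @return Numeric vector of probabilities in [0, 1].
#' @export
scoreProbability <- function(model, psms) {
  X <- cbind(psms$xcorr, psms$deltacn, abs(psms$delta_mass_ppm))
  keys <- assignSubgroup(psms)
  p <- numeric(nrow(psms))
  for (key in unique(keys)) {
    fit <- .fitFor(model, key)
    sel <- keys == key
    s <- drop(X[sel, , drop = FALSE] %*% fit$weights)
    p[sel] <- approx(fit$grid, fit$prob, xout = s, rule = 2)$y
  }
  pmin(1, pmax(0, p))
}

#' Filter PSMs on probability and mass accuracy
#'
#' A PSM passes when its posterior probability is at least \code{p_min}
#' (boundary inclusive) and its absolute DeltaMass does not exceed
#' \code{ppm_max}. Order-preserving; every input row appears exactly once in
#' the output. A PSM failing both criteria is reported as
#' \code{below_probability}.
#'
#' @inheritParams discriminantScores
#' @param p_min Minimum peptide probability (default 0.90).
#' @param ppm_max Maximum absolute DeltaMass in ppm (default 6).
#' @return The input data.frame with added columns \code{probability},
#'   \code{passed} and \code{fail_reason}
#'   (\code{"none"}/\code{"below_probability"}/\code{"ppm_exceeded"}).
#' @export
filterPSMs <- function(psms, model, p_min = 0.90, ppm_max = 6) {
  prob <- scoreProbability(model, psms)
  reason <- rep("none", nrow(psms))
  reason[abs(psms$delta_mass_ppm) > ppm_max] <- "ppm_exceeded"
  reason[prob < p_min] <- "below_probability"
  out <- psms
  out$probability <- prob
  out$passed <- reason == "none"
  out$fail_reason <- reason
  out
}

#' Decoy-estimated false discovery rate
#'
#' The FDR of a filtered PSM set, computed as the percentage of decoy PSMs
#' (every matched protein a decoy) among all PSMs that passed the filters.
#'
#' @param results Output of [filterPSMs()].
#' @param decoy_prefix Decoy id prefix.
#' @return FDR as a percentage.
#' @export
estimateFDR <- function(results, decoy_prefix = "Reverse_") {
  pass <- results[results$passed, , drop = FALSE]
  if (nrow(pass) == 0)
    stop("no passing PSMs: the FDR is undefined")
  100 * sum(.psmIsDecoy(pass$protein_ids, decoy_prefix)) / nrow(pass)
}
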