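# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

ceReference <- function() {
  ref <- makeReference()
  ref[S4Vectors::mcols(ref)$species == "celegans"]
}

# Minimal PSM rows with controllable scores; defaults put everything in the
# (+2, full) subgroup.
makePsms <- function(xcorr, decoy = FALSE, deltacn = 0.2, ppm = 0,
                     peptide = "AAAK", protein = "T1", sample = "a",
                     charge = "2", tryptic = "full", mods = "",
                     truth = NA) {
  n <- length(xcorr)
  data.frame(
    spectrum_id = sprintf("s%06d", seq_len(n)), sample = rep_len(sample, n),
    peptide = rep_len(peptide, n),
    protein_ids = ifelse(rep_len(decoy, n),
                         paste0("Reverse_", rep_len(protein, n)),
                         rep_len(protein, n)),
    charge_class = rep_len(charge, n), tryptic_status = rep_len(tryptic, n),
    xcorr = xcorr, deltacn = rep_len(deltacn, n),
    delta_mass_ppm = rep_len(ppm, n), mods = rep_len(mods, n),
    truth = rep_len(truth, n), stringsAsFactors = FALSE)
}

# A hand-built validation model whose probability equals the PSM's xcorr
# (clipped to [0, 1]), convenient for exercising filter semantics exactly.
identityProbModel <- function() {
  grid <- seq(0, 1, length.out = 512)
  unif <- rep(1, 512)
  fit <- list(weights = c(1, 0, 0), grid = grid, densDirect = unif,
              densDecoy = unif, prob = grid, piIncorrect = 0.5,
              nDirect = 100L, nDecoy = 50L)
  keys <- as.vector(outer(chargeClasses(), trypticStatuses(), paste,
                          sep = ":"))
  subgroups <- stats::setNames(vector("list", length(keys)), keys)
  new("ValidationModel", subgroups = subgroups, pooled = fit,
      decoyPrefix = "Reverse_", nMin = 50)
}

# Tiny target set with controlled substring structure.
toyProteins <- function() {
  proteinRecords(
    ids = c("P1", "P2", "P3"),
    sequences = c(
      P1 = paste0("M", "AAAWWWK", "DDDFFFK", "EEEE"),
      P2 = paste0("M", "CCCYYYK", "DDDFFFK", "GGGG"),
      P3 = paste0("M", "AAAWWWK", "DDDFFFK", "EEEE")),  # identical to P1
    species = "synthetic", family = "other")
}
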