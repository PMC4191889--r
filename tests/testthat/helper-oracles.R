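# Independent brute-force census oracle: loops over every (PSM, modification)
# pair with its own substring search and mass-delta classification, sharing no
# code with countOccurrences().
bruteForceCensus <- function(psms, proteins, tolerance = 0.005) {
  md <- S4Vectors::mcols(proteins)
  targets <- proteins[!md$is_decoy]
  fams <- S4Vectors::mcols(targets)$family
  seqs <- as.character(targets)
  ids <- names(targets)
  deltas <- c(ac = 42.0106, me1 = 14.0157, me2 = 28.0314, me3 = 42.0471)
  allowed <- list(ac = "K", me1 = c("K", "R"), me2 = c("K", "R"),
                  me3 = c("K", "R"))
  passed <- if ("passed" %in% names(psms)) psms$passed else rep(TRUE, nrow(psms))
  tally <- list()
  for (i in seq_len(nrow(psms))) {
    if (!passed[i] || psms$tryptic_status[i] != "full") next
    if (is.na(psms$mods[i]) || !nzchar(psms$mods[i])) next
    # smallest matching protein id, leftmost position
    hit <- which(vapply(seqs, function(s)
      grepl(psms$peptide[i], s, fixed = TRUE), logical(1)))
    if (!length(hit)) next
    hit <- hit[order(ids[hit])][1]
    start <- regexpr(psms$peptide[i], seqs[hit], fixed = TRUE)[1]
    for (tok in strsplit(psms$mods[i], ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
      off <- as.integer(kv[1]); d <- as.numeric(kv[2])
      pos <- start + off - 1L
      letter <- substr(seqs[hit], pos, pos)
      idx <- pos - as.integer(startsWith(seqs[hit], "M"))
      match_ <- names(deltas)[abs(deltas - d) <= tolerance]
      if (length(match_) != 1L) next
      if (!(letter %in% allowed[[match_]])) next
      key <- paste(fams[hit], ids[hit], paste0(letter, idx), match_,
                   psms$sample[i], sep = "|")
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  if (!length(tally))
    return(data.frame(histone_family = character(0), protein_id = character(0),
                      ce_site = character(0), ptm_type = character(0),
                      sample = character(0), occurrences = integer(0)))
  parts <- do.call(rbind, strsplit(names(tally), "|", fixed = TRUE))
  out <- data.frame(histone_family = parts[, 1], protein_id = parts[, 2],
                    ce_site = parts[, 3], ptm_type = parts[, 4],
                    sample = parts[, 5],
                    occurrences = as.integer(unlist(tally)),
                    stringsAsFactors = FALSE)
  out[order(out$sample, out$histone_family, out$protein_id, out$ce_site,
            out$ptm_type), ]
}

# Estimated-vs-true FDR differences over seeded synthetic runs.
fdrCalibrationDiffs <- function(n_runs, n_per_sample, seed0) {
  ref <- ceReference()
  decoys <- reverseDecoys(ref)
  vapply(seq_len(n_runs), function(i) {
    cfg <- simulationConfig(n_psms_per_sample = n_per_sample,
                            seed = seed0 + i)
    psms <- simulatePSMs(cfg, ref, decoys)
    flt <- filterPSMs(psms, fitValidationModel(psms))
    est <- estimateFDR(flt)
    isDecoy <- vapply(strsplit(flt$protein_ids, ","), function(x)
      all(startsWith(x, "Reverse_")), logical(1))
    pass <- flt$passed & !isDecoy
    est - 100 * mean(!flt$truth[pass])
  }, numeric(1))
}
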