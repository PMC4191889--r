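#' Read protein records from FASTA
#'
#' Standard FASTA parsing: the record id is the first whitespace-delimited
#' header token; a \code{"Reverse_"} id prefix marks a decoy. Optional
#' \code{species=} and \code{family=} key-value tokens in the description set
#' the corresponding tags (defaults: \code{synthetic}, \code{other}).
#' Records with empty sequences or characters outside the 20-letter
#' amino-acid alphabet are rejected with an error naming the record.
#'
#' @param path FASTA file path.
#' @param decoy_prefix Decoy id prefix.
#' @return Protein records (see [proteinRecords()]), in file order.
#' @export
readProteinFasta <- function(path, decoy_prefix = "Reverse_") {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  grab <- function(key, default) {
    m <- regmatches(headers, regexpr(sprintf("%s=\\S+", key), headers))
    out <- rep(default, length(headers))
    hit <- grepl(sprintf("%s=", key), headers)
    out[hit] <- sub(sprintf("^%s=", key), "", m)
    out
  }
  seqs <- as.character(set)
  bad <- which(!nzchar(seqs) |
               grepl(sprintf("[^%s]", paste(.aaAlphabet, collapse = "")), seqs))
  if (length(bad))
    stop("malformed FASTA record ", bad[1], " ('", ids[bad[1]], "') in ",
         path, ": empty sequence or illegal characters")
  proteinRecords(ids, unname(seqs),
                 species = grab("species", "synthetic"),
                 family = grab("family", "other"),
                 is_decoy = startsWith(ids, decoy_prefix),
                 decoy_prefix = decoy_prefix)
}

#' Write protein records to FASTA
#'
#' @param proteins Protein records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  md <- S4Vectors::mcols(proteins)
  out <- proteins
  names(out) <- sprintf("%s species=%s family=%s", names(proteins),
                        md$species, md$family)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

.psmCols <- c("spectrum_id", "sample", "peptide", "protein_ids",
              "charge_class", "tryptic_status", "xcorr", "deltacn",
              "delta_mass_ppm", "mods", "truth")

#' Read a PSM table
#'
#' Reads the tab-separated PSM schema written by [writePSMTable()]
#' (and produced by the synthetic generator). The header must match the
#' schema exactly; tags, numeric fields and the modification syntax are
#' validated with errors naming the offending row.
#'
#' @param path TSV path.
#' @return PSM data.frame.
#' @export
readPSMTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  extra <- setdiff(names(df), c(.psmCols, "probability", "passed",
                                "fail_reason"))
  if (length(extra))
    stop("unknown column(s) in PSM table: ", paste(extra, collapse = ", "))
  if (!all(.psmCols %in% names(df)))
    stop("PSM table is missing column(s): ",
         paste(setdiff(.psmCols, names(df)), collapse = ", "))
  badRow <- function(cond, what) {
    if (any(cond))
      stop(sprintf("%s in PSM table row %d", what, which(cond)[1]))
  }
  badRow(!(df$charge_class %in% .chargeClasses), "unknown charge_class tag")
  badRow(!(df$tryptic_status %in% .trypticStatuses),
         "unknown tryptic_status tag")
  badRow(!grepl("^$|^\\d+:\\d+(\\.\\d+)?(;\\d+:\\d+(\\.\\d+)?)*$", df$mods),
         "bad modification syntax")
  badRow(!nzchar(df$protein_ids), "empty protein_ids")
  for (col in c("xcorr", "deltacn", "delta_mass_ppm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    badRow(is.na(v), sprintf("non-numeric %s", col))
    df[[col]] <- v
  }
  badRow(!(df$truth %in% c("TRUE", "FALSE", "NA")), "bad truth flag")
  df$truth <- ifelse(df$truth == "NA", NA, df$truth == "TRUE")
  if ("probability" %in% names(df))
    df$probability <- as.numeric(df$probability)
  if ("passed" %in% names(df)) df$passed <- df$passed == "TRUE"
  df
}

#' Write a PSM table
#'
#' Writes the tab-separated PSM schema; scores carry four decimals (the
#' generator emits them at that precision, so write-then-read is lossless).
#'
#' @param psms PSM data.frame (optionally with the filter columns).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePSMTable <- function(psms, path) {
  out <- psms[, intersect(c(.psmCols, "probability", "passed", "fail_reason"),
                          names(psms))]
  for (col in c("xcorr", "deltacn", "delta_mass_ppm"))
    out[[col]] <- sprintf("%.4f", out[[col]])
  if ("probability" %in% names(out))
    out$probability <- sprintf("%.4f", out$probability)
  out$truth <- ifelse(is.na(psms$truth), "NA",
                      ifelse(psms$truth, "TRUE", "FALSE"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a census table as TSV
#'
#' The counted table goes to \code{path}; flagged-excluded rows go to a
#' parallel file with suffix \code{"_flagged"} before the extension.
#' \code{readCensusTsv()} reproduces an identical [CensusTable-class].
#'
#' @param census A [CensusTable-class].
#' @param path Output TSV path.
#' @return \code{path}, invisibly (writer); a \code{CensusTable} (reader).
#' @export
writeCensusTsv <- function(census, path) {
  write.table(censusCounts(census), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  flaggedPath <- sub("(\\.[^.]+)?$", "_flagged\\1", path)
  write.table(flaggedModifications(census), flaggedPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCensusTsv
#' @export
readCensusTsv <- function(path) {
  cls <- c(histone_family = "character", protein_id = "character",
           ce_site = "character", ref_site = "character",
           ptm_type = "character", sample = "character",
           occurrences = "integer")
  cts <- read.delim(path, stringsAsFactors = FALSE, colClasses = cls)
  flaggedPath <- sub("(\\.[^.]+)?$", "_flagged\\1", path)
  flg <- read.delim(flaggedPath, stringsAsFactors = FALSE,
                    colClasses = c(cls, reason = "character"))
  new("CensusTable", counts = cts, flagged = flg)
}

#' Pipeline configuration
#'
#' Collects every effective parameter of [runPipeline()]. Defaults reproduce
#' the filtering thresholds the analysis is built around: a 90\% minimum
#' peptide probability and a 6 ppm absolute DeltaMass cap, a 0.005 Da
#' PTM-annotation tolerance and a 600-3600 Da emPAI observability window.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Mandatory integer seed.
#' @param p_min,ppm_max Filtering thresholds.
#' @param tolerance_da PTM annotation tolerance (Da).
#' @param mass_range emPAI observability window (Da).
#' @param samples Sample labels (first two are compared as a/b = embryo-like
#'   over sperm-like when computing the fold ratio; see Details).
#' @param n_psms_per_sample,true_match_fraction Passed to
#'   [simulationConfig()].
#' @param psm_path Optional existing PSM TSV; when given, simulation is
#'   skipped and these PSMs are used.
#' @param fasta_path Optional target FASTA; defaults to the packaged
#'   reference histones.
#' @param cross_species Named character vector pairing query ids to
#'   reference ids for site mapping.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir, seed, p_min = 0.90, ppm_max = 6,
                           tolerance_da = 0.005, mass_range = c(600, 3600),
                           samples = c("sperm", "embryo"),
                           n_psms_per_sample = 20000,
                           true_match_fraction = 0.7,
                           psm_path = NULL, fasta_path = NULL,
                           cross_species = c(ceH2A = "mmH2A", ceH2B = "mmH2B",
                                             ceH3 = "mmH3", ceH4 = "mmH4")) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  structure(list(out_dir = out_dir, seed = as.integer(seed), p_min = p_min,
                 ppm_max = ppm_max, tolerance_da = tolerance_da,
                 mass_range = mass_range, samples = samples,
                 n_psms_per_sample = n_psms_per_sample,
                 true_match_fraction = true_match_fraction,
                 psm_path = psm_path, fasta_path = fasta_path,
                 cross_species = cross_species), class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Executes simulate (skipped when \code{psm_path} is given), validate,
#' assemble, census and compare, writing every stage's TSV output plus a run
#' log (seed, thresholds, estimated FDR, warning summary) to
#' \code{config$out_dir}. Any stage failure aborts with a stage-named error.
#' All outputs are deterministic given the configuration.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the filtered PSMs, estimated FDR, per-locus
#'   quantification tables, the census, the comparison summary and the
#'   output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  paths <- list()
  targets <- stage("reference", {
    if (is.null(config$fasta_path)) makeReference()
    else readProteinFasta(config$fasta_path)
  })
  targets <- targets[!S4Vectors::mcols(targets)$is_decoy]
  ceTargets <- targets[S4Vectors::mcols(targets)$species == "celegans"]
  if (length(ceTargets) == 0) ceTargets <- targets
  decoys <- stage("reference", reverseDecoys(ceTargets))
  paths$reference <- file.path(config$out_dir, "reference_with_decoys.fasta")
  writeProteinFasta(c(ceTargets, decoys), paths$reference)
  psms <- stage("simulate", {
    if (!is.null(config$psm_path)) readPSMTable(config$psm_path)
    else {
      cfg <- simulationConfig(n_psms_per_sample = config$n_psms_per_sample,
                              true_match_fraction = config$true_match_fraction,
                              samples = config$samples, seed = config$seed)
      simulatePSMs(cfg, ceTargets, decoys)
    }
  })
  paths$psms <- file.path(config$out_dir, "psms.tsv")
  writePSMTable(psms, paths$psms)
  filtered <- stage("validate", {
    model <- fitValidationModel(psms)
    filterPSMs(psms, model, p_min = config$p_min, ppm_max = config$ppm_max)
  })
  fdr <- stage("validate", estimateFDR(filtered))
  paths$filtered <- file.path(config$out_dir, "psms_filtered.tsv")
  writePSMTable(filtered, paths$filtered)
  passing <- filtered[filtered$passed &
                      !.psmIsDecoy(filtered$protein_ids), , drop = FALSE]
  quant <- stage("assemble", {
    lapply(setNames(nm = config$samples), function(smp)
      proteinQuant(passing[passing$sample == smp, , drop = FALSE],
                   ceTargets, config$mass_range))
  })
  for (smp in config$samples) {
    p <- file.path(config$out_dir, sprintf("protein_quant_%s.tsv", smp))
    q <- quant[[smp]]
    q$spectral_count <- sprintf("%.4f", q$spectral_count)
    q$coverage <- sprintf("%.4f", q$coverage)
    q$nsaf <- sprintf("%.6f", q$nsaf)
    q$empai <- sprintf("%.4f", q$empai)
    write.table(q, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("quant_", smp)]] <- p
  }
  ## cross-species pairing may reference records (e.g. mouse) outside the
  ## search set; keep pairs whose both sides are available and append the
  ## reference records so sites can be mapped
  xs <- config$cross_species[names(config$cross_species) %in%
                             names(ceTargets) &
                             config$cross_species %in% names(targets)]
  censusProteins <- c(ceTargets,
                      targets[setdiff(unname(xs), names(ceTargets))])
  census <- stage("census", countOccurrences(
    passing, censusProteins, tolerance = config$tolerance_da,
    cross_species = if (length(xs)) xs else NULL))
  paths$census <- file.path(config$out_dir, "census.tsv")
  writeCensusTsv(census, paths$census)
  summary <- stage("compare", {
    perSample <- do.call(rbind, lapply(config$samples, function(smp) {
      tot <- sum(passing$sample == smp)
      ptm <- length(unique(censusPSMids(passing, smp)))
      sampleSummary(smp, tot, ptm, census)
    }))
    perSample
  })
  if (nrow(summary) >= 2 && all(summary$total_histone_spectra > 0)) {
    fu <- vapply(seq_len(nrow(summary)), function(i)
      modifiedFraction(summary$ptm_histone_spectra[i],
                       summary$total_histone_spectra[i], digits = NULL),
      numeric(1))
    fold <- if (fu[1] > 0) foldRatio(fu[2], fu[1]) else NA_real_
  } else fold <- NA_real_
  paths$summary <- file.path(config$out_dir, "comparison_summary.tsv")
  write.table(summary, paths$summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$log <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("seed\t%d", config$seed),
    sprintf("p_min\t%g", config$p_min),
    sprintf("ppm_max\t%g", config$ppm_max),
    sprintf("tolerance_da\t%g", config$tolerance_da),
    sprintf("mass_range\t%g-%g", config$mass_range[1], config$mass_range[2]),
    sprintf("n_psms_per_sample\t%d", config$n_psms_per_sample),
    sprintf("true_match_fraction\t%g", config$true_match_fraction),
    sprintf("estimated_fdr_percent\t%.4f", fdr),
    sprintf("fold_ratio_%s_over_%s\t%s", config$samples[2],
            config$samples[1],
            ifelse(is.na(fold), "NA", sprintf("%.1f", fold))),
    sprintf("flagged_occurrences\t%d",
            sum(flaggedModifications(census)$occurrences))),
    paths$log)
  invisible(list(filtered = filtered, fdr = fdr, quant = quant,
                 census = census, summary = summary, fold_ratio = fold,
                 paths = paths))
}

## Spectrum ids of passing full-tryptic PSMs carrying >= 1 countable mod in a
## sample (the "PTM histone spectra" numerator).
censusPSMids <- function(passing, sample) {
  sub <- passing[passing$sample == sample &
                 passing$tryptic_status == "full" &
                 nzchar(passing$mods), , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  modtab <- modificationTable()
  countableDeltas <- modtab$delta[modtab$counted_in_census &
                                  modtab$ptm_type != "ph"]
  keep <- vapply(.parseMods(sub$mods), function(m)
    any(vapply(m$delta, function(d)
      any(abs(countableDeltas - d) <= 0.005), logical(1))), logical(1))
  sub$spectrum_id[keep]
}
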