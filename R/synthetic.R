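#' Construct a set of protein records
#'
#' Protein records are stored as a [Biostrings::AAStringSet] whose
#' \code{mcols} carry \code{species} (celegans/mouse/synthetic),
#' \code{family} (H2A/H2B/H3/H4/H1/variant/other) and \code{is_decoy}.
#'
#' @param ids Character vector of protein identifiers; decoy records must
#'   (and only decoy records may) carry the decoy prefix.
#' @param sequences Character vector of uppercase amino-acid sequences
#'   (20-letter alphabet; leading initiator Met allowed).
#' @param species,family Tag vectors (recycled if length 1).
#' @param is_decoy Logical vector (recycled if length 1).
#' @param decoy_prefix Id prefix that distinguishes decoy records.
#' @return An \code{AAStringSet} with metadata columns.
#' @export
proteinRecords <- function(ids, sequences, species = "synthetic",
                           family = "other", is_decoy = FALSE,
                           decoy_prefix = "Reverse_") {
  n <- length(ids)
  stopifnot(length(sequences) == n, n > 0)
  species <- rep_len(species, n)
  family <- rep_len(family, n)
  is_decoy <- rep_len(is_decoy, n)
  if (any(!nzchar(sequences)))
    stop("protein sequences must be non-empty")
  bad <- grepl(sprintf("[^%s]", paste(.aaAlphabet, collapse = "")), sequences)
  if (any(bad))
    stop("sequence for ", ids[which(bad)[1]],
         " contains characters outside the 20-letter amino-acid alphabet")
  if (!all(species %in% .speciesTags))
    stop("unknown species tag; expected one of ",
         paste(.speciesTags, collapse = ", "))
  if (!all(family %in% .histoneFamilies))
    stop("unknown family tag; expected one of ",
         paste(.histoneFamilies, collapse = ", "))
  pref <- startsWith(ids, decoy_prefix)
  if (any(pref != is_decoy))
    stop("decoy flag and '", decoy_prefix, "' id prefix must agree")
  set <- Biostrings::AAStringSet(sequences)
  names(set) <- ids
  S4Vectors::mcols(set) <- S4Vectors::DataFrame(
    species = species, family = family, is_decoy = is_decoy)
  set
}

#' Packaged reference histone sequences
#'
#' Loads the bundled synthetic stand-in histone sequences: C. elegans core
#' H2A/H2B/H3/H4 plus the sperm-specific H2A variant HTAS-1 and the H2A.Z
#' orthologue HTZ-1, and mouse H2A/H2B/H3/H4 references used for
#' cross-species coordinate mapping. The C. elegans H2A and H2B stand-ins
#' are constructed so that global alignment to the mouse references
#' reproduces the field's documented residue correspondences under post-Met
#' numbering (e.g. mouse H2A K119 to C. elegans K120; mouse H2B K12 to
#' C. elegans K7). Deterministic for a given package version.
#'
#' @param config Optional [simulationConfig()]; accepted for interface
#'   symmetry, the reference set does not depend on it.
#' @return Protein records (see [proteinRecords()]); >= 8 targets covering
#'   families H2A/H2B/H3/H4 plus >= 2 variant records, all \code{is_decoy =
#'   FALSE}, every sequence starting with the initiator Met.
#' @export
makeReference <- function(config = NULL) {
  path <- system.file("extdata", "histone_references_synthetic.fasta",
                      package = "HistoneCensus", mustWork = TRUE)
  readProteinFasta(path)
}

#' Reversed-sequence decoy records
#'
#' Builds one decoy per target by character-reversing the target sequence and
#' prefixing its id, the standard construction for decoy-based FDR estimation.
#'
#' @param targets Protein records, all with \code{is_decoy = FALSE}.
#' @param decoy_prefix Prefix prepended to target ids.
#' @return Decoy protein records (same order as \code{targets}).
#' @export
reverseDecoys <- function(targets, decoy_prefix = "Reverse_") {
  md <- S4Vectors::mcols(targets)
  if (length(targets) == 0) {
    empty <- Biostrings::AAStringSet(character(0))
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      species = character(0), family = character(0), is_decoy = logical(0))
    return(empty)
  }
  if (any(md$is_decoy))
    stop("reverseDecoys() expects target records only; input contains decoys")
  rev <- as.character(Biostrings::reverse(targets))
  proteinRecords(paste0(decoy_prefix, names(targets)), unname(rev),
                 species = md$species, family = md$family, is_decoy = TRUE,
                 decoy_prefix = decoy_prefix)
}

#' Default per-site modification emission frequencies
#'
#' Emission probabilities for the synthetic generator, keyed by
#' (histone family, post-Met residue index, PTM type) with one probability
#' column per sample. The profile mirrors the bundled published occurrence
#' census: each site's emission probability (applied when a correct match's
#' peptide covers the site) is proportional to its published occurrence
#' share, scaled so that the expected modified fraction of passing histone
#' spectra lands near the published 1.8\% (sperm) and 4.2\% (embryo) levels
#' once protein choice, site coverage and the full-tryptic census
#' restriction are accounted for. An
#' embryo-only H2A K120 ubiquitination channel and a small phosphorylation
#' channel exercise the census exclusion rules.
#'
#' @return data.frame with columns \code{histone_family},
#'   \code{residue_index}, \code{ptm_type} and one probability column per
#'   sample (\code{sperm}, \code{embryo}).
#' @export
defaultModSiteFrequencies <- function() {
  pub <- publishedOccurrences()
  wide <- merge(
    stats::aggregate(occurrences ~ histone_family + ce_site + ptm_type,
                     pub[pub$sample == "sperm", ], sum),
    stats::aggregate(occurrences ~ histone_family + ce_site + ptm_type,
                     pub[pub$sample == "embryo", ], sum),
    by = c("histone_family", "ce_site", "ptm_type"), all = TRUE,
    suffixes = c("_sperm", "_embryo"))
  wide[is.na(wide)] <- 0
  out <- data.frame(
    histone_family = wide$histone_family,
    residue_index = as.integer(sub("^[A-Z]", "", wide$ce_site)),
    ptm_type = wide$ptm_type,
    sperm = 1.3 * wide$occurrences_sperm / sum(wide$occurrences_sperm),
    embryo = 4.0 * wide$occurrences_embryo / sum(wide$occurrences_embryo),
    stringsAsFactors = FALSE)
  extra <- data.frame(
    histone_family = c("H2A", "H3"),
    residue_index = c(120L, 10L),
    ptm_type = c("ub", "ph"),
    sperm = c(0, 0.002),
    embryo = c(0.05, 0.002))
  rbind(out, extra)
}

#' Simulation configuration
#'
#' Parameters of the synthetic PSM generator. Score parameters are
#' class-conditional with independent components: XCorr and DeltaCN are
#' Gaussian in both classes (DeltaCN truncated at 0), DeltaMass (ppm) is
#' Gaussian around 0 for correct matches and uniform on +/- the stated
#' half-width for incorrect ones, so the 6 ppm post-filter is consequential.
#' Defaults give overlapping but separable classes.
#'
#' @param n_psms_per_sample PSMs generated per sample.
#' @param true_match_fraction Probability that a PSM is a correct match.
#' @param score_params Nested list \code{list(correct=, incorrect=)}; each
#'   class holds \code{xcorr = c(mean, sd)}, \code{deltacn = c(mean, sd)},
#'   and \code{delta_mass_ppm} (\code{c(mean, sd)} for correct,
#'   \code{c(halfwidth)} for incorrect).
#' @param charge_class_weights Named 4-vector of probabilities over
#'   \code{chargeClasses()}; must sum to 1 (1e-9 tolerance).
#' @param tryptic_status_weights Named 3-vector over
#'   \code{trypticStatuses()}; must sum to 1.
#' @param mod_site_frequencies See [defaultModSiteFrequencies()].
#' @param peptide_length_range Tryptic-like peptide lengths, drawn uniformly.
#' @param samples Sample labels.
#' @param seed Mandatory integer seed.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_psms_per_sample = 20000,
                             true_match_fraction = 0.7,
                             score_params = list(
                               correct = list(xcorr = c(4.0, 0.8),
                                              deltacn = c(0.35, 0.08),
                                              delta_mass_ppm = c(0, 2)),
                               incorrect = list(xcorr = c(2.0, 0.6),
                                                deltacn = c(0.12, 0.06),
                                                delta_mass_ppm = c(50))),
                             charge_class_weights = c(`1` = 0.10, `2` = 0.45,
                                                      `3` = 0.30, gt3 = 0.15),
                             tryptic_status_weights = c(full = 0.70,
                                                        half = 0.20,
                                                        non = 0.10),
                             mod_site_frequencies = defaultModSiteFrequencies(),
                             peptide_length_range = c(7L, 25L),
                             samples = c("sperm", "embryo"),
                             seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory for the synthetic generator")
  if (!is.numeric(true_match_fraction) || true_match_fraction < 0 ||
      true_match_fraction > 1)
    stop("true_match_fraction must lie in [0, 1]")
  if (abs(sum(charge_class_weights) - 1) > 1e-9)
    stop("charge_class_weights must sum to 1")
  if (abs(sum(tryptic_status_weights) - 1) > 1e-9)
    stop("tryptic_status_weights must sum to 1")
  if (!identical(sort(names(charge_class_weights)), sort(.chargeClasses)))
    stop("charge_class_weights must be named after chargeClasses()")
  if (!identical(sort(names(tryptic_status_weights)), sort(.trypticStatuses)))
    stop("tryptic_status_weights must be named after trypticStatuses()")
  if (!all(samples %in% names(mod_site_frequencies)))
    stop("mod_site_frequencies must carry one probability column per sample")
  structure(list(
    n_psms_per_sample = as.integer(n_psms_per_sample),
    true_match_fraction = true_match_fraction,
    score_params = score_params,
    charge_class_weights = charge_class_weights[.chargeClasses],
    tryptic_status_weights = tryptic_status_weights[.trypticStatuses],
    mod_site_frequencies = mod_site_frequencies,
    peptide_length_range = as.integer(peptide_length_range),
    samples = samples,
    seed = as.integer(seed)), class = "SimulationConfig")
}

## Draw class-conditional scores for n PSMs; truth selects the class.
.drawScores <- function(n, truth, sp) {
  xcorr <- deltacn <- dm <- numeric(n)
  for (cls in c("correct", "incorrect")) {
    idx <- if (cls == "correct") which(truth) else which(!truth)
    if (!length(idx)) next
    p <- sp[[cls]]
    xcorr[idx] <- rnorm(length(idx), p$xcorr[1], p$xcorr[2])
    deltacn[idx] <- pmax(0, rnorm(length(idx), p$deltacn[1], p$deltacn[2]))
    dm[idx] <- if (cls == "correct")
      rnorm(length(idx), p$delta_mass_ppm[1], p$delta_mass_ppm[2])
    else runif(length(idx), -p$delta_mass_ppm[1], p$delta_mass_ppm[1])
  }
  list(xcorr = round(xcorr, 4), deltacn = round(deltacn, 4),
       delta_mass_ppm = round(dm, 4))
}

## Emit variable modifications for true matches plus fixed carbamidomethyl-C.
.emitMods <- function(peptide, protein_idx, start, truth, sample,
                      proteins, freq) {
  n <- length(peptide)
  offs <- vector("list", n)
  delt <- vector("list", n)
  modtab <- modificationTable()
  seqs <- as.character(proteins)
  md <- S4Vectors::mcols(proteins)
  startsM <- startsWith(seqs, "M")
  plen <- nchar(peptide)
  pcol <- freq[[sample]]
  for (r in seq_len(nrow(freq))) {
    if (pcol[r] <= 0) next
    fam <- freq$histone_family[r]
    ptm <- freq$ptm_type[r]
    delta <- modtab$delta[match(ptm, modtab$ptm_type)]
    allowed <- strsplit(modtab$residues[match(ptm, modtab$ptm_type)], ",")[[1]]
    prots <- which(md$family == fam & !md$is_decoy)
    for (pi in prots) {
      seqpos <- freq$residue_index[r] + if (startsM[pi]) 1L else 0L
      if (seqpos > nchar(seqs[pi])) next
      if (!(substr(seqs[pi], seqpos, seqpos) %in% allowed)) next
      cand <- which(truth & protein_idx == pi & start <= seqpos &
                    start + plen - 1L >= seqpos)
      if (!length(cand)) next
      hit <- cand[runif(length(cand)) < pcol[r]]
      for (i in hit) {
        offs[[i]] <- c(offs[[i]], seqpos - start[i] + 1L)
        delt[[i]] <- c(delt[[i]], delta)
      }
    }
  }
  ## fixed Cys carbamidomethylation on every peptide that contains C
  camDelta <- modtab$delta[modtab$ptm_type == "carbamidomethyl"]
  hasC <- grepl("C", peptide, fixed = TRUE)
  for (i in which(hasC)) {
    cpos <- gregexpr("C", peptide[i], fixed = TRUE)[[1]]
    offs[[i]] <- c(offs[[i]], as.integer(cpos))
    delt[[i]] <- c(delt[[i]], rep(camDelta, length(cpos)))
  }
  vapply(seq_len(n), function(i) {
    if (is.null(offs[[i]])) return("")
    o <- order(offs[[i]])
    paste(sprintf("%d:%.6f", offs[[i]][o], delt[[i]][o]), collapse = ";")
  }, "")
}

#' Simulate peptide-spectrum matches
#'
#' Generates \code{n_psms_per_sample} PSMs per sample. Correct matches are
#' substrings of target sequences with scores drawn from the correct class;
#' incorrect matches are substrings of targets or decoys (equal chance, the
#' standard target-decoy assumption on which the FDR estimator relies) with
#' scores from the incorrect class. Modifications are emitted for correct
#' matches per the configured per-site frequencies whenever the peptide
#' covers the site; every cysteine carries the fixed carbamidomethyl mass.
#' Fully reproducible from the configured seed.
#'
#' @param config A [simulationConfig()].
#' @param targets,decoys Protein records (non-empty).
#' @return A PSM data.frame with columns \code{spectrum_id}, \code{sample},
#'   \code{peptide}, \code{protein_ids}, \code{charge_class},
#'   \code{tryptic_status}, \code{xcorr}, \code{deltacn},
#'   \code{delta_mass_ppm}, \code{mods} (semicolon-joined
#'   \code{"offset:delta"}), \code{truth}.
#' @export
simulatePSMs <- function(config, targets, decoys) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(targets) == 0 || length(decoys) == 0)
    stop("simulatePSMs() needs non-empty target and decoy references")
  set.seed(config$seed)
  pool <- c(targets, decoys)
  poolLen <- Biostrings::width(pool)
  nTarget <- length(targets)
  out <- vector("list", length(config$samples))
  for (si in seq_along(config$samples)) {
    smp <- config$samples[si]
    n <- config$n_psms_per_sample
    truth <- runif(n) < config$true_match_fraction
    ## protein choice: correct -> targets; incorrect -> coin flip decoy/target
    idx <- integer(n)
    idx[truth] <- sample.int(nTarget, sum(truth), replace = TRUE)
    nf <- sum(!truth)
    fromDecoy <- runif(nf) < 0.5
    fi <- integer(nf)
    fi[fromDecoy] <- nTarget + sample.int(length(decoys), sum(fromDecoy),
                                          replace = TRUE)
    fi[!fromDecoy] <- sample.int(nTarget, sum(!fromDecoy), replace = TRUE)
    idx[!truth] <- fi
    plen <- sample(seq(config$peptide_length_range[1],
                       config$peptide_length_range[2]), n, replace = TRUE)
    plen <- pmin(plen, poolLen[idx])
    start <- 1L + floor(runif(n) * (poolLen[idx] - plen + 1L))
    peptide <- substr(as.character(pool)[idx], start, start + plen - 1L)
    charge <- sample(.chargeClasses, n, replace = TRUE,
                     prob = config$charge_class_weights)
    tryp <- sample(.trypticStatuses, n, replace = TRUE,
                   prob = config$tryptic_status_weights)
    sc <- .drawScores(n, truth, config$score_params)
    mods <- .emitMods(peptide, ifelse(idx <= nTarget, idx, NA_integer_),
                      start, truth, smp, targets,
                      config$mod_site_frequencies)
    out[[si]] <- data.frame(
      spectrum_id = sprintf("%s_%06d", smp, seq_len(n)),
      sample = smp, peptide = peptide,
      protein_ids = names(pool)[idx],
      charge_class = charge, tryptic_status = tryp,
      xcorr = sc$xcorr, deltacn = sc$deltacn,
      delta_mass_ppm = sc$delta_mass_ppm,
      mods = mods, truth = truth, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
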