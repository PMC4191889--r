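## Parse the "offset:delta;offset:delta" modification encoding.
.parseMods <- function(mods) {
  lapply(mods, function(m) {
    if (is.na(m) || !nzchar(m))
      return(data.frame(offset = integer(0), delta = numeric(0)))
    parts <- strsplit(strsplit(m, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(offset = as.integer(vapply(parts, `[`, "", 1)),
               delta = as.numeric(vapply(parts, `[`, "", 2)))
  })
}

.formatMods <- function(offset, delta) {
  if (!length(offset)) return("")
  o <- order(offset)
  paste(sprintf("%d:%.6f", offset[o], delta[o]), collapse = ";")
}

#' Project peptide modifications onto protein coordinates
#'
#' Converts the 1-based peptide offsets of a PSM's modifications into
#' residue coordinates of the matched protein under the histone field's
#' numbering convention: residues are numbered starting at the amino acid
#' after the initiator methionine, so for proteins beginning with 'M' the
#' raw sequence position is decremented by one.
#'
#' @param peptide Peptide string.
#' @param mods data.frame with \code{offset} (1-based peptide position) and
#'   \code{delta} (Da), as returned for one PSM by the PSM-table reader.
#' @param protein_sequence Full protein sequence.
#' @param match_start 1-based start of the peptide in the full sequence.
#' @param tolerance Da tolerance for PTM-type annotation.
#' @return data.frame with \code{offset}, \code{delta}, \code{residue_index}
#'   (post-Met numbering), \code{residue_letter}, \code{ptm_type} and
#'   \code{status} (\code{counted}, \code{excluded}, \code{residue_conflict}
#'   or \code{unannotated}).
#' @export
siteCoordinates <- function(peptide, mods, protein_sequence, match_start,
                            tolerance = 0.005) {
  if (substr(protein_sequence, match_start,
             match_start + nchar(peptide) - 1L) != peptide)
    stop("peptide does not match the protein at match_start")
  if (nrow(mods) && (any(mods$offset < 1) || any(mods$offset > nchar(peptide))))
    stop("modification offset outside the peptide")
  metShift <- as.integer(startsWith(protein_sequence, "M"))
  seqpos <- match_start + mods$offset - 1L
  letter <- substring(protein_sequence, seqpos, seqpos)
  ann <- .annotateModStatus(mods$delta, letter, tolerance)
  data.frame(offset = mods$offset, delta = mods$delta,
             residue_index = seqpos - metShift,
             residue_letter = letter,
             ptm_type = ann$ptm_type, status = ann$status,
             stringsAsFactors = FALSE)
}

#' Map a residue position across species by global alignment
#'
#' Aligns the query protein to the reference protein with Needleman-Wunsch
#' (BLOSUM62 substitution scores, gap opening 10, gap extension 0.5;
#' histones are near-identical so the mapping is insensitive to these, but
#' they are fixed for determinism) and returns the reference residue number,
#' in the same post-initiator-Met numbering, aligned to the query residue.
#'
#' @param query,reference Protein sequences (strings, or single protein
#'   records).
#' @param residue_index Integer vector of query residue indices (post-Met
#'   numbering).
#' @return Integer vector of reference residue indices; \code{NA} where the
#'   query residue aligns to a gap.
#' @export
mapCrossSpecies <- function(query, reference, residue_index) {
  query <- as.character(query)[1]
  reference <- as.character(reference)[1]
  if (!nzchar(query) || !nzchar(reference))
    stop("empty sequence")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = get("BLOSUM62"), gapOpening = 10,
    gapExtension = 0.5, type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  qShift <- as.integer(startsWith(query, "M"))
  rShift <- as.integer(startsWith(reference, "M"))
  vapply(residue_index, function(i) {
    seqI <- i + qShift
    if (seqI < 1 || seqI > nchar(query)) return(NA_integer_)
    col <- which(qpos == seqI & qa != "-")[1]
    if (is.na(col) || ra[col] == "-") return(NA_integer_)
    out <- rpos[col] - rShift
    if (out < 1) NA_integer_ else as.integer(out)
  }, integer(1))
}

.emptyCensusDf <- function(flagged = FALSE) {
  df <- data.frame(histone_family = character(0), protein_id = character(0),
                   ce_site = character(0), ref_site = character(0),
                   ptm_type = character(0), sample = character(0),
                   occurrences = integer(0), stringsAsFactors = FALSE)
  if (flagged) df$reason <- character(0)
  df
}

#' Build the PTM occurrence census
#'
#' Tallies, per sample, the number of times each modification site was
#' identified. Only passing, fully tryptic PSMs that map to a target histone
#' are counted, mirroring the per-subtype full-tryptic peptide listings a
#' census is built from; a spectrum bearing k countable modifications
#' contributes k occurrences (sites on peptides with single and multiple
#' PTMs all count). Ubiquitination (mass-degenerate with the iodoacetamide
#' lysine adduct), phosphorylation and fixed carbamidomethylation are routed
#' to the flagged table, as are modifications whose annotated residue
#' conflicts with the PTM's allowed residues (with a warning).
#'
#' When a peptide matches several proteins the lexicographically smallest
#' matched protein id is used for coordinates; when it matches one protein
#' at several positions the leftmost is used.
#'
#' @param psms Filtered PSM data.frame (only rows with \code{passed == TRUE}
#'   are counted; an unfiltered table is accepted and treated as all-passing
#'   if it has no \code{passed} column).
#' @param proteins Target protein records.
#' @param tolerance Da tolerance for PTM annotation.
#' @param cross_species Optional named character vector pairing query protein
#'   ids to reference protein ids for cross-species site mapping
#'   (e.g. \code{c(ceH2A = "mmH2A")}); reference records must be present in
#'   \code{proteins}.
#' @return A [CensusTable-class] object.
#' @export
countOccurrences <- function(psms, proteins, tolerance = 0.005,
                             cross_species = NULL) {
  passed <- if ("passed" %in% names(psms)) psms$passed else TRUE
  sel <- passed & psms$tryptic_status == "full" & nzchar(psms$mods) &
    !is.na(psms$mods)
  sub <- psms[sel, , drop = FALSE]
  md <- S4Vectors::mcols(proteins)
  targets <- proteins[!md$is_decoy]
  tmd <- S4Vectors::mcols(targets)
  histone <- tmd$family %in% c("H2A", "H2B", "H3", "H4", "H1", "variant")
  seqs <- as.character(targets)
  counts <- list(); flagged <- list()
  if (nrow(sub)) {
    map <- mapPeptides(sub, targets[histone])
    matchOf <- split(seq_len(nrow(map$matches)), map$matches$peptide)
    modsList <- .parseMods(sub$mods)
    for (i in seq_len(nrow(sub))) {
      rows <- matchOf[[sub$peptide[i]]]
      if (is.null(rows)) next
      hit <- map$matches[rows, , drop = FALSE]
      hit <- hit[order(hit$protein_id), , drop = FALSE]
      pid <- hit$protein_id[1]
      start <- hit$start[1]
      fam <- tmd$family[match(pid, names(targets))]
      sc <- siteCoordinates(sub$peptide[i], modsList[[i]],
                            seqs[[match(pid, names(targets))]], start,
                            tolerance)
      if (!nrow(sc)) next
      sc$site <- paste0(sc$residue_letter, sc$residue_index)
      for (k in seq_len(nrow(sc))) {
        rec <- data.frame(histone_family = fam, protein_id = pid,
                          ce_site = sc$site[k], ref_site = NA_character_,
                          ptm_type = sc$ptm_type[k], sample = sub$sample[i],
                          occurrences = 1L, stringsAsFactors = FALSE)
        if (sc$status[k] == "counted") {
          counts[[length(counts) + 1L]] <- rec
        } else {
          rec$reason <- sc$status[k]
          if (is.na(rec$ptm_type)) rec$ptm_type <- "unknown"
          flagged[[length(flagged) + 1L]] <- rec
        }
      }
    }
  }
  agg <- function(lst, flag) {
    if (!length(lst)) return(.emptyCensusDf(flag))
    df <- do.call(rbind, lst)
    by <- c("histone_family", "protein_id", "ce_site", "ptm_type", "sample",
            if (flag) "reason")
    out <- stats::aggregate(df["occurrences"], df[by], sum)
    out$ref_site <- NA_character_
    out[, c(.censusCols, if (flag) "reason")]
  }
  cts <- agg(counts, FALSE)
  flg <- agg(flagged, TRUE)
  if (nrow(flg) && any(flg$reason == "residue_conflict"))
    warning(sum(flg$occurrences[flg$reason == "residue_conflict"]),
            " modification occurrence(s) dropped: residue inconsistent",
            " with the PTM's allowed residues")
  ## cross-species site labels via pairwise alignment
  if (!is.null(cross_species)) {
    fill <- function(df) {
      if (!nrow(df)) return(df)
      for (qid in intersect(unique(df$protein_id), names(cross_species))) {
        rid <- cross_species[[qid]]
        if (!(rid %in% names(proteins))) next
        rows <- which(df$protein_id == qid)
        idx <- as.integer(sub("^[A-Z]", "", df$ce_site[rows]))
        refIdx <- mapCrossSpecies(seqs[[match(qid, names(targets))]],
                                  as.character(proteins[[rid]]), idx)
        refSeq <- as.character(proteins[[rid]])
        shift <- as.integer(startsWith(refSeq, "M"))
        letter <- substring(refSeq, refIdx + shift, refIdx + shift)
        df$ref_site[rows] <- ifelse(is.na(refIdx), NA_character_,
                                    paste0(letter, refIdx))
      }
      df
    }
    cts <- fill(cts); flg <- fill(flg)
  }
  ord <- order(cts$sample, cts$histone_family, cts$protein_id,
               as.integer(sub("^[A-Z]", "", cts$ce_site)), cts$ptm_type)
  cts <- cts[ord, , drop = FALSE]
  rownames(cts) <- NULL; rownames(flg) <- NULL
  new("CensusTable", counts = cts, flagged = flg)
}

#' Build a CensusTable from an occurrence data.frame
#'
#' Wraps an already-tallied occurrence table (for example the bundled
#' published per-site census, see [publishedOccurrences()]) in a
#' [CensusTable-class]. Rows with PTM types outside ac/me1/me2/me3 are
#' routed to the flagged side.
#'
#' @param df data.frame with columns \code{histone_family}, \code{ce_site},
#'   \code{ptm_type}, \code{sample}, \code{occurrences}; optional
#'   \code{protein_id} and \code{ref_site}.
#' @return A [CensusTable-class] object.
#' @export
censusFromCounts <- function(df) {
  if (!("protein_id" %in% names(df)))
    df[["protein_id"]] <- rep(NA_character_, nrow(df))
  if (!("ref_site" %in% names(df)))
    df[["ref_site"]] <- rep(NA_character_, nrow(df))
  df <- df[, c(.censusCols)]
  df$occurrences <- as.integer(df$occurrences)
  countable <- df$ptm_type %in% .countablePTMs
  flg <- df[!countable, , drop = FALSE]
  if (nrow(flg)) flg$reason <- "excluded"
  else flg <- .emptyCensusDf(TRUE)
  rownames(flg) <- NULL
  cts <- df[countable, , drop = FALSE]
  rownames(cts) <- NULL
  new("CensusTable", counts = cts, flagged = flg)
}

#' Bundled published per-site occurrence census
#'
#' The per-site histone PTM occurrence counts for C. elegans sperm and
#' mixed-stage embryo chromatin bundled with the package (transcribed from
#' the published per-subtype occurrence table), with the corresponding mouse
#' site for each C. elegans site.
#'
#' @return data.frame with columns \code{histone_family}, \code{ce_site},
#'   \code{ref_site}, \code{ptm_type}, \code{sample}, \code{occurrences}.
#' @export
publishedOccurrences <- function() {
  path <- system.file("extdata", "census_occurrences_published.tsv",
                      package = "HistoneCensus", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    histone_family = "character", ce_site = "character",
    ref_site = "character", ptm_type = "character", sample = "character",
    occurrences = "integer"))
}

#' Count distinct PTM marks in a sample
#'
#' Number of distinct (histone family, site, PTM type) triples with at least
#' one counted occurrence in the given sample; flagged (ub/ph/artifact)
#' entries are excluded by construction.
#'
#' @param census A [CensusTable-class].
#' @param sample Sample label.
#' @return Integer count of distinct marks.
#' @export
distinctMarks <- function(census, sample) {
  cts <- censusCounts(census)
  cts <- cts[cts$sample == sample & cts$occurrences >= 1L, , drop = FALSE]
  nrow(unique(cts[c("histone_family", "ce_site", "ptm_type")]))
}

#' Total counted occurrences in a sample
#'
#' @inheritParams distinctMarks
#' @return Integer sum of counted occurrences.
#' @export
totalOccurrences <- function(census, sample) {
  cts <- censusCounts(census)
  sum(cts$occurrences[cts$sample == sample])
}
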