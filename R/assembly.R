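## Monoisotopic residue masses (Da); water is added per peptide and cysteine
## carries the fixed carbamidomethyl group during digestion.
.residueMass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.waterMass <- 18.010565
.camMass <- 57.02146

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, with cysteines
#' statically carbamidomethylated (+57.02146 Da each).
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of masses in Da.
#' @export
peptideMass <- function(peptides) {
  vapply(peptides, function(p) {
    aa <- strsplit(p, "")[[1]]
    sum(.residueMass[aa]) + .waterMass + .camMass * sum(aa == "C")
  }, numeric(1), USE.NAMES = FALSE)
}

#' In silico tryptic digestion
#'
#' Cleaves a protein C-terminally to K or R except when the next residue is
#' proline, with no missed cleavages, and keeps the peptides whose
#' monoisotopic mass (fixed Cys carbamidomethylation included) falls inside
#' \code{mass_range}. Used to count the observable peptides entering the
#' emPAI denominator.
#'
#' @param sequence Protein sequence (single string).
#' @param mass_range Length-2 numeric, Da window (default 600-3600 Da).
#' @return Character vector of observable peptides.
#' @export
trypticDigest <- function(sequence, mass_range = c(600, 3600)) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0) return(character(0))
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n & aa[pmin(cut + 1L, n)] != "P" | cut == n]
  ends <- sort(unique(c(cut[cut < n], n)))
  starts <- c(1L, ends[-length(ends)] + 1L)
  peps <- substring(sequence, starts, ends)
  peps[peptideMass(peps) >= mass_range[1] & peptideMass(peps) <= mass_range[2]]
}

#' Map peptides to proteins and cluster indistinguishable loci
#'
#' Performs an exhaustive substring search of every distinct peptide against
#' the supplied protein sequences, then merges proteins whose matched-peptide
#' sets are identical into a single cluster locus (canonical locus id: the
#' lexicographically smallest member id). A peptide is unique when it matches
#' exactly one cluster; peptides matching no protein are retained but flagged
#' unmapped and excluded from downstream counts.
#'
#' @param psms PSM data.frame (typically the passing subset).
#' @param proteins Protein records to search (targets; decoys are ignored
#'   with a message if present).
#' @return A list of class \code{"PeptideProteinMap"} with elements
#'   \code{peptides} (peptide, n_clusters, unique, unmapped),
#'   \code{matches} (peptide, protein_id, start, locus),
#'   \code{clusters} (locus, member_ids, length) and \code{proteins}.
#' @export
mapPeptides <- function(psms, proteins) {
  md <- S4Vectors::mcols(proteins)
  if (!is.null(md$is_decoy) && any(md$is_decoy)) {
    proteins <- proteins[!md$is_decoy]
    md <- S4Vectors::mcols(proteins)
  }
  seqs <- as.character(proteins)
  ids <- names(proteins)
  peps <- sort(unique(psms$peptide))
  hits <- vector("list", length(peps))
  for (i in seq_along(peps)) {
    pos <- vapply(seqs, function(s) regexpr(peps[i], s, fixed = TRUE)[1],
                  integer(1), USE.NAMES = FALSE)
    hit <- pos > 0
    if (any(hit))
      hits[[i]] <- data.frame(peptide = peps[i], protein_id = ids[hit],
                              start = pos[hit], stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, hits)
  if (is.null(matches))
    matches <- data.frame(peptide = character(0), protein_id = character(0),
                          start = integer(0), stringsAsFactors = FALSE)
  ## cluster proteins by identical matched-peptide sets
  pepSet <- vapply(ids, function(id)
    paste(sort(matches$peptide[matches$protein_id == id]), collapse = "\r"),
    "")
  matched <- nzchar(pepSet)
  locusOf <- setNames(rep(NA_character_, length(ids)), ids)
  clusters <- data.frame(locus = character(0), member_ids = character(0),
                         length = integer(0), stringsAsFactors = FALSE)
  if (any(matched)) {
    grp <- unname(split(ids[matched], factor(pepSet[matched],
                                             levels = unique(pepSet[matched]))))
    clusters <- do.call(rbind, lapply(grp, function(members) {
      members <- sort(members)
      data.frame(locus = members[1],
                 member_ids = paste(members, collapse = ","),
                 length = max(Biostrings::width(proteins[members])),
                 stringsAsFactors = FALSE)
    }))
    rownames(clusters) <- NULL
    clusters <- clusters[order(clusters$locus), , drop = FALSE]
    for (k in seq_len(nrow(clusters)))
      locusOf[strsplit(clusters$member_ids[k], ",")[[1]]] <- clusters$locus[k]
  }
  matches$locus <- unname(locusOf[matches$protein_id])
  nClust <- vapply(peps, function(p)
    length(unique(matches$locus[matches$peptide == p])), integer(1),
    USE.NAMES = FALSE)
  peptides <- data.frame(peptide = peps, n_clusters = nClust,
                         unique = nClust == 1L, unmapped = nClust == 0L,
                         stringsAsFactors = FALSE)
  structure(list(peptides = peptides, matches = matches, clusters = clusters,
                 proteins = proteins), class = "PeptideProteinMap")
}

#' Per-locus spectral counts with shared-peptide distribution
#'
#' Each mapped PSM contributes one spectrum to its peptide's locus. Spectra
#' of peptides shared across two or more clusters are split across those
#' clusters proportionally to the clusters' unique-peptide spectral counts;
#' when no sharing cluster has unique evidence the spectra are split equally.
#' Unmapped peptides contribute nothing. Total counts are conserved: they sum
#' to the number of mapped PSMs.
#'
#' @param map A [mapPeptides()] result.
#' @param psms The PSM data.frame whose spectra are counted (typically the
#'   passing subset used to build \code{map}).
#' @return Named numeric vector of (possibly fractional) spectral counts per
#'   locus.
#' @export
spectralCounts <- function(map, psms) {
  counts <- setNames(numeric(nrow(map$clusters)), map$clusters$locus)
  if (!nrow(map$clusters)) return(counts)
  nSpec <- table(psms$peptide)
  pepLoci <- split(map$matches$locus, map$matches$peptide)
  pepLoci <- lapply(pepLoci, unique)
  pepInfo <- map$peptides
  ## unique evidence first
  uniq <- pepInfo$peptide[pepInfo$unique]
  for (p in intersect(uniq, names(nSpec)))
    counts[pepLoci[[p]]] <- counts[pepLoci[[p]]] + nSpec[[p]]
  uniqueEvidence <- counts
  ## distribute shared spectra
  shared <- pepInfo$peptide[pepInfo$n_clusters >= 2L]
  for (p in intersect(shared, names(nSpec))) {
    loci <- pepLoci[[p]]
    w <- uniqueEvidence[loci]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(loci), length(loci))
    counts[loci] <- counts[loci] + nSpec[[p]] * w
  }
  counts
}

#' Sequence coverage of a locus
#'
#' Fraction of the locus sequence touched by at least one matched peptide:
#' the length of the union of matched intervals divided by the sequence
#' length. For a cluster the longest member is used.
#'
#' @param map A [mapPeptides()] result.
#' @param locus Cluster/locus id.
#' @return Coverage fraction in [0, 1].
#' @export
peptideCoverage <- function(map, locus) {
  row <- map$clusters[map$clusters$locus == locus, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown locus '", locus, "'")
  members <- strsplit(row$member_ids, ",")[[1]]
  lens <- Biostrings::width(map$proteins[members])
  rep_id <- members[which.max(lens)]
  m <- map$matches[map$matches$protein_id == rep_id, , drop = FALSE]
  if (!nrow(m)) return(0)
  iv <- cbind(m$start, m$start + nchar(m$peptide) - 1L)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  covered <- 0; curS <- iv[1, 1]; curE <- iv[1, 2]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= curE + 1L) curE <- max(curE, iv[k, 2])
    else { covered <- covered + curE - curS + 1L; curS <- iv[k, 1]; curE <- iv[k, 2] }
  }
  covered <- covered + curE - curS + 1L
  covered / row$length
}

#' Normalized spectral abundance factor
#'
#' \code{NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)}: spectral count over
#' protein length, normalised to sum to 1 over the loci with nonzero counts.
#' Zero-count loci get 0 and are excluded from the normalising sum. Scale
#' invariant: doubling every count leaves the values unchanged.
#'
#' @param counts Named numeric vector of per-locus spectral counts.
#' @param lengths Numeric vector of per-locus lengths (residues), aligned
#'   with \code{counts}.
#' @return Numeric vector of NSAF values summing to 1.
#' @export
nsaf <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  if (all(counts == 0)) stop("all spectral counts are zero; NSAF is undefined")
  saf <- counts / lengths
  saf / sum(saf)
}

#' Exponentially modified protein abundance index
#'
#' \code{emPAI = 10^(N_observed / N_observable) - 1}, with the observed
#' distinct-peptide count capped at the observable count.
#'
#' @param observed Number of distinct peptides observed for the locus.
#' @param observable Number of observable peptides (from [trypticDigest()]
#'   within the mass window); must be >= 1.
#' @return Nonnegative abundance index (vectorised).
#' @export
empai <- function(observed, observable) {
  stopifnot(all(observable >= 1), all(observed >= 0))
  10^(pmin(observed, observable) / observable) - 1
}

#' Assemble per-locus protein quantification
#'
#' Runs the full assembly stage on a set of passing PSMs: peptide-protein
#' mapping with cluster merging, shared-peptide spectral-count distribution,
#' coverage, NSAF and emPAI. Protein-level spectral counts include
#' semi-tryptic PSMs; the PTM census (see [countOccurrences()]) does not.
#'
#' @param psms Passing PSM data.frame.
#' @param proteins Target protein records.
#' @param mass_range emPAI observability window in Da.
#' @return data.frame with columns \code{locus}, \code{member_ids},
#'   \code{unique_count}, \code{spectral_count}, \code{coverage},
#'   \code{nsaf}, \code{empai}, sorted by spectral count descending.
#' @export
proteinQuant <- function(psms, proteins, mass_range = c(600, 3600)) {
  map <- mapPeptides(psms, proteins)
  if (!nrow(map$clusters))
    return(data.frame(locus = character(0), member_ids = character(0),
                      unique_count = integer(0), spectral_count = numeric(0),
                      coverage = numeric(0), nsaf = numeric(0),
                      empai = numeric(0)))
  counts <- spectralCounts(map, psms)
  loci <- map$clusters$locus
  uniqPeps <- map$peptides$peptide[map$peptides$unique]
  uniqCount <- vapply(loci, function(l) {
    m <- map$matches[map$matches$locus == l, ]
    length(intersect(unique(m$peptide), uniqPeps))
  }, integer(1))
  cov <- vapply(loci, function(l) peptideCoverage(map, l), numeric(1))
  nPep <- vapply(loci, function(l)
    length(unique(map$matches$peptide[map$matches$locus == l])), integer(1))
  observable <- vapply(seq_along(loci), function(k) {
    members <- strsplit(map$clusters$member_ids[k], ",")[[1]]
    lens <- Biostrings::width(map$proteins[members])
    max(1L, length(trypticDigest(
      as.character(map$proteins[[members[which.max(lens)]]]), mass_range)))
  }, integer(1))
  out <- data.frame(locus = loci, member_ids = map$clusters$member_ids,
                    unique_count = uniqCount,
                    spectral_count = unname(counts[loci]),
                    coverage = cov,
                    nsaf = nsaf(unname(counts[loci]), map$clusters$length),
                    empai = empai(nPep, observable),
                    stringsAsFactors = FALSE)
  out[order(-out$spectral_count, out$locus), , drop = FALSE]
}
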