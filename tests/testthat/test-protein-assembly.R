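test_that("peptide mapping finds unique peptides, clusters identical proteins, flags unmapped", {
  prots <- toyProteins()  # P1 == P3, both share DDDFFFK with P2
  psms <- makePsms(rep(1, 4), peptide = c("AAAWWWK", "CCCYYYK", "DDDFFFK",
                                          "QQQQ"))
  map <- mapPeptides(psms, prots)
  ## identical proteins merge; canonical id is the smallest member
  expect_equal(sort(map$clusters$locus), c("P1", "P2"))
  expect_equal(map$clusters$member_ids[map$clusters$locus == "P1"], "P1,P3")
  pep <- map$peptides
  expect_true(pep$unique[pep$peptide == "AAAWWWK"])
  expect_true(pep$unique[pep$peptide == "CCCYYYK"])
  expect_false(pep$unique[pep$peptide == "DDDFFFK"])
  expect_equal(pep$n_clusters[pep$peptide == "DDDFFFK"], 2)
  expect_true(pep$unmapped[pep$peptide == "QQQQ"])
  ## matched positions are exact substring matches
  for (k in seq_len(nrow(map$matches))) {
    m <- map$matches[k, ]
    s <- as.character(prots[[m$protein_id]])
    expect_identical(substr(s, m$start, m$start + nchar(m$peptide) - 1L),
                     m$peptide)
  }
})

test_that("shared spectra split proportionally to unique evidence, equally without it", {
  prots <- toyProteins()
  ## 9 unique spectra for P1-cluster, 1 for P2, 10 shared
  psms <- makePsms(rep(1, 20),
                   peptide = c(rep("AAAWWWK", 9), "CCCYYYK",
                               rep("DDDFFFK", 10)))
  map <- mapPeptides(psms, prots)
  counts <- spectralCounts(map, psms)
  expect_equal(unname(counts["P1"]), 9 + 9)
  expect_equal(unname(counts["P2"]), 1 + 1)
  expect_equal(sum(counts), 20)

  ## equal split when no cluster has unique evidence among the counted spectra
  shared <- psms[psms$peptide == "DDDFFFK", ]
  counts2 <- spectralCounts(map, shared)
  expect_equal(unname(counts2["P1"]), 5)
  expect_equal(unname(counts2["P2"]), 5)

  ## no shared peptides: raw tallies
  uniqueOnly <- psms[psms$peptide != "DDDFFFK", ]
  map3 <- mapPeptides(uniqueOnly, prots)
  counts3 <- spectralCounts(map3, uniqueOnly)
  expect_equal(unname(counts3["P1"]), 9)
  expect_equal(unname(counts3["P2"]), 1)
})

test_that("spectral counts are conserved under shared-peptide splitting", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 1500, seed = 77),
                       ref, reverseDecoys(ref))
  keep <- !startsWith(psms$protein_ids, "Reverse_")
  map <- mapPeptides(psms[keep, ], ref)
  counts <- spectralCounts(map, psms[keep, ])
  mapped <- psms$peptide[keep] %in%
    map$peptides$peptide[!map$peptides$unmapped]
  expect_equal(sum(counts), sum(mapped), tolerance = 1e-9)
})

test_that("coverage is the union of matched intervals over the sequence length", {
  seqchars <- paste(rep(c("A", "D", "E", "F", "G", "H", "I", "L", "N", "Q",
                          "S", "T", "V", "W", "Y"), length.out = 100),
                    collapse = "")
  set.seed(4)
  seqchars <- paste(sample(strsplit(seqchars, "")[[1]]), collapse = "")
  prot <- proteinRecords("PX", seqchars)
  ## one 25-residue peptide on a 100-residue protein
  pep1 <- substr(seqchars, 11, 35)
  map1 <- mapPeptides(makePsms(1, peptide = pep1), prot)
  expect_equal(peptideCoverage(map1, "PX"), 0.25)
  ## overlapping 1-30 and 21-50: union is 50 residues
  psms2 <- makePsms(c(1, 1), peptide = c(substr(seqchars, 1, 30),
                                         substr(seqchars, 21, 50)))
  map2 <- mapPeptides(psms2, prot)
  expect_equal(peptideCoverage(map2, "PX"), 0.5)
  expect_error(peptideCoverage(map2, "nope"), "unknown locus")
})

test_that("NSAF normalises by length, sums to one, and is scale invariant", {
  expect_equal(nsaf(10, 100), 1)
  expect_equal(nsaf(c(10, 10), c(100, 200)), c(2 / 3, 1 / 3))
  v <- nsaf(c(3, 7, 11), c(120, 300, 80))
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_equal(nsaf(2 * c(3, 7, 11), c(120, 300, 80)), v)
  withZero <- nsaf(c(10, 0), c(100, 50))
  expect_equal(withZero, c(1, 0))
  expect_error(nsaf(c(0, 0), c(10, 10)), "zero")
})

test_that("emPAI follows the coverage-saturation formula and caps at observable", {
  expect_equal(empai(0, 10), 0)
  expect_equal(empai(10, 10), 9)
  expect_equal(empai(5, 10), 10^0.5 - 1, tolerance = 1e-12)
  expect_equal(empai(15, 10), 9)  # capped
  v <- empai(0:10, 10)
  expect_true(all(diff(v) > 0))
  expect_error(empai(5, 0), "observable")
})

test_that("tryptic digestion cuts after K/R except before P and filters by mass", {
  expect_equal(trypticDigest("AKRPGK", mass_range = c(0, 1e6)),
               c("AK", "RPGK"))
  expect_equal(trypticDigest("AAAGGG", mass_range = c(0, 1e6)), "AAAGGG")
  ## mass window: AK is far below 600 Da
  expect_false("AK" %in% trypticDigest("AKRPGK"))
  ## cysteine carries the fixed carbamidomethyl mass
  expect_equal(peptideMass("ACK"),
               71.03711 + 103.00919 + 128.09496 + 18.010565 + 57.02146,
               tolerance = 1e-9)
  expect_equal(peptideMass("ACCK") - peptideMass("AK"),
               2 * (103.00919 + 57.02146), tolerance = 1e-9)
})

test_that("protein quantification table is internally consistent", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 1200, seed = 13),
                       ref, reverseDecoys(ref))
  keep <- psms[!startsWith(psms$protein_ids, "Reverse_") &
               psms$sample == "sperm", ]
  q <- proteinQuant(keep, ref)
  expect_equal(sum(q$nsaf), 1, tolerance = 1e-9)
  expect_true(all(q$coverage >= 0 & q$coverage <= 1))
  expect_true(all(diff(q$spectral_count) <= 0))  # sorted descending
  expect_true(all(q$empai >= 0))
})
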