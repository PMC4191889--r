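test_that("mass deltas resolve to the correct PTM types", {
  expect_equal(annotateMod(42.0106, "K")$ptm_type, "ac")
  expect_equal(annotateMod(42.0471, "K")$ptm_type, "me3")
  expect_equal(annotateMod(14.0157, "R")$ptm_type, "me1")
  ## supplementary legends print me2 as 28.0313; the tolerance covers both
  expect_equal(annotateMod(28.0313, "K")$ptm_type, "me2")
  ub <- annotateMod(114.042927, "K")
  expect_equal(ub$ptm_type, "ub")
  expect_false(ub$counted_in_census)
  expect_error(annotateMod(50, "K"), "no modification")
  expect_error(annotateMod(79.9663, "K"), "no modification")  # ph not on K
  expect_error(annotateMod(42.03, "K", tolerance = 0.05), "ambiguous")
  expect_error(annotateMod(42.0106, "K", tolerance = 0), "tolerance")
})

test_that("site coordinates follow post-initiator-Met numbering", {
  ## protein starts with M: K at raw position 6 is K5
  sc <- siteCoordinates("SGRGK", data.frame(offset = 5, delta = 42.0106),
                        "MSGRGKAAAA", match_start = 2)
  expect_equal(sc$residue_index, 5)
  expect_equal(sc$residue_letter, "K")
  expect_equal(sc$ptm_type, "ac")
  expect_equal(sc$status, "counted")
  ## no Met adjustment when the protein does not start with M
  sc2 <- siteCoordinates("GRK", data.frame(offset = 3, delta = 14.0157),
                         "GRKAAA", match_start = 1)
  expect_equal(sc2$residue_index, 3)
  ## residue conflicting with the PTM's allowed residues is flagged
  sc3 <- siteCoordinates("SGRGK", data.frame(offset = 1, delta = 79.9663),
                         "MSGRGKAAAA", match_start = 2)
  expect_equal(sc3$ptm_type, "ph")      # valid assignment on S ...
  expect_equal(sc3$status, "excluded")  # ... but not census-countable
  sc4 <- siteCoordinates("SGRGK", data.frame(offset = 2, delta = 79.9663),
                         "MSGRGKAAAA", match_start = 2)
  expect_equal(sc4$status, "residue_conflict")
  expect_error(siteCoordinates("SGRGK", data.frame(offset = 9, delta = 1),
                               "MSGRGKAAAA", 2), "offset")
  expect_error(siteCoordinates("SGRGK", data.frame(offset = 1, delta = 1),
                               "MSGRGKAAAA", 3), "does not match")
})

test_that("cross-species mapping is the identity on identical sequences and symmetric", {
  ref <- makeReference()
  h3 <- as.character(ref[["ceH3"]])
  idx <- c(4, 9, 14, 23, 27, 36, 79)
  expect_equal(mapCrossSpecies(h3, h3, idx), idx)

  ceH2A <- as.character(ref[["ceH2A"]])
  mmH2A <- as.character(ref[["mmH2A"]])
  fwd <- mapCrossSpecies(ceH2A, mmH2A, 1:120)
  back <- mapCrossSpecies(mmH2A, ceH2A, fwd[!is.na(fwd)])
  expect_equal(back, (1:120)[!is.na(fwd)])
  expect_error(mapCrossSpecies("", "MARTK", 1), "empty")
})

test_that("occurrence counting follows the per-spectrum, per-modification rule", {
  prot <- proteinRecords("H3tst", "MARTKQTARKSTGGKAPRKQLATKAARKSAPA",
                         species = "synthetic", family = "H3")
  ## K14 is raw position 15: peptide starting at 11 has K14 at offset 5
  pep <- substr("MARTKQTARKSTGGKAPRKQLATKAARKSAPA", 11, 25)
  one <- makePsms(1, peptide = pep, protein = "H3tst",
                  mods = "5:42.010600")
  cen <- countOccurrences(one, prot)
  cts <- censusCounts(cen)
  expect_equal(nrow(cts), 1)
  expect_equal(cts$ce_site, "K14")
  expect_equal(cts$ptm_type, "ac")
  expect_equal(cts$occurrences, 1)

  ## a spectrum with two countable mods adds two occurrences
  two <- makePsms(1, peptide = pep, protein = "H3tst",
                  mods = "5:28.031400;14:42.010600")
  cen2 <- countOccurrences(two, prot)
  expect_equal(sum(censusCounts(cen2)$occurrences), 2)
  expect_setequal(censusCounts(cen2)$ce_site, c("K14", "K23"))

  ## three identical modified spectra count three occurrences at the site
  three <- makePsms(rep(1, 3), peptide = pep, protein = "H3tst",
                    mods = "5:42.010600")
  expect_equal(censusCounts(countOccurrences(three, prot))$occurrences, 3)

  ## ubiquitination is flagged-excluded, not counted
  ubq <- makePsms(1, peptide = pep, protein = "H3tst", mods = "5:114.042927")
  cenU <- countOccurrences(ubq, prot)
  expect_equal(nrow(censusCounts(cenU)), 0)
  expect_equal(flaggedModifications(cenU)$reason, "excluded")

  ## semi-tryptic PSMs are excluded from the census
  semi <- makePsms(1, peptide = pep, protein = "H3tst",
                   mods = "5:42.010600", tryptic = "half")
  expect_equal(nrow(censusCounts(countOccurrences(semi, prot))), 0)
})

test_that("census equals the brute-force (PSM x mod) enumeration oracle", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 100, seed = 301),
                       ref, reverseDecoys(ref))
  expect_lte(nrow(psms), 200)
  cen <- countOccurrences(psms, ref)
  got <- censusCounts(cen)[c("histone_family", "protein_id", "ce_site",
                             "ptm_type", "sample", "occurrences")]
  want <- bruteForceCensus(psms, ref)
  rownames(got) <- rownames(want) <- NULL
  got <- got[order(got$sample, got$histone_family, got$protein_id,
                   got$ce_site, got$ptm_type), ]
  rownames(got) <- NULL
  expect_equal(got, want)
})

test_that("census occurrences are conserved between counted and flagged sides", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 800, seed = 302),
                       ref, reverseDecoys(ref))
  cen <- countOccurrences(psms, ref)
  ## total = number of modification events on full-tryptic PSMs that map to
  ## a reference protein (every simulated peptide with mods does)
  sub <- psms[psms$tryptic_status == "full" & nzchar(psms$mods) &
              !startsWith(psms$protein_ids, "Reverse_"), ]
  nMods <- sum(lengths(regmatches(sub$mods, gregexpr(":", sub$mods))))
  expect_equal(sum(censusCounts(cen)$occurrences) +
               sum(flaggedModifications(cen)$occurrences), nMods)
})

test_that("census round-trips through TSV serialisation", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 600, seed = 303),
                       ref, reverseDecoys(ref))
  cen <- countOccurrences(psms, makeReference(),
                          cross_species = c(ceH2A = "mmH2A",
                                            ceH2B = "mmH2B"))
  path <- file.path(tempdir(), "census_rt.tsv")
  writeCensusTsv(cen, path)
  cen2 <- readCensusTsv(path)
  expect_equal(censusCounts(cen), censusCounts(cen2))
  expect_equal(flaggedModifications(cen), flaggedModifications(cen2))
})

test_that("distinct marks count (family, site, PTM) triples per sample", {
  pub <- censusFromCounts(publishedOccurrences())
  expect_equal(distinctMarks(pub, "embryo"), 31)
  expect_equal(distinctMarks(pub, "sperm"), 22)
  expect_equal(distinctMarks(pub, "unknown-sample"), 0)
  empty <- censusFromCounts(publishedOccurrences()[0, ])
  expect_equal(distinctMarks(empty, "sperm"), 0)
})
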