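test_that("subgroup assignment maps the 12 tag combinations and rejects others", {
  expect_identical(assignSubgroup("2", "full"), "2:full")
  combos <- expand.grid(c = chargeClasses(), t = trypticStatuses(),
                        stringsAsFactors = FALSE)
  keys <- assignSubgroup(combos$c, combos$t)
  expect_length(unique(keys), 12)
  expect_error(assignSubgroup("4", "full"), "charge_class")
  expect_error(assignSubgroup("2", "tryptic"), "tryptic_status")
})

test_that("perfectly separated classes give direct PSMs probability near 1", {
  set.seed(31)
  psms <- makePsms(c(rnorm(300, 5, 0.1), rnorm(300, 1, 0.1)),
                   decoy = rep(c(FALSE, TRUE), each = 300))
  model <- fitValidationModel(psms)
  p <- scoreProbability(model, psms)
  expect_true(all(p[1:300] > 0.99))
  expect_true(all(p[301:600] < 0.01))
})

test_that("identical direct and decoy distributions yield pi 1 and near-zero probabilities", {
  set.seed(32)
  psms <- makePsms(rnorm(10000, 2, 0.8),
                   decoy = rep(c(FALSE, TRUE), 5000))
  model <- fitValidationModel(psms)
  fit <- modelSubgroups(model)[["2:full"]]
  expect_equal(fit$piIncorrect, 1)
  p <- scoreProbability(model, psms)
  expect_lt(median(p), 0.1)
  expect_lt(mean(p), 0.1)
})

test_that("posterior agrees with the closed-form two-Gaussian oracle", {
  set.seed(33)
  x <- c(rnorm(2000, 2, 1), rnorm(2000, -2, 1))
  psms <- makePsms(x, decoy = rep(c(FALSE, TRUE), each = 2000))
  model <- fitValidationModel(psms)
  p <- scoreProbability(model, psms)
  oracle <- dnorm(x, 2, 1) / (dnorm(x, 2, 1) + dnorm(x, -2, 1))
  expect_lt(mean(abs(p - oracle)), 0.05)
})

test_that("probability is nondecreasing in the discriminant score per subgroup", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 3000, seed = 9),
                       ref, reverseDecoys(ref))
  model <- fitValidationModel(psms)
  s <- discriminantScores(model, psms)
  p <- scoreProbability(model, psms)
  for (key in unique(assignSubgroup(psms))) {
    sel <- assignSubgroup(psms) == key
    o <- order(s[sel])
    expect_false(is.unsorted(p[sel][o]))
  }
})

test_that("model validity holds and sparse subgroups fall back to the pooled fit", {
  set.seed(34)
  ## only 30 decoys in one subgroup: below n_min, must use the pooled model
  psms <- rbind(
    makePsms(rnorm(200, 4, 0.5)),
    makePsms(rnorm(200, 2, 0.5), decoy = TRUE),
    makePsms(rnorm(30, 4, 0.5), charge = "1", tryptic = "non"),
    makePsms(rnorm(30, 2, 0.5), decoy = TRUE, charge = "1", tryptic = "non"))
  model <- fitValidationModel(psms, n_min = 50)
  expect_true(validObject(model))
  fb <- fallbackUsed(model)
  expect_true(fb[["1:non"]])
  expect_false(fb[["2:full"]])
  ## scoring still works for the fallback subgroup
  p <- scoreProbability(model, psms)
  expect_true(all(is.finite(p)))

  expect_error(fitValidationModel(makePsms(rnorm(10, 3))), "no decoy")
  expect_error(fitValidationModel(makePsms(rnorm(10, 3), decoy = TRUE)),
               "no direct")
})

test_that("filtering applies the probability and ppm criteria with stated reasons", {
  model <- identityProbModel()  # probability == xcorr
  psms <- makePsms(xcorr = c(0.95, 0.95, 0.89, 0.90, 0.50),
                   ppm = c(-3, 6.5, 0, 6, 7))
  res <- filterPSMs(psms, model, p_min = 0.90, ppm_max = 6)
  expect_identical(res$spectrum_id, psms$spectrum_id)  # order preserved
  expect_equal(res$passed, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$fail_reason,
               c("none", "ppm_exceeded", "below_probability", "none",
                 "below_probability"))
  expect_true(all(res$passed == (res$fail_reason == "none")))
})

test_that("filtering an already-passing subset changes nothing", {
  ref <- ceReference()
  psms <- simulatePSMs(simulationConfig(n_psms_per_sample = 2000, seed = 21),
                       ref, reverseDecoys(ref))
  model <- fitValidationModel(psms)
  res <- filterPSMs(psms, model)
  sub <- res[res$passed, names(psms)]
  res2 <- filterPSMs(sub, model)
  expect_true(all(res2$passed))
  expect_equal(res2$probability, res$probability[res$passed])
})

test_that("decoy FDR is the decoy percentage among passing PSMs", {
  res <- makePsms(rep(1, 400))
  res$passed <- TRUE
  res$protein_ids[1:2] <- "Reverse_T1"
  expect_equal(estimateFDR(res), 0.5)
  res$protein_ids <- "T1"
  expect_equal(estimateFDR(res), 0)
  ## a PSM matching a target and a decoy is not a decoy PSM
  res$protein_ids[1] <- "Reverse_T1,T2"
  expect_equal(estimateFDR(res), 0)
  res$passed <- FALSE
  expect_error(estimateFDR(res), "no passing")
})
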