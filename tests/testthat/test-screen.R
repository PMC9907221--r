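test_that("window extraction handles protein termini and validates records", {
  prot <- "ACDEFGHIKLMNPQRSTVWY"   # length 20
  # interior mutation: full complement of windows containing the site
  w <- windowPeptides(prot, list(position = 10L, ref = "L", alt = "W"),
                      k = 9L)
  expect_identical(nrow(w), 9L)
  expect_identical(w$start, 2:10)
  expect_identical(w$offset, 9:1)
  expect_true(all(vapply(seq_len(9L), function(i)
    substr(w$peptide[i], w$offset[i], w$offset[i]) == "W", TRUE)))
  expect_true(all(nchar(w$peptide) == 9L))
  # N-terminal mutation: truncated windows are dropped
  w1 <- windowPeptides(prot, list(position = 1L, ref = "A", alt = "G"))
  expect_identical(nrow(w1), 1L)
  expect_identical(w1$start, 1L)
  expect_identical(w1$offset, 1L)
  # C-terminal mutation
  w2 <- windowPeptides(prot, list(position = 20L, ref = "Y", alt = "F"))
  expect_identical(nrow(w2), 1L)
  expect_identical(w2$start, 12L)
  expect_identical(w2$offset, 9L)
  # guards
  expect_error(windowPeptides(prot, list(position = 10L, ref = "A",
                                         alt = "W")), "reference mismatch")
  expect_error(windowPeptides(prot, list(position = 10L, ref = "L",
                                         alt = "L")), "alt residue")
  expect_error(windowPeptides(prot, list(position = 21L, ref = "A",
                                         alt = "W")), "outside protein")
  # protein shorter than the window yields no peptides
  w3 <- windowPeptides("ACDEFGH", list(position = 3L, ref = "D", alt = "Y"))
  expect_identical(nrow(w3), 0L)
})

test_that("matching scores are PWM probability sums with analytic normalization", {
  m <- matrix(1 / 20, 20L, 9L)
  m[1L, 1L] <- 0.5; m[-1L, 1L] <- 0.5 / 19
  pwm <- newPWM(m)
  ms <- matchingScore(c("ACDEFGHIK", "CCDEFGHIK"), pwm)
  expect_equal(ms$raw[1L], 0.5 + 8 / 20)
  expect_equal(ms$raw[2L], 0.5 / 19 + 8 / 20)
  # best peptide normalizes to 1, worst to 0
  expect_equal(ms$normalized[1L], 1)
  expect_equal(ms$normalized[2L], 0)
  none <- matchingScore("ACDEFGHIK", pwm, normalization = "none")
  expect_true(is.na(none$normalized))
  expect_warning(matchingScore("ACDEFGHIK", newPWM(matrix(1 / 20, 20L, 9L))),
                 "degenerate PWM")
})

test_that("discrimination metrics require both classes and detect separation", {
  expect_error(evaluateDiscrimination(1:5, rep(1L, 5L)), "no negative")
  expect_error(evaluateDiscrimination(1:5, rep(0L, 5L)), "no positive")
  perfect <- evaluateDiscrimination(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_identical(perfect$auc, 1)
  expect_lt(perfect$pValue, 0.2)
  inverted <- evaluateDiscrimination(c(10, 11, 1, 2), c(0, 0, 1, 1))
  expect_identical(inverted$auc, 0)
  # all-tied scores give AUC 0.5
  tied <- evaluateDiscrimination(rep(1, 6), c(0, 1, 0, 1, 0, 1))
  expect_identical(tied$auc, 0.5)
  expect_identical(perfect$n1, 2L)
  expect_identical(perfect$medianPositive, 10.5)
})

test_that("screening a planted cohort discriminates neoantigens", {
  w <- stdWorld()
  ch <- synthCohort(w$oracle, nProteins = 12L, proteinLength = 80L,
                    nMutations = 40L, plantedFraction = 0.4, seed = 23L)
  pwms <- lapply(oracleAlleles(w$oracle), function(al)
    hiddenPWM(w$oracle, al, 9L))
  names(pwms) <- oracleAlleles(w$oracle)
  res <- screenNeoantigens(ch$records, ch$proteins, pwms, w$oracle)
  expect_identical(res$skippedAlleles, character(0))
  expect_true(all(c("peptide", "allele", "raw", "normalized", "label")
                  %in% names(res$matches)))
  expect_true(any(res$matches$label == 1L))
  expect_gt(res$summary$auc, 0.9)
  expect_lt(res$summary$wilcoxonP, 1e-6)
  expect_gt(res$summary$medianNeo, res$summary$medianNonNeo)
  expect_identical(nrow(res$perAllele), 3L)
  expect_identical(sum(res$perAllele$nNeoantigen),
                   res$summary$nNeoantigen)
  # no duplicated (peptide, allele) pairs
  expect_false(any(duplicated(res$matches[, c("peptide", "allele")])))
})

test_that("screening skips alleles without a PWM and flags unknown proteins", {
  w <- stdWorld()
  ch <- synthCohort(w$oracle, nProteins = 5L, proteinLength = 60L,
                    nMutations = 10L, seed = 24L)
  pwms <- list(hiddenPWM(w$oracle, "SYN-01", 9L), NULL)
  names(pwms) <- c("SYN-01", "SYN-02")
  res <- screenNeoantigens(ch$records, ch$proteins, pwms, w$oracle)
  expect_identical(res$skippedAlleles, "SYN-02")
  expect_identical(unique(res$matches$allele), "SYN-01")
  bad <- ch$records
  bad$protein_id[1L] <- "NOPE"
  expect_error(screenNeoantigens(bad, ch$proteins, pwms, w$oracle),
               "unknown protein")
  empty <- screenNeoantigens(ch$records[0, ], ch$proteins, pwms, w$oracle)
  expect_identical(empty$skippedAlleles, character(0))
})
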