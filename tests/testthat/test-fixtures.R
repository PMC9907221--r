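test_that("oracle construction validates its parameters", {
  expect_error(makeHiddenOracle(kappa = 0.05), "kappa")
  expect_error(makeHiddenOracle(kappa = 1.2), "kappa")
  expect_error(makeHiddenOracle(lengths = 9L, nAnchors = 9L), "nAnchors")
  o <- makeHiddenOracle(2L, 9L, 4L, 0.9, seed = 3L)
  expect_identical(oracleAlleles(o), c("SYN-01", "SYN-02"))
  expect_true(all(nchar(oraclePseudoSequences(o)) == 34L))
  expect_identical(length(hiddenAnchors(o, "SYN-01", 9L)), 4L)
  expect_error(hiddenPWM(o, "SYN-01", 10L), "no hidden motif")
})

test_that("oracle scores span the full range with correct extremes", {
  w <- stdWorld()
  for (al in oracleAlleles(w$oracle)) {
    cons <- hiddenConsensus(w$oracle, al, 9L)
    expect_equal(presentationScores(w$oracle, cons, al), 1,
                 tolerance = 1e-12)
    # worst peptide: consensus nowhere
    m <- pwmMatrix(hiddenPWM(w$oracle, al, 9L))
    worst <- paste(AA_ALPHABET[apply(m, 2L, which.min)], collapse = "")
    expect_lt(presentationScores(w$oracle, worst, al), 1e-3)
  }
})

test_that("score increases monotonically as anchors are corrected", {
  w <- stdWorld()
  al <- "SYN-01"
  anc <- hiddenAnchors(w$oracle, al, 9L)
  m <- pwmMatrix(hiddenPWM(w$oracle, al, 9L))
  consIdx <- apply(m, 2L, which.max)
  # start from a peptide with every anchor wrong
  x <- consIdx
  for (p in anc) x[p] <- if (consIdx[p] == 1L) 2L else 1L
  scores <- numeric(length(anc) + 1L)
  scores[1L] <- presentationScores(
    w$oracle, paste(AA_ALPHABET[x], collapse = ""), al)
  for (k in seq_along(anc)) {
    x[anc[k]] <- consIdx[anc[k]]
    scores[k + 1L] <- presentationScores(
      w$oracle, paste(AA_ALPHABET[x], collapse = ""), al)
  }
  expect_true(all(diff(scores) > 0))
  # one missing anchor is never qualified; all matched always is
  expect_lt(scores[length(anc)], 0.75)
  expect_equal(scores[length(anc) + 1L], 1, tolerance = 1e-12)
})

test_that("uniform-random peptides virtually never qualify", {
  w <- stdWorld()
  set.seed(95)
  peps <- randomGenerate(10000L, lengths = 9L)
  for (al in oracleAlleles(w$oracle)) {
    s <- presentationScores(w$oracle, peps, al)
    expect_lt(mean(s > 0.75), 0.01)
  }
})

test_that("binding dataset is balanced, labeled by the oracle and reproducible", {
  w <- stdWorld()
  d <- synthBindingDataset(w$oracle, nPerAllele = 50L, seed = 17L)
  expect_identical(nrow(d), 3L * 100L)
  for (al in oracleAlleles(w$oracle)) {
    sub <- d[d$allele == al, ]
    expect_identical(sum(sub$measurement > 0.75), 50L)
    expect_identical(sum(sub$measurement <= 0.75), 50L)
    # measurements are exactly the oracle scores
    expect_equal(sub$measurement,
                 presentationScores(w$oracle, sub$peptide, al))
  }
  d2 <- synthBindingDataset(w$oracle, nPerAllele = 50L, seed = 17L)
  expect_identical(d, d2)
  d3 <- synthBindingDataset(w$oracle, nPerAllele = 50L, seed = 18L)
  expect_false(identical(d$peptide, d3$peptide))
})

test_that("top-scoring random peptides concentrate on the hidden anchors", {
  w <- stdWorld()
  al <- "SYN-02"
  set.seed(96)
  peps <- randomGenerate(20000L, lengths = 9L)
  s <- presentationScores(w$oracle, peps, al)
  top <- peps[order(-s)][1:200]
  pwm <- pwmMatrix(buildPWM(top))
  anc <- hiddenAnchors(w$oracle, al, 9L)
  hid <- pwmMatrix(hiddenPWM(w$oracle, al, 9L))
  consFreq <- pwm[cbind(apply(hid, 2L, which.max), seq_len(9L))]
  expect_gt(mean(consFreq[anc]), 3 * mean(consFreq[-anc]))
})

test_that("synthetic cohort plants consensus neoantigens behind real references", {
  w <- stdWorld()
  ch <- synthCohort(w$oracle, nProteins = 10L, proteinLength = 60L,
                    nMutations = 30L, plantedFraction = 0.4, seed = 19L)
  expect_identical(length(ch$proteins), 10L)
  expect_true(all(nchar(ch$proteins) == 60L))
  expect_identical(nrow(ch$records), 30L)
  validatePeptides(unname(ch$proteins), minLen = NA)
  # every record's reference residue matches its protein
  for (k in seq_len(nrow(ch$records))) {
    r <- ch$records[k, ]
    expect_identical(substr(ch$proteins[[r$protein_id]], r$position,
                            r$position), r$ref)
    expect_false(r$ref == r$alt)
  }
  # at least one mutant window hits a consensus exactly
  consAll <- vapply(oracleAlleles(w$oracle), function(al)
    hiddenConsensus(w$oracle, al, 9L), "")
  hit <- FALSE
  for (k in seq_len(nrow(ch$records))) {
    r <- ch$records[k, ]
    mut <- ch$proteins[[r$protein_id]]
    substr(mut, r$position, r$position) <- r$alt
    for (st in max(1L, r$position - 8L):min(r$position, nchar(mut) - 8L))
      if (substr(mut, st, st + 8L) %in% consAll) hit <- TRUE
  }
  expect_true(hit)
  ch2 <- synthCohort(w$oracle, nProteins = 10L, proteinLength = 60L,
                     nMutations = 30L, plantedFraction = 0.4, seed = 19L)
  expect_identical(ch, ch2)
})

test_that("cohort files round-trip through the production readers", {
  w <- stdWorld()
  ch <- synthCohort(w$oracle, nProteins = 5L, proteinLength = 40L,
                    nMutations = 10L, seed = 20L)
  dir <- tempfile()
  paths <- writeCohort(ch, dir)
  expect_true(all(file.exists(paths)))
  prot <- readProteins(paths[["proteins"]])
  expect_identical(prot, ch$proteins)
  recs <- readMutationRecords(paths[["mutations"]])
  expect_identical(recs$protein_id, ch$records$protein_id)
  expect_identical(recs$position, ch$records$position)
  expect_identical(recs$alt, ch$records$alt)
})
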