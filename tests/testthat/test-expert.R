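test_that("expert profiles are Laplace-smoothed frequencies of qualified binders", {
  pseudoA <- paste(rep("A", 34L), collapse = "")
  pseudoC <- paste(rep("C", 34L), collapse = "")
  dataset <- data.frame(
    allele = c(rep("AL-A", 3L), "AL-C"),
    peptide = c("ACDEFGHIK", "ACDEFGHIK", "YCDEFGHIK", "ACDEFGHIK"),
    measurement = c(0.9, 0.9, 0.8, 0.1))
  expert <- buildExpertPolicy(dataset,
                              c("AL-A" = pseudoA, "AL-C" = pseudoC),
                              minCount = 2L, pseudocount = 1)
  expect_identical(expertAlleles(expert), "AL-A")
  prof <- expertProfile(expert, "AL-A", 9L)
  expect_identical(dim(prof), c(20L, 9L))
  # position 1: A twice, Y once, pseudocount 1 -> (2+1)/(3+20)
  expect_equal(prof[1L, 1L], 3 / 23)
  expect_equal(prof[20L, 1L], 2 / 23)
  expect_equal(prof[3L, 1L], 1 / 23)
  expect_equal(colSums(prof), rep(1, 9L), ignore_attr = TRUE)
})

test_that("qualification rule handles scores and affinities; failure is loud", {
  expect_identical(defaultQualify(c(0.9, 0.5, 0.76)),
                   c(TRUE, FALSE, TRUE))
  expect_identical(defaultQualify(c(100, 600)), c(TRUE, FALSE))
  dataset <- data.frame(allele = "A", peptide = "ACDEFGHIK",
                        measurement = 0.1)
  expect_error(buildExpertPolicy(dataset, c(A = paste(rep("A", 34L),
                                                      collapse = ""))),
               "cannot build an expert policy")
})

test_that("position selection maximizes the popularity gap, ties to lowest index", {
  profile <- matrix(1 / 20, 20L, 3L)
  profile[, 1L] <- 0.5 / 19; profile[1L, 1L] <- 0.5   # peak on A
  profile[, 2L] <- 0.5 / 19; profile[20L, 2L] <- 0.5  # peak on Y
  # position 1 already holds its popular residue (gap 0); position 2 has C
  # where Y is popular (gap 0.5 - 0.5/19); position 3 is uniform (gap 0)
  expect_identical(expertSelectPosition("ACD", profile), 2L)
  # uniform profile: all gaps zero, tie broken at position 1
  expect_identical(expertSelectPosition("ACD", matrix(1 / 20, 20L, 3L)), 1L)
  expect_error(expertSelectPosition("ACDE", profile), "does not match")
})

test_that("expert actions are genuine mutations", {
  set.seed(33)
  profile <- t(randomSimplex(9L))
  for (i in 1:50) {
    pep <- paste(sample(AA_ALPHABET, 9L, replace = TRUE), collapse = "")
    act <- expertAction(pep, profile)
    expect_true(act$position >= 1L && act$position <= 9L)
    expect_false(substr(pep, act$position, act$position) == act$residue)
  }
  expect_error(
    expertSampleResidue(1L, cbind(c(1, rep(0, 19))), "A"),
    "degenerate")
})

test_that("nearest-allele fallback uses BLOSUM62 similarity with lexicographic ties", {
  w <- stdWorld()
  reg <- w$pseudo
  # identical pseudo sequence resolves to that allele at similarity 1
  nn <- nearestAllele(reg[[2L]], reg)
  expect_identical(nn$allele, names(reg)[2L])
  expect_identical(nn$similarity, 1)
  # two identical candidates: lexicographically first name wins
  reg2 <- c(B = reg[[1L]], A = reg[[1L]])
  expect_identical(nearestAllele(reg[[1L]], reg2)$allele, "A")
  expect_error(nearestAllele(reg[[1L]], character(0)), "empty")
  expect_error(nearestAllele("ACD", reg), "34")
})

test_that("profile lookup falls back for alleles without data", {
  w <- stdWorld()
  direct <- expertProfile(w$expert, "SYN-01", 9L)
  expect_identical(dim(direct), c(20L, 9L))
  # unknown allele with SYN-01's pseudo sequence gets SYN-01's profile
  fb <- expertProfile(w$expert, "UNSEEN", 9L, pseudo = w$pseudo[["SYN-01"]])
  expect_identical(fb, direct)
  expect_error(expertProfile(w$expert, "UNSEEN", 9L),
               "no pseudo sequence supplied")
  expect_error(expertProfile(w$expert, "UNSEEN", 10L,
                             pseudo = w$pseudo[["SYN-01"]]),
               "length 10")
})

test_that("expert profile consensus recovers the hidden anchors", {
  w <- stdWorld()
  for (al in names(w$pseudo)) {
    prof <- expertProfile(w$expert, al, 9L)
    hid <- pwmMatrix(hiddenPWM(w$oracle, al, 9L))
    anc <- hiddenAnchors(w$oracle, al, 9L)
    expect_identical(apply(prof[, anc, drop = FALSE], 2L, which.max),
                     apply(hid[, anc, drop = FALSE], 2L, which.max))
  }
})
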