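pseudoX <- paste(rep("A", 34L), collapse = "")

mkState <- function(peptide = "ACDEFGHIK") {
  new("EnvState", peptide = peptide, allele = "X", pseudo = pseudoX,
      step = 0L, score = NA_real_, done = FALSE)
}

test_that("policy initialization and embeddings have the documented shapes", {
  pol <- tinyPolicy()
  expect_s4_class(pol, "MutationPolicy")
  emb <- embedState(pol, mkState())
  expect_identical(dim(emb$h), c(9L, 12L))     # l x 2H, H = 6
  expect_identical(length(emb$hp), 12L)
  expect_identical(length(emb$hm), 12L)
  expect_true(all(is.finite(emb$h)))
  out <- capture.output(show(pol))
  expect_true(any(grepl("MutationPolicy", out)))
})

test_that("action distributions are normalized and mask the current residue", {
  pol <- tinyPolicy()
  s <- mkState("ACDEFGHIK")
  for (pos in c(1L, 5L, 9L)) {
    d <- actionDistributions(pol, s, position = pos)
    expect_equal(sum(d$positionProbs), 1, tolerance = 1e-12)
    expect_equal(sum(d$residueProbs), 1, tolerance = 1e-12)
    cur <- aaIndex(substr("ACDEFGHIK", pos, pos))
    expect_identical(d$residueProbs[cur], 0)
    expect_true(all(d$residueProbs[-cur] > 0))
    expect_true(is.finite(d$value))
  }
})

test_that("sampled actions are never no-ops and reproduce their log probability", {
  pol <- tinyPolicy()
  set.seed(71)
  for (i in 1:60) {
    pep <- paste(sample(AA_ALPHABET, 9L, replace = TRUE), collapse = "")
    s <- mkState(pep)
    a <- sampleAction(pol, s)
    expect_false(substr(pep, a$position, a$position) == a$residue)
    ev <- evaluateActions(pol, list(s), a$position, aaIndex(a$residue))
    expect_equal(ev$logProbs, a$logProb, tolerance = 1e-12)
    expect_equal(ev$values, a$value, tolerance = 1e-12)
    expect_gt(ev$entropies, 0)
  }
})

test_that("evaluateActions rejects no-op actions", {
  pol <- tinyPolicy()
  s <- mkState("ACDEFGHIK")
  expect_error(evaluateActions(pol, list(s), 1L, aaIndex("A")),
               "already present")
})

test_that("batched evaluation matches per-state evaluation", {
  pol <- tinyPolicy()
  set.seed(72)
  peps <- replicate(5, paste(sample(AA_ALPHABET, 9L, replace = TRUE),
                             collapse = ""))
  states <- lapply(peps, mkState)
  pos <- sample.int(9L, 5L, replace = TRUE)
  res <- vapply(seq_len(5L), function(i) {
    cur <- aaIndex(substr(peps[i], pos[i], pos[i]))
    sample(setdiff(1:20, cur), 1L)
  }, 0L)
  batch <- evaluateActions(pol, states, pos, res)
  for (i in seq_len(5L)) {
    one <- evaluateActions(pol, states[i], pos[i], res[i])
    expect_equal(batch$logProbs[i], one$logProbs, tolerance = 1e-12)
    expect_equal(batch$values[i], one$values, tolerance = 1e-12)
    expect_equal(batch$entropies[i], one$entropies, tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip the full policy", {
  pol <- tinyPolicy()
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(pol, path)
  back <- loadCheckpoint(path)
  expect_equal(back@params, pol@params)
  expect_equal(back@boundary, pol@boundary)
  expect_identical(back@hidden, pol@hidden)
  s <- mkState()
  expect_equal(actionDistributions(back, s, 3L),
               actionDistributions(pol, s, 3L), tolerance = 1e-15)
  # format and alphabet guards
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(loadCheckpoint(bad), "not a PepPPO checkpoint")
  ck <- readRDS(path)
  ck$alphabet <- rev(ck$alphabet)
  saveRDS(ck, bad)
  expect_error(loadCheckpoint(bad), "alphabet")
})

test_that("analytic gradients match central finite differences", {
  pol <- tinyPolicy()
  set.seed(73)
  B <- 4L
  X <- matrix(sample.int(20L, B * 9L, replace = TRUE), B, 9L)
  ai <- rep(1L, B)
  pil <- list(aaIndex(pseudoX, split = TRUE))
  pos <- sample.int(9L, B, replace = TRUE)
  res <- vapply(seq_len(B), function(i)
    sample(setdiff(1:20, X[i, pos[i]]), 1L), 0L)
  ceLoss <- function(p) {
    cache <- PepPPO:::.policyForwardA(p, X, ai, pil)
    fb <- PepPPO:::.policyForwardB(p, cache, pos)
    ii <- cbind(seq_len(B), pos)
    sum(-log(cache$posProbs[ii]) -
          log(fb$resProbs[cbind(seq_len(B), res)]))
  }
  g <- PepPPO:::.imitationGroupGrads(pol, X, ai, pil, pos, res, 1)$grads
  eps <- 1e-5
  probe <- list(c("fWx", 1L), c("bWh", 7L), c("W2m", 11L), c("W1c", 3L),
                c("wc", 2L), c("W1d", 5L), c("emb", 9L), c("bd", 1L))
  for (pr in probe) {
    nm <- pr[1L]; idx <- as.integer(pr[2L])
    up <- pol; up@params[[nm]][idx] <- up@params[[nm]][idx] + eps
    dn <- pol; dn@params[[nm]][idx] <- dn@params[[nm]][idx] - eps
    num <- (ceLoss(up) - ceLoss(dn)) / (2 * eps)
    expect_equal(g[[nm]][idx], num, tolerance = 1e-4,
                 label = paste("grad", nm, idx))
  }
  # value-head weights do not affect the action cross-entropy
  expect_equal(max(abs(g$wv2)), 0)
})
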