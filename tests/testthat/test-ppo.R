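test_that("ppoConfig validates its hyperparameters", {
  cfg <- ppoConfig()
  expect_s3_class(cfg, "PPOConfig")
  expect_identical(cfg$gamma, 0.99)
  expect_identical(cfg$lam, 0.95)
  expect_identical(cfg$epsClip, 0.2)
  expect_identical(c(cfg$alpha1, cfg$alpha2, cfg$alpha3), c(0.5, 0.1, 0.01))
  expect_identical(cfg$N, 2048L)
  expect_identical(cfg$K, 4L)
  expect_identical(cfg$minibatch, 256L)
  expect_identical(cfg$expertFractionInit, 0.5)
  expect_identical(cfg$expertDecayFrac, 0.2)
  expect_error(ppoConfig(gamma = 0))
  expect_error(ppoConfig(gamma = 1.1))
  expect_error(ppoConfig(lam = -0.1))
  expect_error(ppoConfig(epsClip = 0))
  expect_error(ppoConfig(alpha1 = -1))
})

test_that("rewardsToGo discounts a sparse terminal reward", {
  expect_equal(rewardsToGo(c(0, 0, 1), 0.5), c(0.25, 0.5, 1))
  expect_equal(rewardsToGo(c(0, 0, 0.8), 1), c(0.8, 0.8, 0.8))
  expect_equal(rewardsToGo(0.3, 0.9), 0.3)
  expect_equal(rewardsToGo(c(0, 0, 0), 0.9), c(0, 0, 0))
  expect_error(rewardsToGo(numeric(0), 0.9), "empty")
  expect_error(rewardsToGo(c(0.2, 0, 1), 0.9), "terminal-reward-only")
})

test_that("gaeAdvantages matches hand-computed cases", {
  # T = 1: A = r + gamma * bootstrap - V
  expect_equal(gaeAdvantages(1, 0.4, 0.9, 0.95), 1 - 0.4)
  expect_equal(gaeAdvantages(1, 0.4, 0.9, 0.95, bootstrap = 0.5),
               1 + 0.9 * 0.5 - 0.4)
  # lam = 0 reduces to one-step TD errors
  r <- c(0, 0, 1); v <- c(0.1, 0.2, 0.3)
  expect_equal(gaeAdvantages(r, v, 0.9, 0),
               c(0 + 0.9 * 0.2 - 0.1, 0 + 0.9 * 0.3 - 0.2, 1 - 0.3))
  # lam = 1, V = 0: advantages equal rewards-to-go
  expect_equal(gaeAdvantages(r, rep(0, 3), 0.9, 1), rewardsToGo(r, 0.9))
  expect_error(gaeAdvantages(r, v[1:2], 0.9, 0.95), "equal length")
})

test_that("clipped surrogate implements the pessimistic min", {
  # phi = 2, A = 1: clip to 1.2
  expect_equal(clippedSurrogate(log(2), 0, 1, 0.2), 1.2)
  # phi = 2, A = -1: unclipped -2 is the min
  expect_equal(clippedSurrogate(log(2), 0, -1, 0.2), -2)
  # phi = 0.5, A = -1: clip at 0.8 -> -0.8
  expect_equal(clippedSurrogate(log(0.5), 0, -1, 0.2), -0.8)
  # phi = 0.5, A = 1: unclipped 0.5
  expect_equal(clippedSurrogate(log(0.5), 0, 1, 0.2), 0.5)
  # batch mean
  expect_equal(clippedSurrogate(c(log(2), 0), c(0, 0), c(1, 1), 0.2),
               (1.2 + 1) / 2)
  expect_error(clippedSurrogate(1e6, -1e6, 1, 0.2), "non-finite")
})

test_that("value and combined losses follow the stated arithmetic", {
  expect_equal(valueLoss(c(1, 2), c(0, 0)), 2.5)
  expect_equal(valueLoss(0.3, 0.3), 0)
  cfg <- ppoConfig()
  # L = -0.4 + 0.5*1 + 0.1*2 - 0.01*4 = 0.26
  expect_equal(combinedLoss(0.4, 1, 2, 4, cfg), 0.26)
})

test_that("rollouts collect enough complete-episode transitions deterministically", {
  w <- stdWorld()
  pol <- tinyPolicy()
  cfg <- ppoConfig(N = 60L, batchEnvs = 16L)
  ecfg <- envConfig(maxSteps = 4L)
  set.seed(81)
  trajs <- collectRollouts(pol, w$oracle, w$pseudo, cfg, ecfg)
  steps <- vapply(trajs, function(tr) length(tr$positions), 0L)
  expect_gte(sum(steps), 60L)
  expect_true(all(steps >= 1L & steps <= 4L))
  for (tr in trajs[1:5]) {
    T <- length(tr$positions)
    expect_identical(nrow(tr$X), T)
    expect_identical(length(tr$logProbs), T)
    expect_identical(tr$rewards[T], tr$terminalScore)
    if (T > 1L) expect_true(all(tr$rewards[-T] == 0))
    expect_equal(tr$returns, rewardsToGo(tr$rewards, cfg$gamma))
    expect_equal(tr$advantages,
                 gaeAdvantages(tr$rewards, tr$values, cfg$gamma, cfg$lam))
    expect_true(tr$allele %in% names(w$pseudo))
    # pre-mutation states: action never a no-op
    expect_true(all(tr$X[cbind(seq_len(T), tr$positions)] != tr$residues))
  }
  # seeded reproducibility
  set.seed(81)
  trajs2 <- collectRollouts(pol, w$oracle, w$pseudo, cfg, ecfg)
  expect_identical(trajs[[1L]]$X, trajs2[[1L]]$X)
  expect_identical(vapply(trajs, `[[`, 0, "terminalScore"),
                   vapply(trajs2, `[[`, 0, "terminalScore"))
})

test_that("expert-driven rollouts take expert positions", {
  w <- stdWorld()
  pol <- tinyPolicy()
  cfg <- ppoConfig(N = 30L, batchEnvs = 8L)
  set.seed(82)
  trajs <- collectRollouts(pol, w$oracle, w$pseudo, cfg,
                           envConfig(maxSteps = 4L), expert = w$expert,
                           expertFraction = 1)
  expect_true(all(vapply(trajs, `[[`, TRUE, "expert")))
  for (tr in trajs[1:5]) {
    prof <- expertProfile(w$expert, tr$allele, ncol(tr$X),
                          w$pseudo[[tr$allele]])
    for (t in seq_along(tr$positions)) {
      pep <- matrixToPeptides(tr$X[t, , drop = FALSE])
      expect_identical(tr$positions[t], expertSelectPosition(pep, prof))
    }
    expect_true(all(is.finite(tr$logProbs)))
  }
})

test_that("PPO gradients match finite differences on the exact update loss", {
  w <- stdWorld()
  pol <- tinyPolicy()
  set.seed(83)
  B <- 5L
  X <- matrix(sample.int(20L, B * 9L, replace = TRUE), B, 9L)
  ai <- sample.int(length(w$pseudo), B, replace = TRUE)
  pil <- lapply(w$pseudo, aaIndex, split = TRUE)
  pos <- sample.int(9L, B, replace = TRUE)
  res <- vapply(seq_len(B), function(i)
    sample(setdiff(1:20, X[i, pos[i]]), 1L), 0L)
  adv <- rnorm(B); ret <- runif(B)
  cfg <- ppoConfig()
  base <- evaluateActions(
    pol, lapply(seq_len(B), function(i)
      new("EnvState", peptide = matrixToPeptides(X[i, , drop = FALSE]),
          allele = names(w$pseudo)[ai[i]], pseudo = w$pseudo[[ai[i]]],
          step = 0L, score = NA_real_, done = FALSE)),
    pos, res)
  oldLp <- base$logProbs + rnorm(B, sd = 0.1)
  ppoLoss <- function(p) {
    ev <- evaluateActions(
      p, lapply(seq_len(B), function(i)
        new("EnvState", peptide = matrixToPeptides(X[i, , drop = FALSE]),
            allele = names(w$pseudo)[ai[i]], pseudo = w$pseudo[[ai[i]]],
            step = 0L, score = NA_real_, done = FALSE)),
      pos, res)
    -clippedSurrogate(ev$logProbs, oldLp, adv, cfg$epsClip) +
      cfg$alpha1 * valueLoss(ev$values, ret) -
      cfg$alpha3 * mean(ev$entropies)
  }
  g <- PepPPO:::.ppoGroupGrads(pol, X, ai, pil, pos, res, oldLp, adv, ret,
                               cfg, B)$grads
  eps <- 1e-5
  probe <- list(c("fWx", 4L), c("bWx", 2L), c("W1m", 6L), c("W2c", 3L),
                c("W3d", 8L), c("Wv1", 5L), c("wv2", 1L), c("b1d", 2L))
  for (pr in probe) {
    nm <- pr[1L]; idx <- as.integer(pr[2L])
    up <- pol; up@params[[nm]][idx] <- up@params[[nm]][idx] + eps
    dn <- pol; dn@params[[nm]][idx] <- dn@params[[nm]][idx] - eps
    num <- (ppoLoss(up) - ppoLoss(dn)) / (2 * eps)
    expect_equal(g[[nm]][idx], num, tolerance = 1e-3,
                 label = paste("PPO grad", nm, idx))
  }
})

test_that("pretraining is a no-op at zero epochs and reduces the loss otherwise", {
  w <- stdWorld()
  pol <- tinyPolicy()
  same <- pretrainPolicy(pol, w$expert, w$pseudo, epochs = 0L)
  expect_identical(same$policy@params, pol@params)
  expect_identical(same$losses, numeric(0))
  set.seed(84)
  fit <- pretrainPolicy(pol, w$expert, w$pseudo, nStates = 128L,
                        epochs = 4L, minibatch = 64L, lr = 2e-3)
  expect_identical(length(fit$losses), 4L)
  expect_lt(fit$losses[4L], fit$losses[1L])
})

test_that("buffer cross-entropy is zero on an empty batch and finite otherwise", {
  w <- stdWorld()
  pol <- tinyPolicy()
  expect_identical(bufferCELoss(pol, list(), w$pseudo), 0)
  batch <- list(list(peptide = "ACDEFGHIK", allele = names(w$pseudo)[1L],
                     position = 2L, residue = 5L))
  l <- bufferCELoss(pol, batch, w$pseudo)
  expect_true(is.finite(l) && l > 0)
})

test_that("a short PPO run produces well-formed metrics", {
  w <- stdWorld()
  set.seed(85)
  pol <- initPolicy(encodingConfig(), 8L, 8L, 8L)
  buf <- experienceBuffer(500L)
  fit <- trainPepPPO(w$oracle, w$pseudo,
                     ppoConfig(N = 64L, iterations = 2L, minibatch = 64L,
                               batchEnvs = 16L, K = 2L),
                     envConfig(maxSteps = 4L), policy = pol,
                     expert = w$expert, buffer = buf)
  m <- fit$metrics
  expect_identical(nrow(m), 2L)
  expect_identical(m$iteration, 1:2)
  expect_true(all(c("meanTerminalScore", "qualifiedFraction",
                    "meanEpisodeLength", "surrogate", "valueLoss",
                    "bufferCE", "entropy", "expertFraction") %in% names(m)))
  expect_true(all(m$meanTerminalScore >= 0 & m$meanTerminalScore <= 1))
  expect_true(all(m$qualifiedFraction >= 0 & m$qualifiedFraction <= 1))
  expect_true(all(m$meanEpisodeLength >= 1 & m$meanEpisodeLength <= 4))
  expect_true(all(is.finite(m$entropy)))
  # expert mixing decays across iterations
  expect_identical(m$expertFraction[1L], 0.5)
  expect_lt(m$expertFraction[2L], m$expertFraction[1L])
  expect_s4_class(fit$policy, "MutationPolicy")
})
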