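#' PPO training configuration
#'
#' Validated list of hyperparameters for proximal policy optimization over
#' the mutation environment. Defaults follow common PPO practice: discount
#' `gamma = 0.99`, GAE `lam = 0.95`, clip radius `epsClip = 0.2`, loss
#' coefficients `alpha1 = 0.5` (value), `alpha2 = 0.1` (buffer imitation),
#' `alpha3 = 0.01` (entropy), `N = 2048` environment steps per iteration
#' optimized for `K = 4` epochs in minibatches of 256. The expert-mixing
#' fraction starts at `expertFractionInit` and decays linearly to zero over
#' the first `expertDecayFrac` of the iterations.
#'
#' @param gamma Discount factor in (0, 1].
#' @param lam GAE bias/variance trade-off in `[0, 1]`.
#' @param epsClip PPO clip radius (> 0).
#' @param alpha1,alpha2,alpha3 Nonnegative loss coefficients.
#' @param N Environment steps collected per iteration.
#' @param K Optimization epochs per iteration.
#' @param minibatch Minibatch size.
#' @param lr Adam learning rate.
#' @param iterations Training iterations.
#' @param expertFractionInit Initial fraction of episodes driven by the
#'   expert policy.
#' @param expertDecayFrac Fraction of iterations over which expert mixing
#'   decays to zero.
#' @param normalizeAdvantages Mean/sd-normalize advantages per iteration
#'   batch (order-preserving).
#' @param batchEnvs Episodes simulated simultaneously during collection.
#' @return An object of class `PPOConfig` (validated list).
#' @export
ppoConfig <- function(gamma = 0.99, lam = 0.95, epsClip = 0.2,
                      alpha1 = 0.5, alpha2 = 0.1, alpha3 = 0.01,
                      N = 2048L, K = 4L, minibatch = 256L, lr = 3e-4,
                      iterations = 50L, expertFractionInit = 0.5,
                      expertDecayFrac = 0.2, normalizeAdvantages = TRUE,
                      batchEnvs = 128L) {
  stopifnot(gamma > 0, gamma <= 1, lam >= 0, lam <= 1, epsClip > 0,
            alpha1 >= 0, alpha2 >= 0, alpha3 >= 0, N >= 1, K >= 1,
            minibatch >= 1, lr > 0, iterations >= 1,
            expertFractionInit >= 0, expertFractionInit <= 1,
            expertDecayFrac >= 0, expertDecayFrac <= 1)
  structure(list(gamma = gamma, lam = lam, epsClip = epsClip,
                 alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 N = as.integer(N), K = as.integer(K),
                 minibatch = as.integer(minibatch), lr = lr,
                 iterations = as.integer(iterations),
                 expertFractionInit = expertFractionInit,
                 expertDecayFrac = expertDecayFrac,
                 normalizeAdvantages = normalizeAdvantages,
                 batchEnvs = as.integer(batchEnvs)),
            class = "PPOConfig")
}

#' Rewards-to-go of a sparse-reward episode
#'
#' With a single terminal reward `r_T`, the return from step t is
#' `gamma^(T - t) * r_T`. Steps are 1-based transition indices, so the
#' final transition (t = T) has return `r_T` itself.
#'
#' @param rewards Per-transition reward vector: zero everywhere except the
#'   final entry (enforced).
#' @param gamma Discount factor.
#' @return Numeric vector of per-step returns.
#' @export
rewardsToGo <- function(rewards, gamma) {
  T <- length(rewards)
  if (T == 0L) stop("empty episode")
  if (T > 1L && any(rewards[-T] != 0))
    stop("episode is not terminal-reward-only: nonzero reward before the ",
         "final transition (incomplete episode?)")
  gamma^(T - seq_len(T)) * rewards[T]
}

#' Generalized advantage estimation
#'
#' `A_t = sum_k (gamma * lam)^k * delta_{t+k}` with
#' `delta_t = r_t + gamma * V(s_{t+1}) - V(s_t)`, computed by the standard
#' backward recursion. `values` holds `V(s_t)` for the T pre-transition
#' states; the value of the terminal state defaults to `bootstrap = 0`.
#'
#' @param rewards Per-transition rewards (length T).
#' @param values Per-state value estimates (length T).
#' @param gamma,lam GAE hyperparameters.
#' @param bootstrap Value assigned to the terminal state.
#' @return Numeric vector of advantages (length T).
#' @export
gaeAdvantages <- function(rewards, values, gamma, lam, bootstrap = 0) {
  T <- length(rewards)
  if (length(values) != T)
    stop("rewards and values must have equal length (",
         T, " vs ", length(values), ")")
  nextV <- c(values[-1L], bootstrap)
  delta <- rewards + gamma * nextV - values
  adv <- numeric(T)
  acc <- 0
  for (t in rev(seq_len(T))) {
    acc <- delta[t] + gamma * lam * acc
    adv[t] <- acc
  }
  adv
}

#' PPO clipped surrogate objective
#'
#' Mean over the batch of `min(phi * A, clip(phi, 1 - eps, 1 + eps) * A)`
#' with `phi = exp(new - old)`.
#'
#' @param logProbsNew,logProbsOld Aligned log-probability vectors.
#' @param advantages Aligned advantage estimates.
#' @param epsClip Clip radius.
#' @return Scalar objective (to be maximized).
#' @export
clippedSurrogate <- function(logProbsNew, logProbsOld, advantages,
                             epsClip) {
  phi <- exp(logProbsNew - logProbsOld)
  if (any(!is.finite(phi)))
    stop("non-finite probability ratio at transition ",
         which(!is.finite(phi))[1L])
  clipped <- pmin(pmax(phi, 1 - epsClip), 1 + epsClip)
  mean(pmin(phi * advantages, clipped * advantages))
}

#' Value-function loss
#' @param values Predicted state values.
#' @param returns Empirical returns (rewards-to-go).
#' @return Mean squared error.
#' @export
valueLoss <- function(values, returns) mean((values - returns)^2)

#' Combined PPO objective
#'
#' `L = -L_CLIP + alpha1 * L_V + alpha2 * L_B - alpha3 * H`, the scalar
#' minimized at each update.
#'
#' @param surrogate Clipped surrogate value `L_CLIP`.
#' @param vLoss Value loss `L_V`.
#' @param bufferCE Buffer imitation cross-entropy `L_B`.
#' @param entropy Mean action entropy `H`.
#' @param cfg A [ppoConfig()].
#' @return Scalar loss.
#' @export
combinedLoss <- function(surrogate, vLoss, bufferCE, entropy, cfg) {
  -surrogate + cfg$alpha1 * vLoss + cfg$alpha2 * bufferCE -
    cfg$alpha3 * entropy
}

# ---- internal batched rollout machinery ----

# forward a set of same-length states and sample (or take expert) actions
.actBatch <- function(policy, X, alleleIdx, pseudoIdxList, expertFlags,
                      expertProfiles) {
  cache <- .policyForwardA(policy, X, alleleIdx, pseudoIdxList)
  B <- nrow(X); l <- ncol(X)
  pos <- integer(B)
  for (b in seq_len(B)) {
    if (expertFlags[b]) {
      prof <- expertProfiles[[alleleIdx[b]]]
      gaps <- prof[cbind(max.col(t(prof), ties.method = "first"),
                         seq_len(l))] - prof[cbind(X[b, ], seq_len(l))]
      pos[b] <- which.max(gaps)
    } else {
      pos[b] <- sample.int(l, 1L, prob = cache$posProbs[b, ])
    }
  }
  fb <- .policyForwardB(policy, cache, pos)
  res <- integer(B)
  for (b in seq_len(B)) {
    if (expertFlags[b]) {
      p <- expertProfiles[[alleleIdx[b]]][, pos[b]]
      p[X[b, pos[b]]] <- 0
      res[b] <- sample.int(20L, 1L, prob = p)
    } else {
      res[b] <- sample.int(20L, 1L, prob = fb$resProbs[b, ])
    }
  }
  lp <- log(cache$posProbs[cbind(seq_len(B), pos)]) +
    log(pmax(fb$resProbs[cbind(seq_len(B), res)], 1e-300))
  list(pos = pos, res = res, logp = lp, value = cache$value)
}

#' Collect PPO rollouts
#'
#' Simulates batched episodes until at least `nSteps` transitions from
#' complete episodes are available. Each episode targets an allele drawn
#' uniformly from `pseudo` and starts from a uniform-random peptide. A
#' fraction of episodes follows the expert policy's actions; their log
#' probabilities are evaluated under the current policy at collection time
#' so PPO ratios stay well defined.
#'
#' @param policy A [MutationPolicy-class].
#' @param scorer A [RewardScorer-class].
#' @param pseudo Named character vector allele -> pseudo sequence.
#' @param cfg A [ppoConfig()].
#' @param envCfg An [EnvConfig-class].
#' @param expert Optional [ExpertPolicy-class].
#' @param expertFraction Fraction of episodes driven by the expert.
#' @param length Peptide length: integer in 8..15 or `"sample"`.
#' @param nSteps Transition target (defaults to `cfg$N`).
#' @return List of trajectory records; each has `allele`, `X` (T x l
#'   integer state matrix, pre-mutation), `positions`, `residues`,
#'   `logProbs`, `values`, `rewards`, `advantages`, `returns`,
#'   `terminalScore`, `expert`.
#' @export
collectRollouts <- function(policy, scorer, pseudo, cfg = ppoConfig(),
                            envCfg = envConfig(), expert = NULL,
                            expertFraction = 0, length = 9L,
                            nSteps = cfg$N) {
  alleles <- names(pseudo)
  pseudoIdxList <- lapply(pseudo, aaIndex, split = TRUE)
  profCache <- list()
  getProfile <- function(ai, l) {
    key <- paste0(ai, ":", l)
    if (is.null(profCache[[key]])) {
      profCache[[key]] <<- expertProfile(expert, alleles[ai], l,
                                         pseudo[[ai]])
    }
    profCache[[key]]
  }
  trajs <- list(); collected <- 0L
  while (collected < nSteps) {
    B <- cfg$batchEnvs
    epLen <- if (identical(length, "sample")) sample(8:15, B, TRUE)
             else rep(as.integer(length), B)
    epAllele <- sample.int(base::length(alleles), B, replace = TRUE)
    epExpert <- if (is.null(expert) || expertFraction <= 0)
      rep(FALSE, B) else stats::runif(B) < expertFraction
    envs <- lapply(seq_len(B), function(b) list(
      x = sample.int(20L, epLen[b], replace = TRUE),
      allele = epAllele[b], expert = epExpert[b],
      Xrows = list(), pos = integer(0), res = integer(0),
      logp = numeric(0), val = numeric(0), score = NA_real_))
    active <- seq_len(B)
    step <- 0L
    while (base::length(active) > 0L && step < envCfg@maxSteps) {
      step <- step + 1L
      for (l in unique(vapply(envs[active], function(e)
        base::length(e$x), 0L))) {
        sel <- active[vapply(envs[active], function(e)
          base::length(e$x) == l, TRUE)]
        X <- do.call(rbind, lapply(envs[sel], function(e) e$x))
        ai <- vapply(envs[sel], function(e) e$allele, 0L)
        ef <- vapply(envs[sel], function(e) e$expert, TRUE)
        profs <- NULL
        if (any(ef)) {
          profs <- vector("list", base::length(alleles))
          for (a in unique(ai[ef])) profs[[a]] <- getProfile(a, l)
        }
        act <- .actBatch(policy, X, ai, pseudoIdxList, ef, profs)
        Xnew <- X
        Xnew[cbind(seq_along(sel), act$pos)] <- act$res
        # score mutated peptides per allele
        scores <- numeric(base::length(sel))
        for (a in unique(ai)) {
          rows <- which(ai == a)
          peps <- matrixToPeptides(Xnew[rows, , drop = FALSE])
          scores[rows] <- presentationScores(scorer, peps, alleles[a])
        }
        for (k in seq_along(sel)) {
          b <- sel[k]
          e <- envs[[b]]
          e$Xrows[[base::length(e$Xrows) + 1L]] <- X[k, ]
          e$pos <- c(e$pos, act$pos[k]); e$res <- c(e$res, act$res[k])
          e$logp <- c(e$logp, act$logp[k]); e$val <- c(e$val, act$value[k])
          e$x <- Xnew[k, ]; e$score <- scores[k]
          envs[[b]] <- e
        }
        done <- scores > envCfg@sigma | step >= envCfg@maxSteps
        active <- setdiff(active, sel[done])
      }
    }
    for (e in envs) {
      T <- base::length(e$pos)
      rewards <- c(rep(0, T - 1L), e$score)
      adv <- gaeAdvantages(rewards, e$val, cfg$gamma, cfg$lam)
      trajs[[base::length(trajs) + 1L]] <- list(
        allele = alleles[e$allele], alleleIdx = e$allele,
        X = do.call(rbind, e$Xrows), positions = e$pos, residues = e$res,
        logProbs = e$logp, values = e$val, rewards = rewards,
        advantages = adv, returns = rewardsToGo(rewards, cfg$gamma),
        terminalScore = e$score, expert = e$expert)
      collected <- collected + T
    }
  }
  attr(trajs, "pseudoIdxList") <- pseudoIdxList
  trajs
}

# cross-entropy gradient helpers: d(-log p_target)/d logits = p - onehot
.ceGrads <- function(probs, targets, coef) {
  g <- probs * coef
  g[cbind(seq_along(targets), targets)] <-
    g[cbind(seq_along(targets), targets)] - coef
  g
}

# entropy gradient: dH/dz = -p * (log p + H); returns d(-H)/dz * coef
.entGrads <- function(probs, coef) {
  lp <- ifelse(probs > 0, log(probs), 0)
  Hrow <- -rowSums(probs * lp)
  (probs * (lp + Hrow)) * coef
}

# one gradient accumulation over a same-length group of transitions
.ppoGroupGrads <- function(policy, X, alleleIdx, pseudoIdxList, pos, res,
                           oldLp, adv, ret, cfg, nMB) {
  cache <- .policyForwardA(policy, X, alleleIdx, pseudoIdxList)
  fb <- .policyForwardB(policy, cache, pos)
  B <- nrow(X)
  ii <- cbind(seq_len(B), pos)
  jj <- cbind(seq_len(B), res)
  lpNew <- log(cache$posProbs[ii]) + log(pmax(fb$resProbs[jj], 1e-300))
  phi <- exp(lpNew - oldLp)
  if (any(!is.finite(phi)))
    stop("non-finite probability ratio at transition ",
         which(!is.finite(phi))[1L])
  clipped <- pmin(pmax(phi, 1 - cfg$epsClip), 1 + cfg$epsClip)
  unclippedMin <- (phi * adv) <= (clipped * adv)
  # d(-L_CLIP)/d lpNew
  coefLp <- -(phi * adv) * unclippedMin / nMB
  dPos <- -.ceGrads(cache$posProbs, pos, coefLp)
  dRes <- -.ceGrads(fb$resProbs, res, coefLp)
  # entropy bonus: loss includes -alpha3 * H
  dPos <- dPos + .entGrads(cache$posProbs, cfg$alpha3 / nMB)
  dRes <- dRes + .entGrads(fb$resProbs, cfg$alpha3 / nMB)
  dRes[cbind(seq_len(B), fb$current)] <- 0
  dVal <- 2 * cfg$alpha1 * (cache$value - ret) / nMB
  grads <- .policyBackward(policy, cache, fb, dPos, dRes, dVal)
  ent <- -rowSums(ifelse(cache$posProbs > 0,
                         cache$posProbs * log(cache$posProbs), 0)) -
    rowSums(ifelse(fb$resProbs > 0, fb$resProbs * log(fb$resProbs), 0))
  list(grads = grads,
       surr = sum(pmin(phi * adv, clipped * adv)),
       vloss = sum((cache$value - ret)^2),
       ent = sum(ent))
}

# cross-entropy grads for imitation (pretraining / buffer batches)
.imitationGroupGrads <- function(policy, X, alleleIdx, pseudoIdxList,
                                 pos, res, coef) {
  cache <- .policyForwardA(policy, X, alleleIdx, pseudoIdxList)
  fb <- .policyForwardB(policy, cache, pos)
  B <- nrow(X)
  dPos <- .ceGrads(cache$posProbs, pos, coef)
  dRes <- .ceGrads(fb$resProbs, res, coef)
  dRes[cbind(seq_len(B), fb$current)] <- 0
  grads <- .policyBackward(policy, cache, fb, dPos, dRes, numeric(B))
  ce <- -log(pmax(cache$posProbs[cbind(seq_len(B), pos)], 1e-300)) -
    log(pmax(fb$resProbs[cbind(seq_len(B), res)], 1e-300))
  list(grads = grads, ce = sum(ce))
}

#' Pretrain the policy on the expert by behavior cloning
#'
#' Samples uniform-random states over the training alleles, queries the
#' expert for its action in each, and minimizes the position + residue
#' cross-entropy (standard negative log-likelihood) against those actions
#' with Adam. With `epochs = 0` the policy is returned unchanged.
#'
#' @param policy A [MutationPolicy-class].
#' @param expert An [ExpertPolicy-class].
#' @param pseudo Named character vector of training alleles.
#' @param nStates States in the cloning dataset.
#' @param epochs Full passes over the dataset.
#' @param minibatch Minibatch size.
#' @param lr Adam learning rate.
#' @param length Peptide length (integer or `"sample"`).
#' @return List with `policy` (updated) and `losses` (mean cross-entropy
#'   per epoch).
#' @export
pretrainPolicy <- function(policy, expert, pseudo, nStates = 4096L,
                           epochs = 20L, minibatch = 256L, lr = 2e-3,
                           length = 9L) {
  if (epochs == 0L) return(list(policy = policy, losses = numeric(0)))
  alleles <- names(pseudo)
  pseudoIdxList <- lapply(pseudo, aaIndex, split = TRUE)
  lens <- if (identical(length, "sample")) sample(8:15, nStates, TRUE)
          else rep(as.integer(length), nStates)
  ai <- sample.int(base::length(alleles), nStates, replace = TRUE)
  states <- vector("list", nStates)
  for (s in seq_len(nStates)) {
    x <- sample.int(20L, lens[s], replace = TRUE)
    prof <- expertProfile(expert, alleles[ai[s]], lens[s],
                          pseudo[[ai[s]]])
    gaps <- apply(prof, 2L, max) - prof[cbind(x, seq_along(x))]
    pos <- which.max(gaps)
    pr <- prof[, pos]; pr[x[pos]] <- 0
    res <- sample.int(20L, 1L, prob = pr)
    states[[s]] <- list(x = x, ai = ai[s], pos = pos, res = res,
                        l = lens[s])
  }
  opt <- .adamInit(policy@params)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nStates)
    total <- 0
    for (mb in split(ord, ceiling(seq_along(ord) / minibatch))) {
      grads <- .zeroLike(policy@params)
      nMB <- base::length(mb)
      for (l in unique(vapply(states[mb], `[[`, 0L, "l"))) {
        sel <- mb[vapply(states[mb], function(s) s$l == l, TRUE)]
        X <- do.call(rbind, lapply(states[sel], `[[`, "x"))
        gg <- .imitationGroupGrads(
          policy, X, vapply(states[sel], `[[`, 0L, "ai"),
          pseudoIdxList, vapply(states[sel], `[[`, 0L, "pos"),
          vapply(states[sel], `[[`, 0L, "res"), 1 / nMB)
        grads <- .addGrads(grads, gg$grads)
        total <- total + gg$ce
      }
      st <- .adamStep(policy@params, grads, opt, lr = lr)
      policy@params <- st$params; opt <- st$state
    }
    losses[ep] <- total / nStates
  }
  list(policy = policy, losses = losses)
}

#' Buffer imitation cross-entropy
#'
#' `L_B` = mean over the batch of `-log pi_c(i|s) - log pi_d(o'|s)`; an
#' empty batch contributes 0.
#'
#' @param policy A [MutationPolicy-class].
#' @param batch List of buffer entries (see [bufferSample()]).
#' @param pseudo Named character vector of pseudo sequences.
#' @return Scalar loss.
#' @export
bufferCELoss <- function(policy, batch, pseudo) {
  if (base::length(batch) == 0L) return(0)
  alleles <- names(pseudo)
  pseudoIdxList <- lapply(pseudo, aaIndex, split = TRUE)
  total <- 0
  lens <- vapply(batch, function(e) nchar(e$peptide), 0L)
  for (l in unique(lens)) {
    sel <- which(lens == l)
    X <- peptideMatrix(vapply(batch[sel], `[[`, "", "peptide"))
    ai <- match(vapply(batch[sel], `[[`, "", "allele"), alleles)
    pos <- vapply(batch[sel], `[[`, 0L, "position")
    res <- vapply(batch[sel], `[[`, 0L, "residue")
    cache <- .policyForwardA(policy, X, ai, pseudoIdxList)
    fb <- .policyForwardB(policy, cache, pos)
    B <- nrow(X)
    total <- total +
      sum(-log(pmax(cache$posProbs[cbind(seq_len(B), pos)], 1e-300)) -
          log(pmax(fb$resProbs[cbind(seq_len(B), res)], 1e-300)))
  }
  total / base::length(batch)
}

#' Train a mutation policy with PPO
#'
#' Runs iterations of rollout collection, advantage estimation and `K`
#' epochs of minibatch updates on the combined objective (clipped
#' surrogate, value loss, optional buffer imitation loss, entropy bonus).
#' Expert-driven episodes are mixed in early per the schedule in `cfg`.
#'
#' @param scorer A [RewardScorer-class] providing rewards.
#' @param pseudo Named character vector allele -> pseudo sequence (the
#'   training alleles).
#' @param cfg A [ppoConfig()].
#' @param envCfg An [EnvConfig-class].
#' @param policy Starting [MutationPolicy-class] (e.g. pretrained); a fresh
#'   one is initialized when `NULL`.
#' @param encCfg Encoding configuration for a fresh policy.
#' @param hidden,headWidth,valueHidden Sizes for a fresh policy.
#' @param expert Optional [ExpertPolicy-class] for mixed rollouts.
#' @param buffer Optional [ExperienceBuffer-class]; when supplied,
#'   qualified trajectories feed it and the imitation loss is active.
#' @param length Peptide length for episodes (integer or `"sample"`).
#' @param verbose Print per-iteration metrics.
#' @return List with `policy`, `metrics` (one row per iteration:
#'   iteration, meanTerminalScore, qualifiedFraction, meanEpisodeLength,
#'   surrogate, valueLoss, bufferCE, entropy) and `buffer`.
#' @export
trainPepPPO <- function(scorer, pseudo, cfg = ppoConfig(),
                        envCfg = envConfig(), policy = NULL,
                        encCfg = encodingConfig(), hidden = 64L,
                        headWidth = 64L, valueHidden = 64L,
                        expert = NULL, buffer = NULL, length = 9L,
                        verbose = FALSE) {
  if (is.null(policy))
    policy <- initPolicy(encCfg, hidden, headWidth, valueHidden)
  pseudoIdxList <- lapply(pseudo, aaIndex, split = TRUE)
  opt <- .adamInit(policy@params)
  metrics <- vector("list", cfg$iterations)
  decayIters <- max(1L, round(cfg$expertDecayFrac * cfg$iterations))
  for (iter in seq_len(cfg$iterations)) {
    ef <- if (is.null(expert)) 0 else
      max(0, cfg$expertFractionInit * (1 - (iter - 1) / decayIters))
    trajs <- collectRollouts(policy, scorer, pseudo, cfg, envCfg,
                             expert = expert, expertFraction = ef,
                             length = length)
    if (!is.null(buffer)) {
      for (tr in trajs) {
        bufferAddTrajectory(buffer, list(
          peptides = matrixToPeptides(tr$X), allele = tr$allele,
          positions = tr$positions, residues = tr$residues,
          terminalScore = tr$terminalScore), threshold = envCfg@sigma)
      }
    }
    # flatten transitions
    trans <- list()
    for (tr in trajs) {
      for (t in seq_along(tr$positions)) {
        trans[[base::length(trans) + 1L]] <- list(
          x = tr$X[t, ], l = ncol(tr$X), ai = tr$alleleIdx,
          pos = tr$positions[t], res = tr$residues[t],
          oldLp = tr$logProbs[t], adv = tr$advantages[t],
          ret = tr$returns[t])
      }
    }
    nT <- base::length(trans)
    if (cfg$normalizeAdvantages) {
      a <- vapply(trans, `[[`, 0, "adv")
      s <- stats::sd(a); if (!is.finite(s) || s < 1e-8) s <- 1
      m <- mean(a)
      for (i in seq_len(nT)) trans[[i]]$adv <- (trans[[i]]$adv - m) / s
    }
    sumSurr <- sumV <- sumEnt <- sumB <- 0; nLoss <- 0; nBLoss <- 0
    for (ep in seq_len(cfg$K)) {
      ord <- sample.int(nT)
      for (mb in split(ord, ceiling(seq_along(ord) / cfg$minibatch))) {
        nMB <- base::length(mb)
        grads <- .zeroLike(policy@params)
        for (l in unique(vapply(trans[mb], `[[`, 0L, "l"))) {
          sel <- mb[vapply(trans[mb], function(s) s$l == l, TRUE)]
          gg <- .ppoGroupGrads(
            policy, do.call(rbind, lapply(trans[sel], `[[`, "x")),
            vapply(trans[sel], `[[`, 0L, "ai"), pseudoIdxList,
            vapply(trans[sel], `[[`, 0L, "pos"),
            vapply(trans[sel], `[[`, 0L, "res"),
            vapply(trans[sel], `[[`, 0, "oldLp"),
            vapply(trans[sel], `[[`, 0, "adv"),
            vapply(trans[sel], `[[`, 0, "ret"), cfg, nMB)
          grads <- .addGrads(grads, gg$grads)
          sumSurr <- sumSurr + gg$surr; sumV <- sumV + gg$vloss
          sumEnt <- sumEnt + gg$ent
        }
        nLoss <- nLoss + nMB
        if (!is.null(buffer) && cfg$alpha2 > 0 && bufferSize(buffer) > 0) {
          batch <- bufferSample(buffer, min(cfg$minibatch,
                                            bufferSize(buffer)))
          lensB <- vapply(batch, function(e) nchar(e$peptide), 0L)
          nB <- base::length(batch)
          for (l in unique(lensB)) {
            sel <- which(lensB == l)
            gg <- .imitationGroupGrads(
              policy, peptideMatrix(vapply(batch[sel], `[[`, "",
                                           "peptide")),
              match(vapply(batch[sel], `[[`, "", "allele"),
                    names(pseudo)),
              pseudoIdxList, vapply(batch[sel], `[[`, 0L, "position"),
              vapply(batch[sel], `[[`, 0L, "residue"),
              cfg$alpha2 / nB)
            grads <- .addGrads(grads, gg$grads)
            sumB <- sumB + gg$ce
          }
          nBLoss <- nBLoss + nB
        }
        st <- .adamStep(policy@params, grads, opt, lr = cfg$lr)
        policy@params <- st$params; opt <- st$state
      }
    }
    scores <- vapply(trajs, `[[`, 0, "terminalScore")
    lens <- vapply(trajs, function(tr) base::length(tr$positions), 0L)
    loss <- combinedLoss(sumSurr / nLoss, sumV / nLoss,
                         if (nBLoss) sumB / nBLoss else 0,
                         sumEnt / nLoss, cfg)
    if (!is.finite(loss))
      stop("NaN/Inf loss at iteration ", iter,
           " (mean terminal score ", round(mean(scores), 3), ")")
    metrics[[iter]] <- data.frame(
      iteration = iter, meanTerminalScore = mean(scores),
      qualifiedFraction = mean(scores > envCfg@sigma),
      meanEpisodeLength = mean(lens),
      surrogate = sumSurr / nLoss, valueLoss = sumV / nLoss,
      bufferCE = if (nBLoss) sumB / nBLoss else NA_real_,
      entropy = sumEnt / nLoss, expertFraction = ef)
    if (verbose)
      message(sprintf(
        "iter %3d | score %.3f | qualified %.2f | eplen %.2f | H %.2f",
        iter, mean(scores), mean(scores > envCfg@sigma), mean(lens),
        sumEnt / nLoss))
  }
  list(policy = policy, metrics = do.call(rbind, metrics),
       buffer = buffer)
}
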