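# Shared fixtures, memoized so expensive objects are built once per session.

.world_cache <- new.env(parent = emptyenv())

# The standard synthetic world: 3-allele hidden-motif oracle (9-mers,
# 4 anchors, kappa = 0.9) with a binding dataset and expert policy.
stdWorld <- function() {
  if (is.null(.world_cache$world)) {
    oracle <- makeHiddenOracle(nAlleles = 3L, lengths = 9L, nAnchors = 4L,
                               kappa = 0.9, seed = 7L)
    pseudo <- oraclePseudoSequences(oracle)
    binding <- synthBindingDataset(oracle, nPerAllele = 200L, seed = 7L)
    expert <- buildExpertPolicy(binding, pseudo, minCount = 50L)
    .world_cache$world <- list(oracle = oracle, pseudo = pseudo,
                               binding = binding, expert = expert)
  }
  .world_cache$world
}

# A tiny untrained policy for shape/contract tests (cheap to forward).
tinyPolicy <- function() {
  if (is.null(.world_cache$tiny)) {
    set.seed(11)
    .world_cache$tiny <- initPolicy(encodingConfig(TRUE, TRUE, 4L, 0.1),
                                    hidden = 6L, headWidth = 6L,
                                    valueHidden = 5L)
  }
  .world_cache$tiny
}

# Full end-to-end training run used by the acceptance criteria: behavior
# cloning on the expert followed by PPO at the acceptance scale (N = 1024,
# 30 iterations). Memoized per seed; elapsed wall time is recorded.
accTraining <- function(seed) {
  key <- paste0("fit", seed)
  if (is.null(.world_cache[[key]])) {
    w <- stdWorld()
    t0 <- Sys.time()
    set.seed(seed)
    policy <- initPolicy(encodingConfig(), hidden = 64L, headWidth = 64L,
                         valueHidden = 64L)
    pre <- pretrainPolicy(policy, w$expert, w$pseudo, length = 9L)
    fit <- trainPepPPO(
      w$oracle, w$pseudo,
      cfg = ppoConfig(N = 1024L, iterations = 30L, minibatch = 256L,
                      batchEnvs = 128L, lr = 3e-4,
                      expertFractionInit = 0.3, expertDecayFrac = 0.5),
      policy = pre$policy, expert = w$expert, buffer = experienceBuffer(),
      length = 9L)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .world_cache[[key]] <- list(policy = fit$policy, metrics = fit$metrics,
                                elapsed = elapsed,
                                pretrainLosses = pre$losses)
  }
  .world_cache[[key]]
}

# Generated repertoire (1000 peptides) for one allele from a trained run.
accGeneration <- function(seed, allele) {
  key <- paste0("gen", seed, allele)
  if (is.null(.world_cache[[key]])) {
    w <- stdWorld()
    fit <- accTraining(seed)
    set.seed(seed + 1L)
    .world_cache[[key]] <- generatePeptides(fit$policy, w$oracle, allele,
                                            w$pseudo[[allele]], n = 1000L,
                                            length = 9L)
  }
  .world_cache[[key]]
}

# random probability vector (rows) helper
randomSimplex <- function(n, k = 20L) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
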