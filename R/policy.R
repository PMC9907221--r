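#' Mutation policy network
#'
#' The policy scores mutations of a peptide in the context of an MHC
#' allele. Residues are encoded per [EncodingConfig-class]; the peptide is
#' embedded with a one-layer bidirectional LSTM (per-residue vectors are
#' the concatenation of the two directions' hidden states, the peptide
#' vector concatenates the two end hidden states); the MHC pseudo sequence
#' is embedded by a two-layer perceptron on the flattened (residue-major)
#' encoding matrix. A position head turns each per-residue vector plus the
#' MHC vector into a replacement score (softmax over positions), and a
#' residue head produces a 20-way distribution at the chosen position with
#' the current residue masked out and renormalized. A separate value head
#' maps the MHC and peptide vectors to a state-value estimate for PPO.
#'
#' All parameters live in the `params` list; the LSTM boundary vectors are
#' drawn once at initialization and then held as frozen constants (the
#' `boundary` slot), so the policy is a deterministic function of the
#' state. Gradients are computed analytically by [policyBackward()].
#'
#' @slot params Named list of weight matrices/vectors.
#' @slot boundary Frozen LSTM boundary vectors (h/c, both directions).
#' @slot cfg The [EncodingConfig-class] used for residue encoding.
#' @slot hidden LSTM hidden width H (each per-residue vector has width 2H).
#' @slot headWidth Hidden width of the position/residue heads.
#' @slot valueHidden Hidden width of the value head.
#' @export
setClass("MutationPolicy",
  representation(params = "list", boundary = "list", cfg = "EncodingConfig",
                 hidden = "integer", headWidth = "integer",
                 valueHidden = "integer"))

setMethod("show", "MutationPolicy", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat("MutationPolicy: d =", encodingWidth(object@cfg),
      "| H =", object@hidden, "| head =", object@headWidth,
      "|", format(np, big.mark = ","), "parameters\n")
})

.gauss <- function(nr, nc, fanIn) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fanIn)), nr, nc)
}

#' Initialize a mutation policy
#'
#' Weights are Gaussian with 1/sqrt(fan-in) scale; LSTM forget-gate biases
#' start at 1 (standard recurrent-network practice). Reproducible under
#' `set.seed()`.
#'
#' @param cfg An [EncodingConfig-class].
#' @param hidden LSTM hidden width H.
#' @param headWidth Position/residue head hidden width.
#' @param valueHidden Value head hidden width.
#' @return A [MutationPolicy-class].
#' @export
initPolicy <- function(cfg = encodingConfig(), hidden = 64L,
                       headWidth = 64L, valueHidden = 64L) {
  H <- as.integer(hidden); C <- as.integer(headWidth)
  Hv <- as.integer(valueHidden)
  d <- encodingWidth(cfg)
  M <- 34L * d
  lstmInit <- function() {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget gate
    list(Wx = .gauss(d, 4L * H, d), Wh = .gauss(H, 4L * H, H), b = b)
  }
  params <- list(
    emb = if (cfg@learnedDim > 0L)
      .gauss(20L, cfg@learnedDim, cfg@learnedDim) else NULL,
    fWx = NULL, fWh = NULL, fb = NULL,
    bWx = NULL, bWh = NULL, bb = NULL,
    W2m = .gauss(2L * H, M, M), b2m = numeric(2L * H),
    W1m = .gauss(2L * H, 2L * H, 2L * H), b1m = numeric(2L * H),
    W1c = .gauss(C, 2L * H, 2L * H), W2c = .gauss(C, 2L * H, 2L * H),
    bc = numeric(C), wc = .gauss(C, 1L, C)[, 1L],
    W2d = .gauss(C, 2L * H, 2L * H), W3d = .gauss(C, 2L * H, 2L * H),
    bd = numeric(C), W1d = .gauss(20L, C, C), b1d = numeric(20L),
    Wv1 = .gauss(Hv, 4L * H, 4L * H), bv1 = numeric(Hv),
    wv2 = .gauss(Hv, 1L, Hv)[, 1L], bv2 = 0)
  f <- lstmInit(); b <- lstmInit()
  params$fWx <- f$Wx; params$fWh <- f$Wh; params$fb <- f$b
  params$bWx <- b$Wx; params$bWh <- b$Wh; params$bb <- b$b
  boundary <- list(h0f = stats::rnorm(H, sd = 0.1),
                   c0f = stats::rnorm(H, sd = 0.1),
                   h0b = stats::rnorm(H, sd = 0.1),
                   c0b = stats::rnorm(H, sd = 0.1))
  new("MutationPolicy", params = params, boundary = boundary, cfg = cfg,
      hidden = H, headWidth = C, valueHidden = Hv)
}

.relu <- function(x) x * (x > 0)
.sigm <- function(x) 1 / (1 + exp(-x))

# row-wise softmax with -Inf support
.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e[is.na(e)] <- 0  # exp(-Inf - -Inf) guards
  e / rowSums(e)
}

# one batched LSTM sweep; returns hidden/cell/gate caches per time step
.lstmSweep <- function(Ex, Wx, Wh, b, h0, c0) {
  l <- length(Ex); B <- nrow(Ex[[1L]]); H <- length(h0)
  Hs <- Cs <- Gs <- vector("list", l)
  h <- matrix(h0, B, H, byrow = TRUE)
  cc <- matrix(c0, B, H, byrow = TRUE)
  for (t in seq_len(l)) {
    G <- Ex[[t]] %*% Wx + h %*% Wh + matrix(b, B, 4L * H, byrow = TRUE)
    i <- .sigm(G[, 1:H, drop = FALSE])
    f <- .sigm(G[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(G[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- .sigm(G[, (3L * H + 1L):(4L * H), drop = FALSE])
    cNew <- f * cc + i * g
    hNew <- o * tanh(cNew)
    Gs[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = cc)
    Hs[[t]] <- hNew; Cs[[t]] <- cNew
    h <- hNew; cc <- cNew
  }
  list(H = Hs, C = Cs, G = Gs)
}

# Stage A of the batched forward: embeddings, position logits, value.
# X: B x l integer matrix; alleleIdx: B integers into pseudoIdxList;
# pseudoIdxList: list of length-34 integer vectors.
.policyForwardA <- function(policy, X, alleleIdx, pseudoIdxList) {
  p <- policy@params; H <- policy@hidden
  B <- nrow(X); l <- ncol(X)
  CB <- encodingCodebook(policy@cfg, p$emb)
  d <- ncol(CB)
  Ex <- lapply(seq_len(l), function(t) CB[X[, t], , drop = FALSE])
  fw <- .lstmSweep(Ex, p$fWx, p$fWh, p$fb,
                   policy@boundary$h0f, policy@boundary$c0f)
  bwEx <- rev(Ex)
  bw <- .lstmSweep(bwEx, p$bWx, p$bWh, p$bb,
                   policy@boundary$h0b, policy@boundary$c0b)
  # bw$H[[k]] corresponds to sequence position l - k + 1
  Hb <- rev(bw$H)
  hcat <- lapply(seq_len(l), function(t) cbind(fw$H[[t]], Hb[[t]]))
  hp <- cbind(fw$H[[l]], Hb[[1L]])
  # MHC embeddings per unique allele
  ua <- sort(unique(alleleIdx))
  mhcCache <- list()
  hmU <- matrix(0, length(ua), 2L * H)
  for (k in seq_along(ua)) {
    em <- CB[pseudoIdxList[[ua[k]]], , drop = FALSE]   # 34 x d
    mvec <- as.vector(t(em))                           # residue-major
    z2 <- drop(p$W2m %*% mvec) + p$b2m
    r2 <- .relu(z2)
    hmU[k, ] <- drop(p$W1m %*% r2) + p$b1m
    mhcCache[[k]] <- list(mvec = mvec, z2 = z2, r2 = r2)
  }
  rowOf <- match(alleleIdx, ua)
  hm <- hmU[rowOf, , drop = FALSE]
  # position head
  hmW2c <- hm %*% t(p$W2c)
  A1 <- vector("list", l)
  posLogits <- matrix(0, B, l)
  for (t in seq_len(l)) {
    A1[[t]] <- hcat[[t]] %*% t(p$W1c) + hmW2c +
      matrix(p$bc, B, policy@headWidth, byrow = TRUE)
    posLogits[, t] <- .relu(A1[[t]]) %*% p$wc
  }
  posProbs <- .softmaxRows(posLogits)
  # value head
  vin <- cbind(hm, hp)
  aV <- vin %*% t(p$Wv1) + matrix(p$bv1, B, policy@valueHidden, byrow = TRUE)
  rV <- .relu(aV)
  value <- drop(rV %*% p$wv2) + p$bv2
  list(X = X, Ex = Ex, fw = fw, bw = bw, Hb = Hb, hcat = hcat, hp = hp,
       ua = ua, rowOf = rowOf, mhcCache = mhcCache, hm = hm, A1 = A1,
       posLogits = posLogits, posProbs = posProbs,
       vin = vin, aV = aV, rV = rV, value = value, CB = CB, d = d,
       pseudoIdxList = pseudoIdxList, alleleIdx = alleleIdx)
}

# Stage B: residue logits at one chosen position per sample, with the
# current residue masked to -Inf before the softmax.
.policyForwardB <- function(policy, cache, positions) {
  p <- policy@params
  B <- nrow(cache$X); H <- policy@hidden
  hsel <- matrix(0, B, 2L * H)
  for (t in unique(positions)) {
    sel <- positions == t
    hsel[sel, ] <- cache$hcat[[t]][sel, , drop = FALSE]
  }
  A2 <- hsel %*% t(p$W2d) + cache$hm %*% t(p$W3d) +
    matrix(p$bd, B, policy@headWidth, byrow = TRUE)
  R2 <- .relu(A2)
  resLogits <- R2 %*% t(p$W1d) + matrix(p$b1d, B, 20L, byrow = TRUE)
  current <- cache$X[cbind(seq_len(B), positions)]
  resLogits[cbind(seq_len(B), current)] <- -Inf
  resProbs <- .softmaxRows(resLogits)
  list(positions = positions, hsel = hsel, A2 = A2, R2 = R2,
       resLogits = resLogits, resProbs = resProbs, current = current)
}

#' Embed a state
#'
#' Returns the per-residue vectors, the peptide vector and the MHC vector
#' for a single state, mirroring the internal batched computation.
#'
#' @param policy A [MutationPolicy-class].
#' @param state An [EnvState-class].
#' @return List with `h` (l x 2H matrix), `hp` (2H), `hm` (2H).
#' @export
embedState <- function(policy, state) {
  X <- peptideMatrix(state@peptide)
  cache <- .policyForwardA(policy, X, 1L,
                           list(aaIndex(state@pseudo, split = TRUE)))
  h <- do.call(rbind, lapply(cache$hcat, function(m) m[1L, ]))
  list(h = h, hp = cache$hp[1L, ], hm = cache$hm[1L, ])
}

#' Action distributions for a single state
#'
#' @param policy A [MutationPolicy-class].
#' @param state An [EnvState-class].
#' @param position Optional fixed position; when `NULL` the residue
#'   distribution is reported for the most probable position.
#' @return List with `positionProbs` (length l, sums to 1),
#'   `residueProbs` (length 20, current residue exactly 0, rest sums to 1),
#'   `value`.
#' @export
actionDistributions <- function(policy, state, position = NULL) {
  X <- peptideMatrix(state@peptide)
  cache <- .policyForwardA(policy, X, 1L,
                           list(aaIndex(state@pseudo, split = TRUE)))
  if (is.null(position)) position <- which.max(cache$posProbs[1L, ])
  fb <- .policyForwardB(policy, cache, position)
  list(positionProbs = cache$posProbs[1L, ],
       residueProbs = fb$resProbs[1L, ],
       value = cache$value[1L])
}

#' Sample one mutation action from the policy
#'
#' Samples the position from the position distribution, then the residue
#' from the masked residue distribution at that position; the joint log
#' probability is the sum of the two log probabilities. The sampled residue
#' never equals the current one.
#'
#' @param policy A [MutationPolicy-class].
#' @param state An [EnvState-class].
#' @return List with `position`, `residue` (one-letter code), `logProb`,
#'   `value`.
#' @export
sampleAction <- function(policy, state) {
  X <- peptideMatrix(state@peptide)
  cache <- .policyForwardA(policy, X, 1L,
                           list(aaIndex(state@pseudo, split = TRUE)))
  pos <- sample.int(ncol(X), 1L, prob = cache$posProbs[1L, ])
  fb <- .policyForwardB(policy, cache, pos)
  res <- sample.int(20L, 1L, prob = fb$resProbs[1L, ])
  list(position = pos, residue = AA_ALPHABET[res],
       logProb = log(cache$posProbs[1L, pos]) + log(fb$resProbs[1L, res]),
       value = cache$value[1L])
}

#' Evaluate actions under the current policy
#'
#' Re-computes log probabilities, entropies and values for previously taken
#' actions; re-evaluating a just-sampled action reproduces its stored log
#' probability. The entropy is the position-distribution entropy plus the
#' masked residue-distribution entropy at the taken position.
#'
#' @param policy A [MutationPolicy-class].
#' @param states List of [EnvState-class] objects (all peptides of one
#'   length).
#' @param positions,residues Integer vectors: 1-based positions and
#'   alphabet indices of the taken actions.
#' @return List with `logProbs`, `entropies`, `values`.
#' @export
evaluateActions <- function(policy, states, positions, residues) {
  peptides <- vapply(states, function(s) s@peptide, "")
  pseudos <- vapply(states, function(s) s@pseudo, "")
  up <- unique(pseudos)
  X <- peptideMatrix(peptides)
  cur <- X[cbind(seq_len(nrow(X)), positions)]
  if (any(cur == residues))
    stop("action proposes the residue already present at its position")
  cache <- .policyForwardA(policy, X, match(pseudos, up),
                           lapply(up, aaIndex, split = TRUE))
  fb <- .policyForwardB(policy, cache, positions)
  B <- nrow(X)
  lp <- log(cache$posProbs[cbind(seq_len(B), positions)]) +
    log(fb$resProbs[cbind(seq_len(B), residues)])
  entPos <- -rowSums(ifelse(cache$posProbs > 0,
                            cache$posProbs * log(cache$posProbs), 0))
  entRes <- -rowSums(ifelse(fb$resProbs > 0,
                            fb$resProbs * log(fb$resProbs), 0))
  list(logProbs = lp, entropies = entPos + entRes, values = cache$value)
}

#' Save / load a policy checkpoint
#'
#' The checkpoint holds all parameters, the frozen boundary vectors, the
#' encoding configuration, the canonical alphabet order and the flattening
#' convention, so it fully determines generation behavior given a seed.
#'
#' @param policy A [MutationPolicy-class].
#' @param path File path.
#' @export
saveCheckpoint <- function(policy, path) {
  saveRDS(list(format = "PepPPO-checkpoint-1",
               params = policy@params, boundary = policy@boundary,
               cfg = list(useBlosum = policy@cfg@useBlosum,
                          useOnehot = policy@cfg@useOnehot,
                          learnedDim = policy@cfg@learnedDim,
                          blosumScale = policy@cfg@blosumScale),
               hidden = policy@hidden, headWidth = policy@headWidth,
               valueHidden = policy@valueHidden,
               alphabet = AA_ALPHABET, mhcFlatten = "residue-major"),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "PepPPO-checkpoint-1"))
    stop("not a PepPPO checkpoint: ", path)
  if (!identical(ck$alphabet, AA_ALPHABET))
    stop("checkpoint uses a different alphabet order")
  cfg <- encodingConfig(ck$cfg$useBlosum, ck$cfg$useOnehot,
                        ck$cfg$learnedDim, ck$cfg$blosumScale)
  new("MutationPolicy", params = ck$params, boundary = ck$boundary,
      cfg = cfg, hidden = ck$hidden, headWidth = ck$headWidth,
      valueHidden = ck$valueHidden)
}
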