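# Analytic reverse pass for the mutation policy.
#
# policyBackward() takes the caches of the two forward stages plus the
# gradients of a scalar loss with respect to the position logits (B x l),
# the residue logits at the chosen positions (B x 20, masked entries must
# be 0) and the value outputs (B), and returns gradients for every
# trainable parameter. The frozen LSTM boundary vectors receive no
# gradient by design. Correctness is pinned down by a finite-difference
# test over every parameter block.

.zeroLike <- function(params) {
  lapply(params, function(p) if (is.null(p)) NULL else p * 0)
}

.addGrads <- function(a, b, scale = 1) {
  for (nm in names(b))
    if (!is.null(b[[nm]])) a[[nm]] <- a[[nm]] + scale * b[[nm]]
  a
}

# backward through one LSTM sweep (in sweep order); dH is the list of
# gradients w.r.t. the sweep's hidden outputs, aligned with sweep indices
.lstmBackward <- function(sweep, Ex, Wx, Wh, dH, H) {
  l <- length(Ex); B <- nrow(Ex[[1L]])
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4L * H)
  dEx <- vector("list", l)
  dhCarry <- matrix(0, B, H); dcCarry <- matrix(0, B, H)
  for (t in rev(seq_len(l))) {
    g <- sweep$G[[t]]
    cNew <- sweep$C[[t]]
    tanhc <- tanh(cNew)
    dh <- dH[[t]] + dhCarry
    do <- dh * tanhc
    dc <- dcCarry + dh * g$o * (1 - tanhc^2)
    di <- dc * g$g
    dg <- dc * g$i
    df <- dc * g$cPrev
    dcCarry <- dc * g$f
    dG <- cbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do * g$o * (1 - g$o))
    dWx <- dWx + crossprod(Ex[[t]], dG)
    hPrev <- if (t > 1L) sweep$H[[t - 1L]] else
      matrix(sweep$h0, B, H, byrow = TRUE)
    dWh <- dWh + crossprod(hPrev, dG)
    db <- db + colSums(dG)
    dhCarry <- dG %*% t(Wh)
    dEx[[t]] <- dG %*% t(Wx)
  }
  list(dWx = dWx, dWh = dWh, db = db, dEx = dEx)
}

.policyBackward <- function(policy, cache, fb, dPosLogits, dResLogits,
                            dValue) {
  p <- policy@params
  H <- policy@hidden
  B <- nrow(cache$X); l <- ncol(cache$X)
  gr <- .zeroLike(p)
  lc <- learnedColumns(policy@cfg)
  dhm <- matrix(0, B, 2L * H)
  dhcat <- lapply(seq_len(l), function(t) matrix(0, B, 2L * H))

  # value head
  if (!all(dValue == 0)) {
    dV <- matrix(dValue, B, 1L)
    gr$wv2 <- gr$wv2 + drop(crossprod(cache$rV, dV))
    gr$bv2 <- gr$bv2 + sum(dValue)
    drV <- dV %*% t(matrix(p$wv2, ncol = 1L))  # B x Hv
    daV <- drV * (cache$aV > 0)
    gr$Wv1 <- gr$Wv1 + crossprod(daV, cache$vin)
    gr$bv1 <- gr$bv1 + colSums(daV)
    dvin <- daV %*% p$Wv1
    dhm <- dhm + dvin[, 1:(2L * H), drop = FALSE]
    dhp <- dvin[, (2L * H + 1L):(4L * H), drop = FALSE]
    dhcat[[l]][, 1:H] <- dhcat[[l]][, 1:H] + dhp[, 1:H, drop = FALSE]
    dhcat[[1L]][, (H + 1L):(2L * H)] <-
      dhcat[[1L]][, (H + 1L):(2L * H)] +
      dhp[, (H + 1L):(2L * H), drop = FALSE]
  }

  # residue head (at chosen positions)
  if (!is.null(fb) && !all(dResLogits == 0)) {
    gr$W1d <- gr$W1d + crossprod(dResLogits, fb$R2)
    gr$b1d <- gr$b1d + colSums(dResLogits)
    dR2 <- dResLogits %*% p$W1d
    dA2 <- dR2 * (fb$A2 > 0)
    gr$W2d <- gr$W2d + crossprod(dA2, fb$hsel)
    gr$W3d <- gr$W3d + crossprod(dA2, cache$hm)
    gr$bd <- gr$bd + colSums(dA2)
    dhm <- dhm + dA2 %*% p$W3d
    dhsel <- dA2 %*% p$W2d
    for (t in unique(fb$positions)) {
      sel <- fb$positions == t
      dhcat[[t]][sel, ] <- dhcat[[t]][sel, ] + dhsel[sel, , drop = FALSE]
    }
  }

  # position head
  if (!all(dPosLogits == 0)) {
    for (t in seq_len(l)) {
      ds <- dPosLogits[, t]
      if (all(ds == 0)) next
      R <- .relu(cache$A1[[t]])
      gr$wc <- gr$wc + drop(crossprod(R, ds))
      dR <- matrix(ds, B, 1L) %*% t(matrix(p$wc, ncol = 1L))
      dA1 <- dR * (cache$A1[[t]] > 0)
      gr$W1c <- gr$W1c + crossprod(dA1, cache$hcat[[t]])
      gr$W2c <- gr$W2c + crossprod(dA1, cache$hm)
      gr$bc <- gr$bc + colSums(dA1)
      dhcat[[t]] <- dhcat[[t]] + dA1 %*% p$W1c
      dhm <- dhm + dA1 %*% p$W2c
    }
  }

  # split per-residue gradients into the two LSTM directions
  dHf <- lapply(dhcat, function(m) m[, 1:H, drop = FALSE])
  dHbPos <- lapply(dhcat, function(m) m[, (H + 1L):(2L * H), drop = FALSE])

  cache$fw$h0 <- policy@boundary$h0f
  cache$bw$h0 <- policy@boundary$h0b
  fwB <- .lstmBackward(cache$fw, cache$Ex, p$fWx, p$fWh, dHf, H)
  bwB <- .lstmBackward(cache$bw, rev(cache$Ex), p$bWx, p$bWh,
                       rev(dHbPos), H)
  gr$fWx <- gr$fWx + fwB$dWx; gr$fWh <- gr$fWh + fwB$dWh
  gr$fb <- gr$fb + fwB$db
  gr$bWx <- gr$bWx + bwB$dWx; gr$bWh <- gr$bWh + bwB$dWh
  gr$bb <- gr$bb + bwB$db

  # accumulate learned-embedding gradients from the peptide encodings
  if (length(lc)) {
    for (t in seq_len(l)) {
      dEx <- fwB$dEx[[t]] + bwB$dEx[[l - t + 1L]]
      dLearn <- dEx[, lc, drop = FALSE]
      agg <- rowsum(dLearn, group = cache$X[, t])
      rows <- as.integer(rownames(agg))
      gr$emb[rows, ] <- gr$emb[rows, ] + agg
    }
  }

  # MHC encoder path: aggregate dhm per unique allele
  d <- cache$d
  for (k in seq_along(cache$ua)) {
    sel <- cache$rowOf == k
    if (!any(sel)) next
    dhmA <- colSums(dhm[sel, , drop = FALSE])
    mc <- cache$mhcCache[[k]]
    gr$W1m <- gr$W1m + dhmA %o% mc$r2
    gr$b1m <- gr$b1m + dhmA
    dr2 <- drop(crossprod(p$W1m, dhmA))
    da2 <- dr2 * (mc$z2 > 0)
    gr$W2m <- gr$W2m + da2 %o% mc$mvec
    gr$b2m <- gr$b2m + da2
    if (length(lc)) {
      dmvec <- drop(crossprod(p$W2m, da2))
      dEm <- t(matrix(dmvec, nrow = d))          # 34 x d, residue-major
      dLearn <- dEm[, lc, drop = FALSE]
      idx <- cache$pseudoIdxList[[cache$ua[k]]]
      agg <- rowsum(dLearn, group = idx)
      rows <- as.integer(rownames(agg))
      gr$emb[rows, ] <- gr$emb[rows, ] + agg
    }
  }
  gr
}

# ---- Adam optimizer over named parameter lists ----

.adamInit <- function(params) {
  list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clipNorm = 5) {
  # global gradient-norm clipping for stability
  sq <- sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g^2), numeric(1L)))
  nrm <- sqrt(sq)
  scale <- if (is.finite(nrm) && nrm > clipNorm) clipNorm / nrm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (is.null(params[[nm]]) || is.null(grads[[nm]])) next
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
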