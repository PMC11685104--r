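# Reverse-mode gradients for the full design network, derived analytically
# and verified against central finite differences in the test suite.
#
# The loss is the unit-weight (configurable) combination of the iterative
# sequence cross-entropy, summed over all refinement iterations, and the
# secondary-structure cross-entropy on the final latent. Gradients flow
# through every refinement iteration, including the path where iteration k's
# probabilities re-enter iteration k+1 as the injected prior.

zero_like <- function(params) lapply(params, function(x) x * 0)

# Backward through row-softmax: given dL/dP and P, return dL/dlogits.
softmax_rows_backward <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

# Backward through layernorm_forward. dY is the gradient at the output.
layernorm_backward <- function(dY, xhat, inv, g) {
  dxhat <- sweep(dY, 2L, g, `*`)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# Backward through one encode() call. Accumulates parameter gradients into
# `grads` (an environment-free list returned updated) and returns the
# gradient at the (masked) initial node state H0.
encode_backward <- function(params, cfg, graph, cache, dH, grads) {
  n <- graph$n; K <- graph$config$K
  d <- cfg$hidden_dim
  nm <- graph$node_mask
  lay <- cache$lay
  for (l in rev(seq_len(cfg$encoder_layers))) {
    pre <- sprintf("L%d.", l)
    lc <- cache$layers[[l]]
    if (!is.null(lc$dmask)) dH <- dH * lc$dmask
    dH[!nm, ] <- 0
    lb <- layernorm_backward(dH, lc$xhat, lc$inv, params[[paste0(pre, "ln_g")]])
    grads[[paste0(pre, "ln_g")]] <- grads[[paste0(pre, "ln_g")]] + lb$dg
    grads[[paste0(pre, "ln_b")]] <- grads[[paste0(pre, "ln_b")]] + lb$db
    dpre <- lb$dx
    dpre[!nm, ] <- 0
    dH_prev <- dpre                       # residual branch
    dagg_e <- dpre[lay$i_idx, , drop = FALSE]
    dwflat <- rowSums(lc$M * dagg_e)
    wflat <- as.vector(t(lc$W))
    dM <- wflat * dagg_e
    dW_att_mat <- matrix(dwflat, n, K, byrow = TRUE)
    dS_att <- softmax_rows_backward(dW_att_mat, lc$W)
    ds <- as.vector(t(dS_att))
    grads[[paste0(pre, "W2")]] <- grads[[paste0(pre, "W2")]] +
      crossprod(lc$R1, dM)
    grads[[paste0(pre, "b2")]] <- grads[[paste0(pre, "b2")]] + colSums(dM)
    dR1 <- dM %*% t(params[[paste0(pre, "W2")]])
    grads[[paste0(pre, "w_att")]] <- grads[[paste0(pre, "w_att")]] +
      drop(crossprod(lc$R1, ds))
    grads[[paste0(pre, "b_att")]] <- grads[[paste0(pre, "b_att")]] + sum(ds)
    dR1 <- dR1 + tcrossprod(ds, params[[paste0(pre, "w_att")]])
    dA1 <- dR1 * lc$pos
    Z <- cbind(lc$H_in[lay$i_idx, , drop = FALSE],
               lc$H_in[lay$j_idx, , drop = FALSE], lay$E2)
    grads[[paste0(pre, "W1")]] <- grads[[paste0(pre, "W1")]] +
      crossprod(Z, dA1)
    grads[[paste0(pre, "b1")]] <- grads[[paste0(pre, "b1")]] + colSums(dA1)
    dZ <- dA1 %*% t(params[[paste0(pre, "W1")]])
    dHi <- rowsum(dZ[, seq_len(d), drop = FALSE], lay$i_idx)
    rownames(dHi) <- NULL
    dH_prev <- dH_prev + dHi
    dHj <- rowsum(dZ[, d + seq_len(d), drop = FALSE], lay$j_idx)
    tgt <- as.integer(rownames(dHj))
    dH_prev[tgt, ] <- dH_prev[tgt, , drop = FALSE] + dHj
    dH <- dH_prev
    dH[!nm, ] <- 0
  }
  list(grads = grads, dH0 = dH)
}

# Backward through predict_secondary(). Returns updated grads and the
# gradient at the latent.
ss_backward <- function(params, cache, dlogits, grads) {
  n <- nrow(dlogits)
  nm <- cache$node_mask
  grads$ss.W_ss <- grads$ss.W_ss + crossprod(cache$S2, dlogits)
  grads$ss.b_ss <- grads$ss.b_ss + colSums(dlogits)
  dS2 <- dlogits %*% t(params$ss.W_ss)
  dS2[!nm, ] <- 0
  lb <- layernorm_backward(dS2, cache$xhat, cache$inv, params$ss.ln_g)
  grads$ss.ln_g <- grads$ss.ln_g + lb$dg
  grads$ss.ln_b <- grads$ss.ln_b + lb$db
  dpre2 <- lb$dx
  dpre2[!nm, ] <- 0
  dH <- dpre2                              # residual branch
  dO <- dpre2
  grads$ss.Wo <- grads$ss.Wo + crossprod(cache$Cc, dO)
  grads$ss.bo <- grads$ss.bo + colSums(dO)
  dC <- dO %*% t(params$ss.Wo)
  dQ <- matrix(0, n, ncol(dH)); dK <- dQ; dV <- dQ
  dh <- cache$dh
  for (h in seq_len(cache$heads)) {
    ch <- (h - 1L) * dh + seq_len(dh)
    A <- cache$A[[h]]
    dCh <- dC[, ch, drop = FALSE]
    dA <- tcrossprod(dCh, cache$V[, ch, drop = FALSE])
    dV[, ch] <- crossprod(A, dCh)
    dS <- softmax_rows_backward(dA, A)
    dQ[, ch] <- dS %*% cache$Km[, ch, drop = FALSE] / sqrt(dh)
    dK[, ch] <- crossprod(dS, cache$Q[, ch, drop = FALSE]) / sqrt(dh)
  }
  latent <- cache$latent
  grads$ss.Wq <- grads$ss.Wq + crossprod(latent, dQ)
  grads$ss.Wk <- grads$ss.Wk + crossprod(latent, dK)
  grads$ss.Wv <- grads$ss.Wv + crossprod(latent, dV)
  dH <- dH + dQ %*% t(params$ss.Wq) + dK %*% t(params$ss.Wk) +
    dV %*% t(params$ss.Wv)
  list(grads = grads, dH = dH)
}

# Full forward + backward for one (graph, targets) pair.
#
# target_idx: integer length n in 1..4 (A,U,C,G), NA excludes a position
#   (padding) from the sequence loss.
# ss_idx: integer length n in 1..3 (., (, )), NA excludes; NULL disables the
#   secondary head entirely.
# weights: c(sup, sec) loss weights (total loss = sup * L_sup + sec * L_sec).
# Returns list(l_sup, l_sec, loss, grads, P_final).
model_grad <- function(model, graph, target_idx, ss_idx = NULL,
                       weights = c(1, 1), drop_masks_all = NULL) {
  params <- model$params
  cfg <- model$config
  n <- graph$n
  k_iter <- cfg$refinement_iterations
  clamp <- 1e-9

  priors <- vector("list", k_iter + 1L)
  priors[[1L]] <- matrix(0.25, n, 4L)
  enc_caches <- vector("list", k_iter)
  dec_caches <- vector("list", k_iter)
  P_list <- vector("list", k_iter)
  H <- NULL
  for (k in seq_len(k_iter)) {
    dm <- if (!is.null(drop_masks_all)) drop_masks_all[[k]] else NULL
    H <- encode(model, graph, priors[[k]], drop_masks = dm, want_cache = TRUE)
    enc_caches[[k]] <- attr(H, "cache")
    Pk <- decode_sequence(model, H, priors[[k]], want_cache = TRUE)
    dec_caches[[k]] <- attr(Pk, "cache")
    P_list[[k]] <- Pk
    priors[[k + 1L]] <- Pk
  }

  valid <- which(!is.na(target_idx))
  l_sup <- 0
  for (k in seq_len(k_iter)) {
    pt <- P_list[[k]][cbind(valid, target_idx[valid])]
    l_sup <- l_sup - sum(log(pmax(pt, clamp)))
  }

  l_sec <- 0
  ss_cache <- NULL
  P3 <- NULL
  if (!is.null(ss_idx)) {
    P3 <- predict_secondary(model, H, graph$node_mask, want_cache = TRUE)
    ss_cache <- attr(P3, "cache")
    ss_cache$latent <- H
    sv <- which(!is.na(ss_idx))
    at <- P3[cbind(sv, ss_idx[sv])]
    l_sec <- -sum(log(pmax(at, clamp)))
  }

  grads <- zero_like(params)
  dH_extra <- matrix(0, n, cfg$hidden_dim)
  if (!is.null(ss_idx)) {
    sv <- which(!is.na(ss_idx))
    dP3 <- matrix(0, n, 3L)
    at <- P3[cbind(sv, ss_idx[sv])]
    dP3[cbind(sv, ss_idx[sv])] <- -weights[2L] * (at >= clamp) / pmax(at, clamp)
    dlog3 <- softmax_rows_backward(dP3, P3)
    sb <- ss_backward(params, ss_cache, dlog3, grads)
    grads <- sb$grads
    dH_extra <- sb$dH
  }

  dP_next <- matrix(0, n, 4L)
  for (k in rev(seq_len(k_iter))) {
    Pk <- P_list[[k]]
    dP <- dP_next
    pt <- Pk[cbind(valid, target_idx[valid])]
    dP[cbind(valid, target_idx[valid])] <-
      dP[cbind(valid, target_idx[valid])] -
      weights[1L] * (pt >= clamp) / pmax(pt, clamp)
    dlogits <- softmax_rows_backward(dP, Pk)
    Zd <- dec_caches[[k]]$Zd
    grads$dec.W_dec <- grads$dec.W_dec + crossprod(Zd, dlogits)
    grads$dec.b_dec <- grads$dec.b_dec + colSums(dlogits)
    dZd <- dlogits %*% t(params$dec.W_dec)
    d <- cfg$hidden_dim
    dH <- dZd[, seq_len(d), drop = FALSE]
    if (k == k_iter) dH <- dH + dH_extra
    dPe <- dZd[, d + seq_len(cfg$prior_embed_dim), drop = FALSE]
    grads$dec.W_pemb <- grads$dec.W_pemb + crossprod(priors[[k]], dPe)
    grads$dec.b_pemb <- grads$dec.b_pemb + colSums(dPe)
    dP_prev <- dPe %*% t(params$dec.W_pemb)
    eb <- encode_backward(params, cfg, graph, enc_caches[[k]], dH, grads)
    grads <- eb$grads
    dH0 <- eb$dH0
    dH0[!graph$node_mask, ] <- 0
    grads$W_in <- grads$W_in + crossprod(graph$node, dH0)
    grads$b_in <- grads$b_in + colSums(dH0)
    grads$W_prior <- grads$W_prior + crossprod(priors[[k]], dH0)
    dP_prev <- dP_prev + dH0 %*% t(params$W_prior)
    dP_next <- dP_prev
  }

  list(l_sup = l_sup, l_sec = l_sec,
       loss = weights[1L] * l_sup + weights[2L] * l_sec,
       grads = grads, P_final = P_list[[k_iter]], P3 = P3)
}
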