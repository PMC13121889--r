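# Reverse-mode differentiation of forward_batch. Hand-derived per layer;
# correctness is enforced by finite-difference tests over all backbones,
# poolings and penalty modes. Returns parameter gradients and, on request,
# gradients with respect to the input node/edge feature matrices (used by
# the attribution methods) plus the upstream gradient at the last
# message-passing layer (used by Grad-CAM).

.pool_backward <- function(dr, H, mask, inst, pooling, cache, gate = NULL) {
  N <- nrow(H); h <- ncol(H)
  dH <- matrix(0, N, h)
  dgate <- NULL
  if (pooling == "mean") {
    w <- mask / pmax(cache$counts, 1)[inst]
    dH <- dr[inst, , drop = FALSE] * w
  } else if (pooling == "sum") {
    dH <- dr[inst, , drop = FALSE] * mask
  } else if (pooling == "max") {
    for (q in seq_len(nrow(dr))) {
      am <- cache$argmax[q, ]
      ok <- which(!is.na(am))
      for (c in ok) dH[am[c], c] <- dH[am[c], c] + dr[q, c]
    }
  } else { # attention
    dgate <- numeric(h)
    alpha <- cache$alpha
    for (q in seq_len(nrow(dr))) {
      idx <- which(inst == q & mask > 0)
      if (length(idx) == 0) next
      a <- alpha[idx]
      Hs <- H[idx, , drop = FALSE]
      dalpha <- as.numeric(Hs %*% dr[q, ])
      dH[idx, ] <- dH[idx, ] + a * matrix(dr[q, ], length(idx), h, byrow = TRUE)
      dscore <- a * (dalpha - sum(a * dalpha))
      dH[idx, ] <- dH[idx, ] + outer(dscore, gate)
      dgate <- dgate + as.numeric(dscore %*% Hs)
    }
  }
  list(dH = dH, dgate = dgate)
}

backward_batch <- function(state, batch, fwd, dyhat,
                           ddelta_cn = NULL, ddelta_ucn = NULL,
                           want_input_grads = FALSE) {
  cfg <- state$config
  pr <- state$params
  h <- cfg$hidden_dim
  N <- nrow(batch$X)
  M <- length(batch$src)
  sd <- cfg$subgraph_dim
  gr <- lapply(pr, function(p) { p[] <- 0; p })

  n_inst <- batch$n_inst
  ds_cn <- numeric(n_inst); ds_ucn <- numeric(n_inst)
  if (batch$n_pairs > 0 && !is.null(ddelta_cn)) {
    ds_cn[batch$inst_i] <- ds_cn[batch$inst_i] + ddelta_cn
    ds_cn[batch$inst_j] <- ds_cn[batch$inst_j] - ddelta_cn
    ds_ucn[batch$inst_i] <- ds_ucn[batch$inst_i] + ddelta_ucn
    ds_ucn[batch$inst_j] <- ds_ucn[batch$inst_j] - ddelta_ucn
  }

  hin_cn <- if (cfg$head_input == "projection") fwd$G_cn else fwd$r_cn
  hin_ucn <- if (cfg$head_input == "projection") fwd$G_ucn else fwd$r_ucn
  gr$beta_cn <- as.numeric(crossprod(hin_cn, ds_cn))
  gr$beta_ucn <- as.numeric(crossprod(hin_ucn, ds_ucn))
  gr$bhead_cn <- sum(ds_cn)
  gr$bhead_ucn <- sum(ds_ucn)
  dhin_cn <- outer(ds_cn, pr$beta_cn)
  dhin_ucn <- outer(ds_ucn, pr$beta_ucn)

  gr$wy <- as.numeric(crossprod(cbind(fwd$G_cn, fwd$G_ucn), dyhat))
  gr$by <- sum(dyhat)
  dG_cn <- outer(dyhat, pr$wy[seq_len(sd)])
  dG_ucn <- outer(dyhat, pr$wy[sd + seq_len(sd)])
  dr_cn <- matrix(0, n_inst, h); dr_ucn <- matrix(0, n_inst, h)
  if (cfg$head_input == "projection") {
    dG_cn <- dG_cn + dhin_cn
    dG_ucn <- dG_ucn + dhin_ucn
  } else {
    dr_cn <- dr_cn + dhin_cn
    dr_ucn <- dr_ucn + dhin_ucn
  }
  gr$P_cn <- crossprod(fwd$r_cn, dG_cn)
  gr$c_cn <- colSums(dG_cn)
  gr$P_ucn <- crossprod(fwd$r_ucn, dG_ucn)
  gr$c_ucn <- colSums(dG_ucn)
  dr_cn <- dr_cn + dG_cn %*% t(pr$P_cn)
  dr_ucn <- dr_ucn + dG_ucn %*% t(pr$P_ucn)

  pb_cn <- .pool_backward(dr_cn, fwd$H, batch$mask_cn, batch$inst,
                          cfg$pooling, fwd$pool_cn, pr$gate_cn)
  pb_ucn <- .pool_backward(dr_ucn, fwd$H, batch$mask_ucn, batch$inst,
                           cfg$pooling, fwd$pool_ucn, pr$gate_ucn)
  dH <- pb_cn$dH + pb_ucn$dH
  if (cfg$pooling == "attention") {
    gr$gate_cn <- pb_cn$dgate
    gr$gate_ucn <- pb_ucn$dgate
  }
  dH_last <- dH

  dEun_acc <- NULL
  dEemb_edge <- if (want_input_grads && M > 0) matrix(0, M, h) else NULL
  if (cfg$backbone == "edge_conditioned" && !is.null(fwd$Eun)) {
    dEun_acc <- matrix(0, nrow(fwd$Eun), h)
  }

  for (l in rev(seq_len(cfg$n_layers))) {
    cache <- fwd$layers[[l]]
    dZbn <- if (cfg$activation == "relu") dH * (cache$Zbn > 0) else dH
    gamma <- pr[[paste0("gamma_", l)]]
    gr[[paste0("gamma_", l)]] <- colSums(dZbn * cache$Zhat)
    gr[[paste0("beta_", l)]] <- colSums(dZbn)
    if (isTRUE(cache$training_bn)) {
      dZhat <- .mulrow(dZbn, gamma)
      m1 <- colMeans(dZhat)
      m2 <- colMeans(dZhat * cache$Zhat)
      dZ <- .addrow(dZhat, -m1) - .mulrow(cache$Zhat, m2)
      dZ <- .mulrow(dZ, cache$istd)
    } else {
      dZ <- .mulrow(dZbn, gamma * cache$istd)
    }
    gr[[paste0("b_", l)]] <- colSums(dZ)
    Hprev <- cache$Hprev

    if (cfg$backbone == "edge_conditioned") {
      Ws <- pr[[paste0("Ws_", l)]]
      gr[[paste0("Ws_", l)]] <- crossprod(Hprev, dZ)
      dHprev <- dZ %*% t(Ws)
      if (M > 0) {
        dmsg <- dZ[batch$dst, , drop = FALSE]
        Hsrc <- Hprev[batch$src, , drop = FALSE]
        dHsrc <- matrix(0, M, h)
        u <- nrow(cache$Aun)
        dAun <- matrix(0, u, h * h)
        for (t in seq_len(u)) {
          idx <- which(batch$etype == t)
          if (length(idx) == 0) next
          Wt <- matrix(cache$Aun[t, ], h, h)
          dHsrc[idx, ] <- dmsg[idx, , drop = FALSE] %*% t(Wt)
          dAun[t, ] <- as.numeric(crossprod(Hsrc[idx, , drop = FALSE],
                                            dmsg[idx, , drop = FALSE]))
        }
        dHprev <- dHprev + .seg_sum(dHsrc, batch$src, N)
        Wa <- pr[[paste0("Wa_", l)]]
        gr[[paste0("Wa_", l)]] <- crossprod(fwd$Eun, dAun)
        gr[[paste0("ba_", l)]] <- colSums(dAun)
        dEun_acc <- dEun_acc + dAun %*% t(Wa)
        if (want_input_grads) {
          # per-edge gradient through the edge network (cannot be shared
          # across edges of one feature type); column-major vec layout to
          # match matrix(Aun[t, ], h, h)
          dA_edge <- matrix(0, M, h * h)
          for (j in seq_len(h)) {
            dA_edge[, (j - 1L) * h + seq_len(h)] <- dmsg[, j] * Hsrc
          }
          dEemb_edge <- dEemb_edge + dA_edge %*% t(Wa)
        }
      }
    } else if (cfg$backbone == "gin") {
      eps <- pr[[paste0("eps_", l)]]
      W1 <- pr[[paste0("W1_", l)]]
      dpre <- dZ %*% t(W1)
      gr[[paste0("W1_", l)]] <- crossprod(cache$pre, dZ)
      gr[[paste0("eps_", l)]] <- sum(dpre * Hprev)
      dHprev <- (1 + eps) * dpre
      if (M > 0) {
        dHprev <- dHprev + .seg_sum(dpre[batch$dst, , drop = FALSE],
                                    batch$src, N)
      }
    } else { # gat
      Wg <- pr[[paste0("Wg_", l)]]
      asrc <- pr[[paste0("asrc_", l)]]
      adst <- pr[[paste0("adst_", l)]]
      P1 <- cache$P1
      src2 <- cache$src2; dst2 <- cache$dst2
      alpha <- cache$alpha
      dout_e <- dZ[dst2, , drop = FALSE]
      P1src <- P1[src2, , drop = FALSE]
      dalpha <- rowSums(dout_e * P1src)
      dP1 <- .seg_sum(dout_e * alpha, src2, N)
      Ssum <- as.numeric(.seg_sum(matrix(alpha * dalpha), dst2, N))
      dscore <- alpha * (dalpha - Ssum[dst2])
      dsr <- dscore * ifelse(cache$s > 0, 1, 0.2)
      gr[[paste0("asrc_", l)]] <- as.numeric(crossprod(P1src, dsr))
      gr[[paste0("adst_", l)]] <- as.numeric(crossprod(P1[dst2, , drop = FALSE], dsr))
      dP1 <- dP1 + .seg_sum(outer(dsr, asrc), src2, N) +
        .seg_sum(outer(dsr, adst), dst2, N)
      gr[[paste0("Wg_", l)]] <- crossprod(Hprev, dP1)
      dHprev <- dP1 %*% t(Wg)
    }
    dH <- dHprev
  }

  gr$Wn <- crossprod(batch$X, dH)
  gr$bn <- colSums(dH)
  dX <- NULL; dE <- NULL
  if (want_input_grads) dX <- dH %*% t(pr$Wn)
  if (!is.null(dEun_acc)) {
    gr$We <- crossprod(batch$E_unique, dEun_acc)
    gr$be <- colSums(dEun_acc)
    if (want_input_grads && !is.null(dEemb_edge)) {
      dE <- dEemb_edge %*% t(pr$We)
    }
  } else if (want_input_grads && M > 0) {
    dE <- matrix(0, M, cfg$edge_dim)
  }
  list(grads = gr, dX = dX, dE = dE, dH_last = dH_last)
}
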