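#' Model architecture configuration
#'
#' Describes the message-passing backbone used for affinity prediction:
#' separate 50->32 node and 10->32 edge embedding layers, three
#' message-passing layers with additive neighbour aggregation (each followed
#' by batch normalization and an activation), masked common/uncommon
#' readouts, 32->16 branch projections, a final linear affinity head on the
#' 16+16 concatenation, and 16->1 subgraph heads whose weights carry the
#' structured-sparsity penalties.
#'
#' @param backbone `"edge_conditioned"` (an NNConv-style layer whose edge
#'   network maps the 32-d edge embedding to a 32 x 32 message weight
#'   matrix), `"gin"` (graph isomorphism layer with a learnable epsilon) or
#'   `"gat"` (single-head graph attention; node features only).
#' @param n_layers Number of message-passing layers.
#' @param hidden_dim Hidden width of node/edge embeddings.
#' @param subgraph_dim Width of the projected subgraph representations fed to
#'   the subgraph heads.
#' @param pooling Readout pooling; defaults to the backbone's convention
#'   (edge_conditioned -> mean, gin -> sum, gat -> mean).
#' @param activation `"relu"` or `"identity"` (the latter makes the network
#'   linear, which is useful for attribution sanity checks).
#' @param head_input `"projection"`: the subgraph heads consume the 16-d
#'   projections (default); `"readout"`: they consume the 32-d readouts.
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("edge_conditioned", "gin", "gat"),
                         n_layers = 3, hidden_dim = 32, subgraph_dim = 16,
                         pooling = NULL,
                         activation = c("relu", "identity"),
                         head_input = c("projection", "readout")) {
  backbone <- match.arg(backbone)
  activation <- match.arg(activation)
  head_input <- match.arg(head_input)
  if (is.null(pooling)) {
    pooling <- switch(backbone, edge_conditioned = "mean", gin = "sum",
                      gat = "mean")
  }
  pooling <- match.arg(pooling, c("mean", "sum", "max", "attention"))
  stopifnot(n_layers >= 1, hidden_dim >= 1, subgraph_dim >= 1)
  structure(list(backbone = backbone, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 subgraph_dim = as.integer(subgraph_dim), pooling = pooling,
                 activation = activation, head_input = head_input,
                 node_dim = 50L, edge_dim = 10L, bn_eps = 1e-5,
                 bn_momentum = 0.1),
            class = "model_config")
}

.glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

.param_shapes <- function(cfg) {
  h <- cfg$hidden_dim
  p <- if (cfg$head_input == "projection") cfg$subgraph_dim else h
  shapes <- list(Wn = c(cfg$node_dim, h), bn = h,
                 We = c(cfg$edge_dim, h), be = h)
  for (l in seq_len(cfg$n_layers)) {
    if (cfg$backbone == "edge_conditioned") {
      shapes[[paste0("Wa_", l)]] <- c(h, h * h)
      shapes[[paste0("ba_", l)]] <- h * h
      shapes[[paste0("Ws_", l)]] <- c(h, h)
    } else if (cfg$backbone == "gin") {
      shapes[[paste0("eps_", l)]] <- 1
      shapes[[paste0("W1_", l)]] <- c(h, h)
    } else {
      shapes[[paste0("Wg_", l)]] <- c(h, h)
      shapes[[paste0("asrc_", l)]] <- h
      shapes[[paste0("adst_", l)]] <- h
    }
    shapes[[paste0("b_", l)]] <- h
    shapes[[paste0("gamma_", l)]] <- h
    shapes[[paste0("beta_", l)]] <- h
  }
  shapes$P_cn <- c(h, cfg$subgraph_dim); shapes$c_cn <- cfg$subgraph_dim
  shapes$P_ucn <- c(h, cfg$subgraph_dim); shapes$c_ucn <- cfg$subgraph_dim
  shapes$wy <- 2L * cfg$subgraph_dim; shapes$by <- 1
  shapes$beta_cn <- p; shapes$bhead_cn <- 1
  shapes$beta_ucn <- p; shapes$bhead_ucn <- 1
  shapes$cam_w_cn <- h; shapes$cam_b_cn <- 1
  shapes$cam_w_ucn <- h; shapes$cam_b_ucn <- 1
  if (cfg$pooling == "attention") {
    shapes$gate_cn <- h; shapes$gate_ucn <- h
  }
  shapes
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, batch-norm scale 1 / shift 0, unit
#' running variance. Fully reproducible given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed governing initialization.
#' @return A `model_state`: `config`, `params` (named list of arrays),
#'   `bn_mean`/`bn_var` running statistics per layer, and `seed`.
#' @export
init_model_state <- function(config, seed = 1) {
  shapes <- .param_shapes(config)
  zero_re <- "^(bn|be|ba_[0-9]+|b_[0-9]+|beta_[0-9]+|c_cn|c_ucn|by|bhead_cn|bhead_ucn|cam_b_cn|cam_b_ucn)$"
  params <- withr::with_seed(as.integer(seed), {
    lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (startsWith(nm, "gamma")) return(rep(1, sh))
      if (startsWith(nm, "eps_")) return(0)
      if (grepl(zero_re, nm)) return(if (length(sh) == 2) matrix(0, sh[1], sh[2]) else rep(0, sh))
      if (length(sh) == 2) .glorot(sh[1], sh[2])
      else {
        a <- sqrt(6 / (sh + 1))
        stats::runif(sh, -a, a)
      }
    })
  })
  names(params) <- names(shapes)
  h <- config$hidden_dim
  bn_mean <- replicate(config$n_layers, rep(0, h), simplify = FALSE)
  bn_var <- replicate(config$n_layers, rep(1, h), simplify = FALSE)
  structure(list(config = config, params = params, bn_mean = bn_mean,
                 bn_var = bn_var, seed = as.integer(seed)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<model_state: %s backbone, %d layers, %d hidden, %d params>\n",
              x$config$backbone, x$config$n_layers, x$config$hidden_dim,
              as.integer(np)))
  invisible(x)
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(vec, params) {
  out <- params
  pos <- 0L
  for (nm in names(params)) {
    len <- length(params[[nm]])
    out[[nm]][] <- vec[pos + seq_len(len)]
    pos <- pos + len
  }
  out
}

# --- batched graph assembly ---------------------------------------------

# A "batch" concatenates compound instances (each pair contributes two, in
# order i then j) into one block-diagonal graph, the standard trick for
# vectorizing message passing. Masks are per node; pooling groups by
# instance id.
build_pair_batch <- function(pair_rows, masks, graphs, activities = NULL) {
  pid_v <- pair_rows$pair_id
  i_v <- pair_rows$i
  j_v <- pair_rows$j
  P <- length(pid_v)
  Xs <- vector("list", 2L * P); Es <- vector("list", 2L * P)
  keys <- vector("list", 2L * P)
  srcs <- vector("list", 2L * P); dsts <- vector("list", 2L * P)
  inst <- vector("list", 2L * P)
  mc <- vector("list", 2L * P); mu <- vector("list", 2L * P)
  y <- numeric(2L * P)
  offset <- 0L
  for (p in seq_len(P)) {
    mk <- masks[[pid_v[p]]]
    for (side in 1:2) {
      q <- 2L * (p - 1L) + side
      cid <- if (side == 1) i_v[p] else j_v[p]
      g <- graphs[[cid]]
      if (is.null(g)) {
        stop(sprintf("no graph for compound %s (pair %s)", cid, pid_v[p]))
      }
      if (length(mk[[if (side == 1) "mask_common_i" else "mask_common_j"]]) !=
          g$n_atoms) {
        stop(sprintf("mask/graph length mismatch for pair %s", pid_v[p]))
      }
      if (!is.null(activities)) y[q] <- activities[[cid]]
      Xs[[q]] <- g$node_features
      Es[[q]] <- g$edge_features
      keys[[q]] <- g$edge_key
      srcs[[q]] <- g$edge_index[, 1L] + offset
      dsts[[q]] <- g$edge_index[, 2L] + offset
      inst[[q]] <- rep(q, g$n_atoms)
      mc[[q]] <- if (side == 1) mk$mask_common_i else mk$mask_common_j
      mu[[q]] <- if (side == 1) mk$mask_uncommon_i else mk$mask_uncommon_j
      offset <- offset + g$n_atoms
    }
  }
  E <- do.call(rbind, Es)
  key <- unlist(keys)
  ukey <- unique(key)
  list(X = do.call(rbind, Xs), E = E,
       E_unique = E[match(ukey, key), , drop = FALSE],
       etype = match(key, ukey),
       src = unlist(srcs), dst = unlist(dsts),
       inst = unlist(inst), n_inst = 2L * P, n_pairs = P,
       mask_cn = as.numeric(unlist(mc)), mask_ucn = as.numeric(unlist(mu)),
       pair_ids = pid_v, y = y,
       delta_y = pair_rows$delta_y,
       inst_i = 2L * seq_len(P) - 1L, inst_j = 2L * seq_len(P))
}

# Single-compound batch; by default both branches see the whole graph
# (all-ones masks), which is the convention for standalone prediction and
# attribution outside a pair context.
build_single_batch <- function(graph, mask_cn = NULL, mask_ucn = NULL) {
  n <- graph$n_atoms
  if (is.null(mask_cn)) mask_cn <- rep(1L, n)
  if (is.null(mask_ucn)) mask_ucn <- rep(1L, n)
  E <- graph$edge_features
  key <- if (is.null(graph$edge_key) && nrow(E) > 0) {
    apply(E, 1, paste, collapse = ",")
  } else graph$edge_key
  ukey <- unique(key)
  list(X = graph$node_features, E = E,
       E_unique = E[match(ukey, key), , drop = FALSE],
       etype = match(key, ukey),
       src = graph$edge_index[, 1L], dst = graph$edge_index[, 2L],
       inst = rep(1L, n), n_inst = 1L, n_pairs = 0L,
       mask_cn = as.numeric(mask_cn), mask_ucn = as.numeric(mask_ucn),
       pair_ids = character(0), inst_i = integer(0), inst_j = integer(0))
}

.addrow <- function(M, v) M + rep(v, each = nrow(M))
.mulrow <- function(M, v) M * rep(v, each = nrow(M))

.seg_sum <- function(M, group, n_groups) {
  out <- matrix(0, n_groups, ncol(M))
  if (nrow(M) > 0) {
    tmp <- rowsum(M, group)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

# --- forward pass --------------------------------------------------------

.pool_forward <- function(H, mask, inst, n_inst, pooling, gate = NULL) {
  h <- ncol(H)
  sel <- H * mask
  cache <- list()
  if (pooling %in% c("mean", "sum")) {
    sums <- .seg_sum(sel, inst, n_inst)
    counts <- as.numeric(.seg_sum(matrix(mask), inst, n_inst))
    r <- if (pooling == "mean") sums / pmax(counts, 1) else sums
    cache <- list(counts = counts)
  } else if (pooling == "max") {
    r <- matrix(0, n_inst, h)
    argm <- matrix(NA_integer_, n_inst, h)
    for (q in seq_len(n_inst)) {
      idx <- which(inst == q & mask > 0)
      if (length(idx) == 0) next
      sub <- H[idx, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      r[q, ] <- sub[cbind(am, seq_len(h))]
      argm[q, ] <- idx[am]
    }
    cache <- list(argmax = argm)
  } else { # attention
    r <- matrix(0, n_inst, h)
    alpha <- numeric(length(mask))
    for (q in seq_len(n_inst)) {
      idx <- which(inst == q & mask > 0)
      if (length(idx) == 0) next
      s <- as.numeric(H[idx, , drop = FALSE] %*% gate)
      a <- exp(s - max(s)); a <- a / sum(a)
      alpha[idx] <- a
      r[q, ] <- as.numeric(a %*% H[idx, , drop = FALSE])
    }
    cache <- list(alpha = alpha)
  }
  list(r = r, cache = cache)
}

# Full forward pass over a batch. In `training` mode batch normalization
# uses batch statistics (and optionally updates the running ones); in
# inference mode it is an affine map using the running statistics.
forward_batch <- function(state, batch, training = FALSE,
                          update_bn = training) {
  cfg <- state$config
  pr <- state$params
  h <- cfg$hidden_dim
  N <- nrow(batch$X)
  M <- length(batch$src)
  act <- function(Z) if (cfg$activation == "relu") pmax(Z, 0) else Z

  H <- batch$X %*% pr$Wn
  H <- .addrow(H, pr$bn)
  Eun <- NULL
  if (cfg$backbone == "edge_conditioned" && nrow(batch$E_unique) > 0) {
    Eun <- .addrow(batch$E_unique %*% pr$We, pr$be)
  }

  layers <- vector("list", cfg$n_layers)
  new_bn_mean <- state$bn_mean
  new_bn_var <- state$bn_var
  for (l in seq_len(cfg$n_layers)) {
    cache <- list(Hprev = H)
    if (cfg$backbone == "edge_conditioned") {
      agg <- matrix(0, N, h)
      if (M > 0) {
        Aun <- .addrow(Eun %*% pr[[paste0("Wa_", l)]], pr[[paste0("ba_", l)]])
        Hsrc <- H[batch$src, , drop = FALSE]
        msg <- matrix(0, M, h)
        for (t in seq_len(nrow(Aun))) {
          idx <- which(batch$etype == t)
          if (length(idx) == 0) next
          Wt <- matrix(Aun[t, ], h, h)
          msg[idx, ] <- Hsrc[idx, , drop = FALSE] %*% Wt
        }
        agg <- .seg_sum(msg, batch$dst, N)
        cache$Aun <- Aun; cache$msg <- msg
      }
      Z <- H %*% pr[[paste0("Ws_", l)]] + agg
    } else if (cfg$backbone == "gin") {
      agg <- matrix(0, N, h)
      if (M > 0) agg <- .seg_sum(H[batch$src, , drop = FALSE], batch$dst, N)
      pre <- (1 + pr[[paste0("eps_", l)]]) * H + agg
      Z <- pre %*% pr[[paste0("W1_", l)]]
      cache$pre <- pre
    } else { # gat, with self-loops in the attention
      P1 <- H %*% pr[[paste0("Wg_", l)]]
      src2 <- c(batch$src, seq_len(N))
      dst2 <- c(batch$dst, seq_len(N))
      s <- as.numeric(P1[src2, , drop = FALSE] %*% pr[[paste0("asrc_", l)]]) +
        as.numeric(P1[dst2, , drop = FALSE] %*% pr[[paste0("adst_", l)]])
      sl <- ifelse(s > 0, s, 0.2 * s)
      grp <- dst2
      mx <- tapply(sl, grp, max)[as.character(grp)]
      ex <- exp(sl - as.numeric(mx))
      denom <- as.numeric(.seg_sum(matrix(ex), grp, N))
      alpha <- ex / denom[grp]
      Z <- .seg_sum(P1[src2, , drop = FALSE] * alpha, grp, N)
      cache$P1 <- P1; cache$s <- s; cache$alpha <- alpha
      cache$src2 <- src2; cache$dst2 <- dst2
    }
    Z <- .addrow(Z, pr[[paste0("b_", l)]])
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(.addrow(Z, -mu)^2)
      if (update_bn) {
        mom <- cfg$bn_momentum
        new_bn_mean[[l]] <- (1 - mom) * new_bn_mean[[l]] + mom * mu
        vub <- if (N > 1) v * N / (N - 1) else v
        new_bn_var[[l]] <- (1 - mom) * new_bn_var[[l]] + mom * vub
      }
    } else {
      mu <- state$bn_mean[[l]]
      v <- state$bn_var[[l]]
    }
    istd <- 1 / sqrt(v + cfg$bn_eps)
    Zhat <- .mulrow(.addrow(Z, -mu), istd)
    Zbn <- .addrow(.mulrow(Zhat, pr[[paste0("gamma_", l)]]), pr[[paste0("beta_", l)]])
    Hnew <- act(Zbn)
    cache$Zhat <- Zhat; cache$istd <- istd; cache$Zbn <- Zbn
    cache$training_bn <- training
    layers[[l]] <- cache
    H <- Hnew
  }

  gcn <- .pool_forward(H, batch$mask_cn, batch$inst, batch$n_inst,
                       cfg$pooling, pr$gate_cn)
  gucn <- .pool_forward(H, batch$mask_ucn, batch$inst, batch$n_inst,
                        cfg$pooling, pr$gate_ucn)
  G_cn <- .addrow(gcn$r %*% pr$P_cn, pr$c_cn)
  G_ucn <- .addrow(gucn$r %*% pr$P_ucn, pr$c_ucn)
  yhat <- as.numeric(cbind(G_cn, G_ucn) %*% pr$wy) + pr$by

  head_cn_in <- if (cfg$head_input == "projection") G_cn else gcn$r
  head_ucn_in <- if (cfg$head_input == "projection") G_ucn else gucn$r
  s_cn <- as.numeric(head_cn_in %*% pr$beta_cn) + pr$bhead_cn
  s_ucn <- as.numeric(head_ucn_in %*% pr$beta_ucn) + pr$bhead_ucn

  delta_cn <- delta_ucn <- numeric(0)
  if (batch$n_pairs > 0) {
    delta_cn <- s_cn[batch$inst_i] - s_cn[batch$inst_j]
    delta_ucn <- s_ucn[batch$inst_i] - s_ucn[batch$inst_j]
  }
  list(H = H, Eun = Eun, layers = layers,
       r_cn = gcn$r, r_ucn = gucn$r, pool_cn = gcn$cache,
       pool_ucn = gucn$cache, G_cn = G_cn, G_ucn = G_ucn,
       yhat = yhat, s_cn = s_cn, s_ucn = s_ucn,
       delta_cn = delta_cn, delta_ucn = delta_ucn,
       bn_mean = new_bn_mean, bn_var = new_bn_var)
}

# --- exported operation wrappers ----------------------------------------

#' Node embeddings after message passing
#'
#' Runs the input embedding and all message-passing layers (inference mode)
#' for one compound and returns the latent node representations.
#'
#' @param state A `model_state`.
#' @param graph A featurized `molecular_graph`.
#' @return Matrix n_atoms x hidden_dim.
#' @export
embed_and_propagate <- function(state, graph) {
  if (ncol(graph$node_features) != state$config$node_dim ||
      ncol(graph$edge_features) != state$config$edge_dim) {
    stop("graph feature widths do not match the model configuration")
  }
  batch <- build_single_batch(graph)
  forward_batch(state, batch, training = FALSE)$H
}

#' Masked subgraph readout
#'
#' Pools the rows of `h` selected by a binary mask into one vector. Mean
#' pooling divides by the number of selected nodes (not the total); an
#' all-zero mask returns the zero vector.
#'
#' @param h Node-embedding matrix (n x d).
#' @param mask Binary vector of length n.
#' @param pooling `"mean"`, `"sum"`, `"max"` or `"attention"`.
#' @param gate Gate vector (length d) for attention pooling.
#' @return Numeric vector of length d.
#' @export
masked_readout <- function(h, mask, pooling = "mean", gate = NULL) {
  stopifnot(length(mask) == nrow(h))
  if (pooling == "attention" && is.null(gate)) {
    stop("attention pooling needs a gate vector")
  }
  out <- .pool_forward(h, as.numeric(mask), rep(1L, nrow(h)), 1L, pooling,
                       gate)
  as.numeric(out$r[1, ])
}

#' Linear affinity head
#'
#' @param g_cn,g_ucn Projected common / uncommon subgraph representations.
#' @param state A `model_state`.
#' @return Scalar predicted pIC50 (linear in the concatenation).
#' @export
affinity_head <- function(g_cn, g_ucn, state) {
  as.numeric(sum(c(g_cn, g_ucn) * state$params$wy) + state$params$by)
}

#' Predicted activity difference, decomposed by subgraph
#'
#' Applies the two subgraph heads to both compounds' representations and
#' returns the common and uncommon components of the predicted activity
#' difference. Head biases cancel in each difference.
#'
#' @param g_i_cn,g_i_ucn,g_j_cn,g_j_ucn Subgraph representations of
#'   compounds i and j.
#' @param state A `model_state`.
#' @return List with `delta_cn` and `delta_ucn`.
#' @export
subgraph_delta <- function(g_i_cn, g_i_ucn, g_j_cn, g_j_ucn, state) {
  list(delta_cn = as.numeric(sum(state$params$beta_cn * (g_i_cn - g_j_cn))),
       delta_ucn = as.numeric(sum(state$params$beta_ucn * (g_i_ucn - g_j_ucn))))
}

#' Full forward pass for one activity-cliff pair
#'
#' Embeds both compounds, applies the masked common/uncommon readouts,
#' predicts both affinities and the decomposed activity difference.
#' Deterministic in inference mode.
#'
#' @param state A `model_state`.
#' @param dataset An `ac_pair_dataset`.
#' @param pair_id A pair id present in the dataset.
#' @return List with `yhat_i`, `yhat_j`, `delta_cn`, `delta_ucn`, and the
#'   per-compound readouts `g_cn`, `g_ucn` (rows: i, j).
#' @export
forward_pair <- function(state, dataset, pair_id) {
  rows <- dataset$pairs[dataset$pairs$pair_id == pair_id, , drop = FALSE]
  if (nrow(rows) != 1) stop(sprintf("unknown pair_id: %s", pair_id))
  batch <- build_pair_batch(rows, dataset$masks, dataset$graphs,
                            .activities_of(dataset))
  fwd <- forward_batch(state, batch, training = FALSE)
  list(yhat_i = fwd$yhat[1], yhat_j = fwd$yhat[2],
       delta_cn = fwd$delta_cn[1], delta_ucn = fwd$delta_ucn[1],
       g_cn = fwd$G_cn, g_ucn = fwd$G_ucn)
}
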