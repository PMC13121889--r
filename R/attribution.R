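#' Compute a signed per-atom attribution map
#'
#' Four gradient-based attribution methods over the predicted affinity
#' (a regression target: all gradients are taken with respect to the scalar
#' prediction). Scores are signed; per-feature contributions are reduced to
#' per-node (and, for the input-gradient methods, per-directed-edge) scalars
#' by summation, which keeps the closed-form equalities of linear models
#' exact.
#'
#' Methods:
#' * `cam`: last-layer node activations dotted with the effective linear
#'   readout weights (projection weights composed with the affinity head);
#'   only defined for the linear readout path (mean or sum pooling).
#' * `grad_cam`: channel weights are the node-mean of the gradient of the
#'   prediction with respect to the last-layer activations; node score is
#'   the weighted channel sum, without rectification so that negative
#'   contributions survive.
#' * `gradient_x_input`: elementwise product of input features and the
#'   prediction gradient, summed per node/edge.
#' * `integrated_gradients`: path integral from the all-zero-feature
#'   baseline on the same topology, trapezoid rule with `options$steps`
#'   interpolation points (default 64).
#'
#' @param state A trained `model_state`.
#' @param graph A featurized `molecular_graph`.
#' @param method One of `"cam"`, `"grad_cam"`, `"gradient_x_input"`,
#'   `"integrated_gradients"`.
#' @param options List: `steps` (IG interpolants, >= 2), `mask_common` /
#'   `mask_uncommon` (branch masks; default whole graph for both).
#' @return An `attribution_map`: `compound_id`, `method`, `node_scores`,
#'   `edge_scores` (per directed edge, or `NULL`), `options`.
#' @export
attribute <- function(state, graph,
                      method = c("cam", "grad_cam", "gradient_x_input",
                                 "integrated_gradients"),
                      options = list()) {
  method <- match.arg(method)
  cfg <- state$config
  sd <- cfg$subgraph_dim
  batch <- build_single_batch(graph, options$mask_common,
                              options$mask_uncommon)
  new_map <- function(node, edge = NULL) {
    structure(list(compound_id = graph$compound_id, method = method,
                   node_scores = as.numeric(node), edge_scores = edge,
                   options = options),
              class = "attribution_map")
  }

  if (method == "cam") {
    if (!cfg$pooling %in% c("mean", "sum")) {
      stop(sprintf(
        "CAM requires the linear readout path (mean or sum pooling), not '%s'",
        cfg$pooling))
    }
    fwd <- forward_batch(state, batch, training = FALSE)
    w_eff <- state$params$P_cn %*% state$params$wy[seq_len(sd)] +
      state$params$P_ucn %*% state$params$wy[sd + seq_len(sd)]
    return(new_map(fwd$H %*% w_eff))
  }

  if (method == "grad_cam") {
    fwd <- forward_batch(state, batch, training = FALSE)
    bk <- backward_batch(state, batch, fwd, dyhat = 1)
    ch_w <- colMeans(bk$dH_last)
    return(new_map(as.numeric(fwd$H %*% ch_w)))
  }

  if (method == "gradient_x_input") {
    fwd <- forward_batch(state, batch, training = FALSE)
    bk <- backward_batch(state, batch, fwd, dyhat = 1,
                         want_input_grads = TRUE)
    node <- rowSums(batch$X * bk$dX)
    edge <- if (!is.null(bk$dE) && nrow(batch$E) > 0) {
      rowSums(batch$E * bk$dE)
    } else if (nrow(batch$E) > 0) numeric(nrow(batch$E)) else NULL
    return(new_map(node, edge))
  }

  # integrated gradients
  steps <- if (is.null(options$steps)) 64L else as.integer(options$steps)
  if (steps < 2L) stop("integrated gradients needs options$steps >= 2")
  tgrid <- seq(0, 1, length.out = steps)
  w <- rep(1, steps); w[c(1, steps)] <- 0.5; w <- w / (steps - 1)
  accX <- matrix(0, nrow(batch$X), ncol(batch$X))
  accE <- if (nrow(batch$E) > 0) matrix(0, nrow(batch$E), ncol(batch$E)) else NULL
  for (s in seq_len(steps)) {
    bt <- batch
    bt$X <- batch$X * tgrid[s]
    bt$E <- batch$E * tgrid[s]
    bt$E_unique <- batch$E_unique * tgrid[s]
    fwd <- forward_batch(state, bt, training = FALSE)
    bk <- backward_batch(state, bt, fwd, dyhat = 1, want_input_grads = TRUE)
    accX <- accX + w[s] * bk$dX
    if (!is.null(accE) && !is.null(bk$dE)) accE <- accE + w[s] * bk$dE
  }
  node <- rowSums(batch$X * accX)
  edge <- if (!is.null(accE)) rowSums(batch$E * accE) else NULL
  new_map(node, edge)
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map %s [%s]: %d node scores%s>\n",
              x$compound_id, x$method, length(x$node_scores),
              if (is.null(x$edge_scores)) "" else
                sprintf(", %d edge scores", length(x$edge_scores))))
  invisible(x)
}

#' Redistribute edge attributions onto endpoint nodes
#'
#' The two directed scores of each bond are first averaged into one bond
#' score, which then splits half to each endpoint atom. The total
#' attribution mass is conserved: the new node-score sum equals the old
#' node-score sum plus the per-bond score sum.
#'
#' @param map An `attribution_map` with `edge_scores`.
#' @param graph The `molecular_graph` the map belongs to.
#' @return A node-only `attribution_map`.
#' @export
redistribute_edge_to_nodes <- function(map, graph) {
  stopifnot(inherits(map, "attribution_map"))
  if (is.null(map$edge_scores)) return(map)
  node <- map$node_scores
  m <- nrow(graph$bonds)
  if (m > 0) {
    es <- map$edge_scores
    for (t in seq_len(m)) {
      bond_score <- (es[2 * t - 1] + es[2 * t]) / 2
      node[graph$bonds$a[t]] <- node[graph$bonds$a[t]] + bond_score / 2
      node[graph$bonds$b[t]] <- node[graph$bonds$b[t]] + bond_score / 2
    }
  }
  map$node_scores <- node
  map$edge_scores <- NULL
  map
}

#' Raw outputs of the per-node linear attribution heads
#'
#' The two 32 -> 1 node-level heads (common and uncommon) applied to the
#' last-layer node embeddings. These heads are exposed for CAM-style
#' inspection but do not enter the affinity prediction path.
#'
#' @param state A `model_state`.
#' @param graph A featurized `molecular_graph`.
#' @return Matrix n x 2 with columns `cn`, `ucn`.
#' @export
node_head_scores <- function(state, graph) {
  batch <- build_single_batch(graph)
  fwd <- forward_batch(state, batch, training = FALSE)
  cbind(cn = as.numeric(fwd$H %*% state$params$cam_w_cn) +
          state$params$cam_b_cn,
        ucn = as.numeric(fwd$H %*% state$params$cam_w_ucn) +
          state$params$cam_b_ucn)
}

#' Attribution maps for every compound of a dataset
#'
#' @param state A trained `model_state`.
#' @param dataset An `ac_pair_dataset` (graphs are taken from it).
#' @param method Attribution method passed to [attribute()].
#' @param options Options passed to [attribute()].
#' @param redistribute Fold edge scores onto nodes (default `TRUE`).
#' @param compound_ids Subset of compounds (default: all).
#' @return Named list of node-score vectors keyed by compound id.
#' @export
attribute_all <- function(state, dataset, method = "gradient_x_input",
                          options = list(), redistribute = TRUE,
                          compound_ids = NULL) {
  if (is.null(compound_ids)) compound_ids <- names(dataset$graphs)
  maps <- lapply(compound_ids, function(cid) {
    g <- dataset$graphs[[cid]]
    m <- attribute(state, g, method, options)
    if (redistribute) m <- redistribute_edge_to_nodes(m, g)
    m$node_scores
  })
  names(maps) <- compound_ids
  maps
}
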