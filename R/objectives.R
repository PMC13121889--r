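#' Loss configuration
#'
#' Bundles the weights of the node-level pair loss, the structured-sparsity
#' penalty on the subgraph heads, and the baseline-mode switch.
#'
#' @param lambda_cn,lambda_ucn Non-negative weights of the common / uncommon
#'   predicted activity differences inside the node-level loss.
#' @param penalty `"none"`, `"group_lasso"` or `"sparse_group_lasso"`.
#' @param lambda_pen Penalty strength (lambda).
#' @param alpha Convex mix of the sparse group lasso: 0 recovers the group
#'   lasso, 1 the plain lasso.
#' @param mode `"N"` uses both branches; `"UCN_only"` forces
#'   `lambda_cn = 0`, reproducing the uncommon-node-only baseline loss.
#' @param group_weight Group-size weighting of the group-lasso norm terms:
#'   `"sqrt_p"` (the standard convention, default) or `"p"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_cn = 1, lambda_ucn = 1,
                        penalty = c("none", "group_lasso",
                                    "sparse_group_lasso"),
                        lambda_pen = 1e-3, alpha = 0.5,
                        mode = c("N", "UCN_only"),
                        group_weight = c("sqrt_p", "p")) {
  penalty <- match.arg(penalty)
  mode <- match.arg(mode)
  group_weight <- match.arg(group_weight)
  if (lambda_cn < 0 || lambda_ucn < 0 || lambda_pen < 0) {
    stop("loss weights must be non-negative")
  }
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (mode == "UCN_only") lambda_cn <- 0
  structure(list(lambda_cn = lambda_cn, lambda_ucn = lambda_ucn,
                 penalty = penalty, lambda_pen = lambda_pen, alpha = alpha,
                 mode = mode, group_weight = group_weight),
            class = "loss_config")
}

#' Mean-square affinity loss
#'
#' Sum of squared residuals over the supplied predictions (both compounds of
#' every pair in a batch); callers apply the batch-mean over pairs.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) < 1) {
    stop("'predictions' and 'targets' must have equal length >= 1")
  }
  sum((targets - predictions)^2)
}

#' Node-level pair loss
#'
#' The squared residual of the decomposed activity-difference prediction:
#' `(lambda_cn * delta_cn + lambda_ucn * delta_ucn - delta_y)^2` per pair,
#' summed. With `mode = "UCN_only"` (`lambda_cn = 0`) it reduces to the
#' uncommon-branch baseline `(lambda_ucn * delta_ucn - delta_y)^2`.
#'
#' @param delta_cn,delta_ucn Predicted common / uncommon activity-difference
#'   components (vectors over pairs).
#' @param delta_y True activity differences.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar (sum over supplied pairs).
#' @export
node_pair_loss <- function(delta_cn, delta_ucn, delta_y, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  r <- cfg$lambda_cn * delta_cn + cfg$lambda_ucn * delta_ucn - delta_y
  sum(r^2)
}

.group_w <- function(p, group_weight) {
  if (group_weight == "sqrt_p") sqrt(p) else p
}

#' Group lasso penalty on the subgraph heads
#'
#' `lambda * (w(p_cn) * ||beta_cn||_2 + w(p_ucn) * ||beta_ucn||_2)` with
#' `w = sqrt` by default; biases are never penalized.
#'
#' @param beta_cn,beta_ucn Weight vectors of the two subgraph heads.
#' @param lambda_pen Penalty strength.
#' @param group_weight `"sqrt_p"` or `"p"` group-size weighting.
#' @return Non-negative scalar.
#' @export
group_lasso_penalty <- function(beta_cn, beta_ucn, lambda_pen,
                                group_weight = "sqrt_p") {
  lambda_pen * (.group_w(length(beta_cn), group_weight) * sqrt(sum(beta_cn^2)) +
                .group_w(length(beta_ucn), group_weight) * sqrt(sum(beta_ucn^2)))
}

#' Sparse group lasso penalty
#'
#' `(1 - alpha) * group_lasso + alpha * lambda * ||beta||_1` over the
#' concatenated head weights; `alpha = 0` recovers the group lasso and
#' `alpha = 1` the lasso.
#'
#' @inheritParams group_lasso_penalty
#' @param alpha Mix parameter in \[0, 1\].
#' @return Non-negative scalar.
#' @export
sparse_group_lasso_penalty <- function(beta_cn, beta_ucn, lambda_pen,
                                       alpha = 0.5, group_weight = "sqrt_p") {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  (1 - alpha) * group_lasso_penalty(beta_cn, beta_ucn, lambda_pen,
                                    group_weight) +
    alpha * lambda_pen * sum(abs(c(beta_cn, beta_ucn)))
}

.penalty_value <- function(params, cfg) {
  switch(cfg$penalty,
    none = 0,
    group_lasso = group_lasso_penalty(params$beta_cn, params$beta_ucn,
                                      cfg$lambda_pen, cfg$group_weight),
    sparse_group_lasso = sparse_group_lasso_penalty(
      params$beta_cn, params$beta_ucn, cfg$lambda_pen, cfg$alpha,
      cfg$group_weight))
}

# subgradient of the penalty w.r.t. each head weight vector (0 at 0)
.penalty_grad <- function(params, cfg) {
  z <- list(beta_cn = numeric(length(params$beta_cn)),
            beta_ucn = numeric(length(params$beta_ucn)))
  if (cfg$penalty == "none") return(z)
  gl_part <- function(beta) {
    nb <- sqrt(sum(beta^2))
    if (nb == 0) return(numeric(length(beta)))
    .group_w(length(beta), cfg$group_weight) * beta / nb
  }
  scale_gl <- if (cfg$penalty == "group_lasso") 1 else (1 - cfg$alpha)
  g_cn <- cfg$lambda_pen * scale_gl * gl_part(params$beta_cn)
  g_ucn <- cfg$lambda_pen * scale_gl * gl_part(params$beta_ucn)
  if (cfg$penalty == "sparse_group_lasso") {
    g_cn <- g_cn + cfg$alpha * cfg$lambda_pen * sign(params$beta_cn)
    g_ucn <- g_ucn + cfg$alpha * cfg$lambda_pen * sign(params$beta_ucn)
  }
  list(beta_cn = g_cn, beta_ucn = g_ucn)
}

#' Composite training objective
#'
#' Batch-mean of the affinity MSE (per-pair sum over both compounds) plus
#' the batch-mean node-level loss plus the structured-sparsity penalty (the
#' penalty is not batch-scaled). Optionally also returns hand-derived
#' gradients with respect to every model parameter.
#'
#' @param state A `model_state`.
#' @param batch A pair batch (internal structure from the training loop).
#' @param loss_cfg A [loss_config()].
#' @param training Use batch statistics in batch norm (training mode).
#' @param with_grads Also compute parameter gradients.
#' @param fwd Optional precomputed forward pass.
#' @return List with `value`, `breakdown` (mse, node, penalty), `fwd`, and
#'   (if requested) `grads`.
#' @export
total_objective <- function(state, batch, loss_cfg = loss_config(),
                            training = TRUE, with_grads = FALSE,
                            fwd = NULL) {
  if (is.null(fwd)) {
    fwd <- forward_batch(state, batch, training = training,
                         update_bn = FALSE)
  }
  P <- batch$n_pairs
  stopifnot(P >= 1)
  mse <- mse_loss(fwd$yhat, batch$y) / P
  resid <- loss_cfg$lambda_cn * fwd$delta_cn +
    loss_cfg$lambda_ucn * fwd$delta_ucn - batch$delta_y
  node <- sum(resid^2) / P
  pen <- .penalty_value(state$params, loss_cfg)
  value <- mse + node + pen
  if (!is.finite(value)) {
    bad <- c(mse = mse, node = node, penalty = pen)
    stop(sprintf("non-finite objective term(s): %s",
                 paste(names(bad)[!is.finite(bad)], collapse = ", ")))
  }
  out <- list(value = value,
              breakdown = c(mse = mse, node = node, penalty = pen),
              fwd = fwd)
  if (with_grads) {
    dyhat <- 2 * (fwd$yhat - batch$y) / P
    ddelta_cn <- 2 * resid * loss_cfg$lambda_cn / P
    ddelta_ucn <- 2 * resid * loss_cfg$lambda_ucn / P
    bk <- backward_batch(state, batch, fwd, dyhat, ddelta_cn, ddelta_ucn)
    pg <- .penalty_grad(state$params, loss_cfg)
    bk$grads$beta_cn <- bk$grads$beta_cn + pg$beta_cn
    bk$grads$beta_ucn <- bk$grads$beta_ucn + pg$beta_ucn
    out$grads <- bk$grads
  }
  out
}
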