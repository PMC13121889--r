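#' Training schedule
#'
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Pairs per minibatch.
#' @param lr Initial learning rate of the Adam optimizer.
#' @param plateau_factor Multiplier applied to the learning rate when the
#'   validation RMSE has not improved for `plateau_patience` epochs.
#' @param plateau_patience,early_stop_patience Patience in epochs for the
#'   learning-rate decay and for early stopping.
#' @param min_lr Learning-rate floor.
#' @param improve_tol Minimum absolute validation-RMSE decrease that counts
#'   as an improvement for both patience rules.
#' @param seed Seed governing parameter initialization and batch shuffling.
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(max_epochs = 300, batch_size = 32, lr = 1e-3,
                           plateau_factor = 0.5, plateau_patience = 10,
                           early_stop_patience = 30, min_lr = 1e-5,
                           improve_tol = 1e-4, seed = 1) {
  stopifnot(plateau_patience >= 1, early_stop_patience >= 1,
            plateau_factor > 0, plateau_factor < 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_lr = min_lr, improve_tol = improve_tol,
                 seed = as.integer(seed)),
            class = "train_schedule")
}

.activities_of <- function(dataset) {
  stats::setNames(dataset$compounds$activity, dataset$compounds$compound_id)
}

.pair_rows <- function(dataset, pair_ids) {
  dataset$pairs[match(pair_ids, dataset$pairs$pair_id), , drop = FALSE]
}

#' Inference-mode predictions for a set of pairs
#'
#' Runs the pair forward pass (pair masks, running batch-norm statistics)
#' and returns per-compound predicted and observed pIC50 — each pair
#' contributes its two compounds — plus the decomposed activity-difference
#' predictions.
#'
#' @param state A trained `model_state`.
#' @param dataset An `ac_pair_dataset`.
#' @param pair_ids Pair ids to predict.
#' @return List with `yhat`, `y` (length 2 x pairs, order i then j per
#'   pair), `delta_cn`, `delta_ucn`, `delta_y`, `pair_ids`.
#' @export
predict_pair_batch <- function(state, dataset, pair_ids) {
  rows <- .pair_rows(dataset, pair_ids)
  batch <- build_pair_batch(rows, dataset$masks, dataset$graphs,
                            .activities_of(dataset))
  fwd <- forward_batch(state, batch, training = FALSE)
  list(batch = batch, fwd = fwd, yhat = fwd$yhat, y = batch$y,
       delta_cn = fwd$delta_cn, delta_ucn = fwd$delta_ucn,
       delta_y = batch$delta_y, pair_ids = rows$pair_id)
}

#' Predicted affinity of a single compound
#'
#' Standalone prediction outside a pair context: both masked branches see
#' the whole graph (all-ones masks).
#'
#' @param state A trained `model_state`.
#' @param graph A featurized `molecular_graph`.
#' @return Scalar predicted pIC50.
#' @export
predict_affinity <- function(state, graph) {
  batch <- build_single_batch(graph)
  forward_batch(state, batch, training = FALSE)$yhat[1]
}

.adam_new <- function(params) {
  z <- lapply(params, function(p) { p[] <- 0; p })
  list(m = z, v = z, t = 0L)
}

# Adam over the named parameter list, in place
.adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(opt = opt, params = params)
}

#' Train the model on activity-cliff pairs
#'
#' Minibatch Adam on the composite objective with a plateau learning-rate
#' schedule and early stopping, both driven by validation RMSE. Fully
#' reproducible given the schedule seed.
#'
#' @param dataset An `ac_pair_dataset`.
#' @param train_pair_ids,val_pair_ids Pair ids for training and validation;
#'   the validation set must be non-empty (early stopping is undefined
#'   otherwise).
#' @param config A [model_config()].
#' @param loss_cfg A [loss_config()].
#' @param schedule A [train_schedule()].
#' @return A `train_result`: `state` (best by validation RMSE), `history`
#'   (per-epoch train loss, validation RMSE, learning rate), `best_epoch`,
#'   `stop_reason`.
#' @export
train_model <- function(dataset, train_pair_ids, val_pair_ids,
                        config = model_config(), loss_cfg = loss_config(),
                        schedule = train_schedule()) {
  if (length(train_pair_ids) == 0) stop("empty training pair set")
  if (length(val_pair_ids) == 0) stop("empty validation pair set")
  acts <- .activities_of(dataset)
  state <- init_model_state(config, schedule$seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_rmse = numeric(0), lr = numeric(0))
  if (schedule$max_epochs == 0L) {
    return(structure(list(state = state, history = history,
                          best_epoch = NA_integer_,
                          stop_reason = "max_epochs"),
                     class = "train_result"))
  }
  train_df <- .pair_rows(dataset, train_pair_ids)
  train_rows <- list(pair_id = train_df$pair_id, i = train_df$i,
                     j = train_df$j, delta_y = train_df$delta_y)
  val_rows <- .pair_rows(dataset, val_pair_ids)
  val_batch <- build_pair_batch(val_rows, dataset$masks, dataset$graphs, acts)

  opt <- .adam_new(state$params)
  lr <- schedule$lr
  best <- list(rmse = Inf, state = state, epoch = 0L)
  plateau_wait <- 0L; stop_wait <- 0L
  stop_reason <- "max_epochs"
  n_train <- length(train_rows$pair_id)

  rng <- .derive_seed(schedule$seed, 7919L)
  withr::with_seed(rng, {
    for (epoch in seq_len(schedule$max_epochs)) {
      ord <- sample.int(n_train)
      losses <- numeric(0)
      for (start in seq(1L, n_train, by = schedule$batch_size)) {
        idx <- ord[start:min(start + schedule$batch_size - 1L, n_train)]
        batch <- build_pair_batch(lapply(train_rows, `[`, idx),
                                  dataset$masks, dataset$graphs, acts)
        fwd <- forward_batch(state, batch, training = TRUE, update_bn = TRUE)
        state$bn_mean <- fwd$bn_mean
        state$bn_var <- fwd$bn_var
        obj <- total_objective(state, batch, loss_cfg, training = TRUE,
                               with_grads = TRUE, fwd = fwd)
        if (!is.finite(obj$value)) {
          stop_reason <- "divergence"
          break
        }
        step <- .adam_step(opt, state$params, obj$grads, lr)
        opt <- step$opt
        state$params <- step$params
        losses <- c(losses, obj$value)
      }
      if (stop_reason == "divergence") break

      vfwd <- forward_batch(state, val_batch, training = FALSE)
      val_rmse <- sqrt(mean((vfwd$yhat - val_batch$y)^2))
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_rmse = val_rmse,
        lr = lr))
      if (val_rmse < best$rmse - schedule$improve_tol) {
        best <- list(rmse = val_rmse, state = state, epoch = epoch)
        plateau_wait <- 0L; stop_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        stop_wait <- stop_wait + 1L
        if (plateau_wait >= schedule$plateau_patience) {
          lr <- max(lr * schedule$plateau_factor, schedule$min_lr)
          plateau_wait <- 0L
        }
        if (stop_wait >= schedule$early_stop_patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  structure(list(state = best$state, history = history,
                 best_epoch = best$epoch, best_val_rmse = best$rmse,
                 stop_reason = stop_reason),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result: %d epochs, best val RMSE %.4f @ epoch %d (%s)>\n",
              nrow(x$history), x$best_val_rmse, x$best_epoch, x$stop_reason))
  invisible(x)
}

#' k-fold cross-validation driver
#'
#' Runs `k` independent seeded 70/10/20 compound-level splits (pairs follow
#' their first ligand), trains a model per fold, and evaluates RMSE and
#' Pearson correlation on the test pairs of each fold. Re-checks the
#' first-ligand leakage rule on every fold.
#'
#' @param dataset An `ac_pair_dataset` (must have passed the minimum-pair
#'   rule).
#' @param k Number of folds.
#' @param config,loss_cfg,schedule Model, loss and schedule configurations.
#' @param seed Master seed for the splits (fold seeds derived).
#' @param fractions Train/val/test compound fractions.
#' @return A `cv_result`: `folds` (per-fold `train_result`, metrics, split),
#'   `metrics` (per-fold data frame) and `aggregate` (mean, sd and
#'   pair-count-weighted mean of RMSE/PCC).
#' @export
cross_validate <- function(dataset, k = 5, config = model_config(),
                           loss_cfg = loss_config(),
                           schedule = train_schedule(), seed = 1,
                           fractions = c(0.7, 0.1, 0.2)) {
  if (nrow(dataset$pairs) == 0) stop("empty pair dataset")
  splits <- make_fold_splits(dataset$compounds, dataset$pairs, k = k,
                             fractions = fractions, seed = seed)
  folds <- list()
  metrics <- data.frame()
  for (sp in splits) {
    leak <- intersect(dataset$pairs$i[dataset$pairs$pair_id %in% sp$test_pairs],
                      sp$train_compounds)
    stopifnot(length(leak) == 0)
    if (length(sp$test_pairs) == 0) {
      warning(sprintf("fold %d has no test pairs; skipped", sp$fold))
      next
    }
    sched <- schedule
    sched$seed <- .derive_seed(schedule$seed, sp$fold)
    tr <- train_model(dataset, sp$train_pairs, sp$val_pairs, config,
                      loss_cfg, sched)
    pred <- predict_pair_batch(tr$state, dataset, sp$test_pairs)
    rm <- regression_metrics(pred$yhat, pred$y)
    folds[[length(folds) + 1L]] <- list(split = sp, result = tr,
                                        test_pred = pred, metrics = rm)
    metrics <- rbind(metrics, data.frame(
      fold = sp$fold, n_test_pairs = length(sp$test_pairs),
      rmse = rm["rmse"], pcc = rm["pcc"], row.names = NULL))
  }
  w <- metrics$n_test_pairs / sum(metrics$n_test_pairs)
  aggregate <- list(
    rmse_mean = mean(metrics$rmse), rmse_sd = stats::sd(metrics$rmse),
    pcc_mean = mean(metrics$pcc), pcc_sd = stats::sd(metrics$pcc),
    rmse_weighted = sum(w * metrics$rmse),
    pcc_weighted = sum(w * metrics$pcc))
  structure(list(folds = folds, metrics = metrics, aggregate = aggregate),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_result: %d folds, RMSE %.4f +/- %.4f, PCC %.4f +/- %.4f>\n",
              nrow(x$metrics), a$rmse_mean, a$rmse_sd, a$pcc_mean, a$pcc_sd))
  invisible(x)
}
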