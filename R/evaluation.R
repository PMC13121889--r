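#' Regression metrics
#'
#' @param yhat,y Predicted and observed pIC50 vectors.
#' @return Named vector `c(rmse, pcc)`. With zero-variance predictions the
#'   Pearson correlation is undefined and reported as `NA` with a warning.
#' @export
regression_metrics <- function(yhat, y) {
  stopifnot(length(yhat) == length(y), length(y) >= 1)
  rmse <- sqrt(mean((y - yhat)^2))
  pcc <- NA_real_
  if (length(y) >= 2) {
    if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
      warning("zero-variance input: Pearson correlation undefined")
    } else {
      pcc <- stats::cor(yhat, y)
    }
  }
  c(rmse = rmse, pcc = pcc)
}

#' Global direction of a pair's attributions
#'
#' Scores 1 when the difference of mean uncommon-atom attributions between
#' the two compounds of a cliff pair has the same sign as the true activity
#' difference, else 0. An exact tie cannot preserve the direction of a
#' nonzero activity difference and scores 0.
#'
#' @param delta_y True activity difference (must be nonzero).
#' @param scores_i,scores_j Node-score vectors of the two compounds.
#' @param mask_uncommon_i,mask_uncommon_j Binary uncommon-atom masks; at
#'   least one side must have an uncommon atom. A side without uncommon
#'   atoms contributes mean attribution 0.
#' @return 0 or 1.
#' @export
global_direction <- function(delta_y, scores_i, scores_j,
                             mask_uncommon_i, mask_uncommon_j) {
  if (!is.finite(delta_y) || delta_y == 0) {
    stop("global direction undefined: delta_y is zero (not a cliff)")
  }
  if (sum(mask_uncommon_i) == 0 && sum(mask_uncommon_j) == 0) {
    stop("global direction undefined: no uncommon atoms on either side")
  }
  r_i <- if (sum(mask_uncommon_i) > 0) {
    mean(scores_i[mask_uncommon_i > 0])
  } else 0
  r_j <- if (sum(mask_uncommon_j) > 0) {
    mean(scores_j[mask_uncommon_j > 0])
  } else 0
  as.numeric(sign(r_i - r_j) == sign(delta_y))
}

#' Mean global direction across MCS thresholds
#'
#' At each threshold t, averages the global-direction score over the pairs
#' whose shared fraction reaches t on both sides. Pair sets are nested:
#' raising the threshold never adds pairs. Empty subsets give `NA`.
#'
#' @param dataset An `ac_pair_dataset`.
#' @param maps Named list of node-score vectors keyed by compound id (from
#'   [attribute_all()]).
#' @param pair_ids Pairs to evaluate (default: all).
#' @param thresholds MCS thresholds (default 0.50 to 0.95 in steps of 0.05).
#' @return Named numeric vector: threshold -> mean gdir.
#' @export
gdir_curve <- function(dataset, maps, pair_ids = NULL,
                       thresholds = seq(0.50, 0.95, by = 0.05)) {
  pr <- dataset$pairs
  if (!is.null(pair_ids)) pr <- pr[pr$pair_id %in% pair_ids, , drop = FALSE]
  g <- vapply(seq_len(nrow(pr)), function(r) {
    pid <- pr$pair_id[r]
    mk <- dataset$masks[[pid]]
    global_direction(pr$delta_y[r], maps[[pr$i[r]]], maps[[pr$j[r]]],
                     mk$mask_uncommon_i, mk$mask_uncommon_j)
  }, numeric(1))
  out <- vapply(thresholds, function(t) {
    keep <- pr$shared_fraction_i >= t & pr$shared_fraction_j >= t
    if (!any(keep)) NA_real_ else mean(g[keep])
  }, numeric(1))
  names(out) <- sprintf("%.2f", thresholds)
  out
}

# collect (score, label) for every uncommon atom of the chosen pairs
gather_uncommon_atoms <- function(dataset, maps, pair_ids = NULL) {
  pr <- dataset$pairs
  if (!is.null(pair_ids)) pr <- pr[pr$pair_id %in% pair_ids, , drop = FALSE]
  sc <- list(); lb <- list()
  for (r in seq_len(nrow(pr))) {
    pid <- pr$pair_id[r]
    col <- dataset$colorings[[pid]]
    for (side in c("i", "j")) {
      cid <- pr[[side]][r]
      labels <- col[[paste0("labels_", side)]]
      keep <- labels != 0
      if (any(keep)) {
        sc[[length(sc) + 1L]] <- maps[[cid]][keep]
        lb[[length(lb) + 1L]] <- labels[keep]
      }
    }
  }
  data.frame(score = unlist(sc), label = unlist(lb))
}

#' Node-coloring classification metrics
#'
#' Over uncommon atoms only (ground-truth labels +1/-1): the predicted class
#' is the sign of the attribution score; zero scores match neither class and
#' count as misclassified. Accuracy and macro-F1 over the two classes.
#'
#' @param dataset,maps,pair_ids As in [gdir_curve()].
#' @return Named vector `c(accuracy, f1)`; `NA` with a warning when the
#'   evaluation set has no uncommon atoms.
#' @export
coloring_metrics <- function(dataset, maps, pair_ids = NULL) {
  du <- gather_uncommon_atoms(dataset, maps, pair_ids)
  if (nrow(du) == 0) {
    warning("no uncommon atoms in the evaluation set")
    return(c(accuracy = NA_real_, f1 = NA_real_))
  }
  pred <- sign(du$score)
  acc <- mean(pred == du$label)
  f1_of <- function(cls) {
    tp <- sum(pred == cls & du$label == cls)
    fp <- sum(pred == cls & du$label != cls)
    fn <- sum(pred != cls & du$label == cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  c(accuracy = acc, f1 = mean(c(f1_of(1), f1_of(-1))))
}

#' Spearman alignment of attributions with signed ground truth
#'
#' Rank correlation between attribution scores and the +1/-1 labels on
#' uncommon atoms (ties mid-ranked).
#'
#' @param dataset,maps,pair_ids As in [gdir_curve()].
#' @return Scalar rho, or `NA` with a warning when fewer than 3 uncommon
#'   atoms or only one class is present.
#' @export
spearman_alignment <- function(dataset, maps, pair_ids = NULL) {
  du <- gather_uncommon_atoms(dataset, maps, pair_ids)
  .spearman_sl(du$score, du$label)
}

.spearman_sl <- function(score, label) {
  if (length(label) < 3 || length(unique(label)) < 2) {
    warning("Spearman alignment undefined: need >= 3 atoms with both classes")
    return(NA_real_)
  }
  stats::cor(score, label, method = "spearman")
}

.auroc_midrank <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Directional AUROC of atom attributions
#'
#' AUROC computed separately for activity-increasing atoms (label +1,
#' raw scores) and activity-decreasing atoms (label -1, negated scores), so
#' that higher is better for both. Midrank (Mann-Whitney) estimator.
#'
#' @param dataset,maps,pair_ids As in [gdir_curve()].
#' @return Named vector `c(auroc_pos, auroc_neg)`; `NA` when a class is
#'   absent.
#' @export
directional_auroc <- function(dataset, maps, pair_ids = NULL) {
  du <- gather_uncommon_atoms(dataset, maps, pair_ids)
  c(auroc_pos = .auroc_midrank(du$score, du$label == 1),
    auroc_neg = .auroc_midrank(-du$score, du$label == -1))
}

# drop each undirected bond independently with probability `rate`
# (topology-only perturbation; node features are left untouched)
drop_graph_edges <- function(graph, rate) {
  m <- nrow(graph$bonds)
  if (m == 0 || rate <= 0) return(graph)
  keep <- stats::runif(m) >= rate
  graph$bonds <- graph$bonds[keep, , drop = FALSE]
  rows <- as.vector(rbind(2 * which(keep) - 1, 2 * which(keep)))
  graph$edge_features <- graph$edge_features[rows, , drop = FALSE]
  graph$edge_index <- graph$edge_index[rows, , drop = FALSE]
  graph$edge_key <- graph$edge_key[rows]
  graph
}

#' Attribution stability under edge dropout
#'
#' Recomputes the Spearman alignment after dropping each bond independently
#' with the given probabilities (both directed edges of a dropped bond are
#' removed; isolated atoms are allowed). Rate 0 reproduces the unperturbed
#' value exactly.
#'
#' @param state A trained `model_state`.
#' @param dataset An `ac_pair_dataset`.
#' @param method Attribution method.
#' @param pair_ids Pairs to evaluate (default: all).
#' @param rates Dropout probabilities (default 0, 0.05, 0.10, 0.20, 0.30).
#' @param seed Seed for the dropout draws.
#' @param options Attribution options.
#' @return Named numeric vector: rate -> Spearman rho.
#' @export
perturbation_stability <- function(state, dataset,
                                   method = "gradient_x_input",
                                   pair_ids = NULL,
                                   rates = c(0, 0.05, 0.10, 0.20, 0.30),
                                   seed = 1, options = list()) {
  cids <- unique(c(dataset$pairs$i, dataset$pairs$j))
  if (!is.null(pair_ids)) {
    pr <- dataset$pairs[dataset$pairs$pair_id %in% pair_ids, ]
    cids <- unique(c(pr$i, pr$j))
  }
  out <- vapply(seq_along(rates), function(k) {
    rate <- rates[k]
    maps <- withr::with_seed(.derive_seed(seed, k), {
      ms <- lapply(cids, function(cid) {
        g <- drop_graph_edges(dataset$graphs[[cid]], rate)
        m <- attribute(state, g, method, options)
        redistribute_edge_to_nodes(m, g)$node_scores
      })
      names(ms) <- cids
      ms
    })
    suppressWarnings(spearman_alignment(dataset, maps, pair_ids))
  }, numeric(1))
  names(out) <- sprintf("%g", rates)
  out
}

#' Paired significance tests
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test over paired metric
#' vectors (e.g. per-fold or per-target scores). Zero differences are
#' dropped for the Wilcoxon test (the original procedure); the exact null
#' distribution is used for n <= 25 untied differences, the normal
#' approximation above.
#'
#' @param metric_a,metric_b Equal-length numeric vectors (length >= 3).
#' @return Named vector `c(t_p, wilcoxon_p)`. With identical inputs the
#'   t-test p-value is 1 by convention and the Wilcoxon p is `NA`.
#' @export
paired_tests <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 3)
  d <- metric_a - metric_b
  t_p <- if (stats::sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::t.test(metric_a, metric_b, paired = TRUE)$p.value
  }
  nz <- d[d != 0]
  w_p <- if (length(nz) == 0) {
    NA_real_
  } else {
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    suppressWarnings(stats::wilcox.test(nz, exact = exact)$p.value)
  }
  c(t_p = t_p, wilcoxon_p = w_p)
}

#' Full interpretability evaluation of a trained model
#'
#' Computes regression metrics on the given pairs plus, per attribution
#' method, the gdir-by-threshold curve, coloring accuracy/F1, Spearman
#' alignment, directional AUROC and the edge-dropout stability curve.
#'
#' @param state A trained `model_state`.
#' @param dataset An `ac_pair_dataset`.
#' @param pair_ids Pairs to evaluate (default: all).
#' @param methods Attribution methods to evaluate.
#' @param thresholds MCS thresholds for the gdir curve.
#' @param rates Edge-dropout rates for the stability curve.
#' @param seed Seed for the stability perturbations.
#' @param options Attribution options.
#' @return An `evaluation_report` list.
#' @export
evaluate_model <- function(state, dataset, pair_ids = NULL,
                           methods = c("cam", "grad_cam",
                                       "gradient_x_input",
                                       "integrated_gradients"),
                           thresholds = seq(0.50, 0.95, by = 0.05),
                           rates = c(0, 0.05, 0.10, 0.20, 0.30),
                           seed = 1, options = list()) {
  if (is.null(pair_ids)) pair_ids <- dataset$pairs$pair_id
  pred <- predict_pair_batch(state, dataset, pair_ids)
  rm <- suppressWarnings(regression_metrics(pred$yhat, pred$y))
  cids <- unique(c(.pair_rows(dataset, pair_ids)$i,
                   .pair_rows(dataset, pair_ids)$j))
  per_method <- lapply(methods, function(m) {
    maps <- attribute_all(state, dataset, m, options, compound_ids = cids)
    list(method = m,
         gdir = gdir_curve(dataset, maps, pair_ids, thresholds),
         coloring = suppressWarnings(coloring_metrics(dataset, maps, pair_ids)),
         spearman = suppressWarnings(spearman_alignment(dataset, maps, pair_ids)),
         auroc = directional_auroc(dataset, maps, pair_ids),
         stability = perturbation_stability(state, dataset, m, pair_ids,
                                            rates, seed, options))
  })
  names(per_method) <- methods
  structure(list(rmse = rm[["rmse"]], pcc = rm[["pcc"]],
                 methods = per_method, pair_ids = pair_ids,
                 thresholds = thresholds, rates = rates),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d pairs, RMSE %.4f, PCC %.4f>\n",
              length(x$pair_ids), x$rmse, x$pcc))
  for (m in names(x$methods)) {
    pm <- x$methods[[m]]
    cat(sprintf("  %-20s gdir@0.50 %.3f  acc %.3f  rho %.3f  AUROC+ %.3f\n",
                m, pm$gdir[["0.50"]], pm$coloring[["accuracy"]],
                pm$spearman, pm$auroc[["auroc_pos"]]))
  }
  invisible(x)
}
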