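#' Maximum common substructure between two molecular graphs
#'
#' Branch-and-bound search for the largest connected common substructure
#' under element-exact atom matching and bond-order-exact bond matching
#' (optionally requiring ring bonds to match only ring bonds). Among
#' equally large solutions the one with most matched bonds is preferred, and
#' remaining ties resolve to the first solution in canonical (input) atom
#' order, so the result is deterministic.
#'
#' @param g_i,g_j Featurized `molecular_graph` objects.
#' @param timeout_s Wall-clock budget in seconds; on timeout the result is
#'   flagged `timed_out` (callers exclude such pairs rather than crash).
#' @param match_ring_bonds If `TRUE` (default) ring bonds only match ring
#'   bonds.
#' @return List with integer vectors `map_i`, `map_j` (matched atom indices,
#'   parallel), `n_atoms`, `n_bonds` and logical `timed_out`.
#' @export
find_mcs <- function(g_i, g_j, timeout_s = 10, match_ring_bonds = TRUE) {
  stopifnot(inherits(g_i, "molecular_graph"), inherits(g_j, "molecular_graph"))
  syms <- unique(c(g_i$atoms$symbol, g_j$atoms$symbol))
  elem1 <- match(g_i$atoms$symbol, syms)
  elem2 <- match(g_j$atoms$symbol, syms)
  adj <- function(g) {
    A <- matrix(0L, g$n_atoms, g$n_atoms)
    if (nrow(g$bonds) > 0L) {
      ord <- match(g$bonds$order, BOND_ORDERS)
      lab <- as.integer(ord * 10L +
                          if (match_ring_bonds) as.integer(g$bonds$ring) else 0L)
      A[cbind(g$bonds$a, g$bonds$b)] <- lab
      A[cbind(g$bonds$b, g$bonds$a)] <- lab
    }
    A
  }
  res <- mcs_search_cpp(as.integer(elem1), adj(g_i),
                        as.integer(elem2), adj(g_j), timeout_s)
  list(map_i = as.integer(res$map_i), map_j = as.integer(res$map_j),
       n_atoms = length(res$map_i), n_bonds = res$n_bonds,
       timed_out = isTRUE(res$timed_out))
}

#' Common/uncommon atom masks from an MCS mapping
#'
#' Atoms covered by the mapping are common; all others are uncommon. The two
#' masks of each compound always form an exact partition of its atoms.
#'
#' @param mapping Result of [find_mcs()].
#' @param g_i,g_j The two molecular graphs.
#' @return List with binary vectors `mask_common_i`, `mask_uncommon_i`,
#'   `mask_common_j`, `mask_uncommon_j` and `shared_fraction_i`,
#'   `shared_fraction_j` (matched heavy atoms / heavy atoms).
#' @export
compute_masks <- function(mapping, g_i, g_j) {
  ci <- integer(g_i$n_atoms)
  cj <- integer(g_j$n_atoms)
  ci[mapping$map_i] <- 1L
  cj[mapping$map_j] <- 1L
  list(mask_common_i = ci, mask_uncommon_i = 1L - ci,
       mask_common_j = cj, mask_uncommon_j = 1L - cj,
       shared_fraction_i = sum(ci) / g_i$n_atoms,
       shared_fraction_j = sum(cj) / g_j$n_atoms)
}

#' Is a compound pair an activity cliff?
#'
#' @param y_i,y_j pIC50 values (log10 units).
#' @param threshold Minimum absolute activity difference in log units;
#'   the boundary is inclusive ("at least" 1 log unit by default).
#' @return `TRUE` iff `|y_i - y_j| >= threshold`.
#' @export
is_activity_cliff <- function(y_i, y_j, threshold = 1.0) {
  stopifnot(is.finite(y_i), is.finite(y_j))
  abs(y_i - y_j) >= threshold
}

#' Ground-truth atom coloring for an activity-cliff pair
#'
#' Common (scaffold) atoms are labelled 0. Uncommon atoms of the
#' higher-activity compound are labelled +1 and those of the lower-activity
#' compound -1, following the MCS-derived proxy ground truth used for
#' attribution benchmarking.
#'
#' @param pair A list with `delta_y` and the four masks (one row of an
#'   [assemble_pair_dataset()] result, or any list with those fields).
#' @return List with integer vectors `labels_i`, `labels_j` in \{-1, 0, +1\}.
#' @export
ground_truth_coloring <- function(pair) {
  if (!is.finite(pair$delta_y) || pair$delta_y == 0) {
    stop("ground-truth coloring undefined: delta_y is zero (not a cliff)")
  }
  s <- sign(pair$delta_y)
  list(labels_i = as.integer(pair$mask_uncommon_i * s),
       labels_j = as.integer(pair$mask_uncommon_j * -s))
}

#' Assemble the activity-cliff pair dataset
#'
#' Enumerates compound pairs (ordered by the compound table: the earlier
#' compound is the pair's first ligand; the reverse orientation is not
#' added), computes the MCS for each, and keeps pairs whose shared fraction
#' reaches `min_shared_fraction` on BOTH molecules and whose absolute
#' activity difference reaches `cliff_threshold`. A dataset with fewer than
#' `min_pairs` qualifying pairs is rejected (empty result with a diagnostic).
#'
#' @param compounds Data frame with `compound_id`, `smiles`, `activity`.
#' @param graphs Optional named list of featurized graphs (built if absent).
#' @param min_shared_fraction MCS threshold applied to both compounds.
#' @param cliff_threshold Minimum |delta pIC50| (inclusive).
#' @param min_pairs Minimum number of qualifying pairs for a usable dataset.
#' @param timeout_s Per-pair MCS budget; timed-out pairs are excluded and
#'   counted in the diagnostics.
#' @return An `ac_pair_dataset`: `pairs` (data frame with pair_id, i, j,
#'   delta_y, shared fractions), `masks` and `colorings` (lists keyed by
#'   pair_id), `compounds`, and `diagnostics`.
#' @export
assemble_pair_dataset <- function(compounds, graphs = NULL,
                                  min_shared_fraction = 0.5,
                                  cliff_threshold = 1.0, min_pairs = 50,
                                  timeout_s = 10) {
  n <- nrow(compounds)
  diag <- list(n_compounds = n, n_candidates = 0L, mcs_timeouts = 0L,
               rejected = FALSE, reason = NULL)
  empty <- function(reason) {
    diag$rejected <<- TRUE; diag$reason <<- reason
    message("pair dataset rejected: ", reason)
    structure(list(pairs = data.frame(), masks = list(), colorings = list(),
                   compounds = compounds, graphs = graphs,
                   diagnostics = diag),
              class = "ac_pair_dataset")
  }
  if (n < 2L) return(empty("fewer than 2 compounds"))
  if (is.null(graphs)) graphs <- build_graphs(compounds)

  rows <- list(); masks <- list(); colorings <- list()
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      dy <- compounds$activity[a] - compounds$activity[b]
      if (!is_activity_cliff(compounds$activity[a], compounds$activity[b],
                             cliff_threshold)) next
      diag$n_candidates <- diag$n_candidates + 1L
      gi <- graphs[[compounds$compound_id[a]]]
      gj <- graphs[[compounds$compound_id[b]]]
      mcs <- find_mcs(gi, gj, timeout_s = timeout_s)
      if (mcs$timed_out) {
        diag$mcs_timeouts <- diag$mcs_timeouts + 1L
        next
      }
      mk <- compute_masks(mcs, gi, gj)
      if (mk$shared_fraction_i < min_shared_fraction ||
          mk$shared_fraction_j < min_shared_fraction) next
      pid <- sprintf("%s|%s", compounds$compound_id[a], compounds$compound_id[b])
      rows[[pid]] <- data.frame(
        pair_id = pid, i = compounds$compound_id[a],
        j = compounds$compound_id[b], delta_y = dy,
        shared_fraction_i = mk$shared_fraction_i,
        shared_fraction_j = mk$shared_fraction_j,
        stringsAsFactors = FALSE)
      masks[[pid]] <- mk
      colorings[[pid]] <- ground_truth_coloring(c(mk, list(delta_y = dy)))
    }
  }
  if (length(rows) < min_pairs) {
    return(empty(sprintf("only %d qualifying pair(s), need >= %d",
                         length(rows), min_pairs)))
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, masks = masks, colorings = colorings,
                 compounds = compounds, graphs = graphs, diagnostics = diag),
            class = "ac_pair_dataset")
}

#' @export
print.ac_pair_dataset <- function(x, ...) {
  cat(sprintf("<ac_pair_dataset: %d compounds, %d cliff pairs%s>\n",
              nrow(x$compounds), nrow(x$pairs),
              if (x$diagnostics$rejected) " (REJECTED)" else ""))
  invisible(x)
}

#' Re-filter a pair dataset at a stricter MCS threshold
#'
#' Pairs at threshold t' >= t are always a subset of those at t, so
#' evaluation sweeps can reuse one assembled dataset.
#'
#' @param dataset An `ac_pair_dataset`.
#' @param min_shared_fraction New (higher) threshold.
#' @return Logical vector over `dataset$pairs` rows.
#' @export
pairs_at_threshold <- function(dataset, min_shared_fraction) {
  dataset$pairs$shared_fraction_i >= min_shared_fraction &
    dataset$pairs$shared_fraction_j >= min_shared_fraction
}

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 271 * k) %% 2147483647)
}

#' Leakage-controlled cross-validation splits
#'
#' Produces `k` independent seeded compound-level splits into train /
#' validation / test sets (default 70/10/20). Every pair is assigned to the
#' partition of its FIRST ligand, mirroring the pair-level split rule of
#' single-target activity-cliff benchmarks; validation compounds are carved
#' out of the training compounds.
#'
#' @param compounds Compound data frame (or character vector of ids).
#' @param pairs Pair data frame with columns `pair_id` and `i`.
#' @param k Number of folds.
#' @param fractions Train/validation/test compound fractions (sum to 1).
#' @param seed Master seed; per-fold seeds are derived deterministically.
#' @return List of `k` fold splits, each with compound-id and pair-id sets.
#' @export
make_fold_splits <- function(compounds, pairs, k = 5,
                             fractions = c(0.7, 0.1, 0.2), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must sum to 1")
  }
  ids <- if (is.data.frame(compounds)) compounds$compound_id else compounds
  n <- length(ids)
  unknown <- setdiff(unique(c(pairs$i, pairs$j)), ids)
  if (length(unknown) > 0L) {
    stop(sprintf("pairs reference unknown compound(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  lapply(seq_len(k), function(fold) {
    fs <- .derive_seed(seed, fold)
    perm <- withr::with_seed(fs, sample(ids))
    n_test <- max(1L, round(fractions[3] * n))
    n_val <- max(1L, round(fractions[2] * n))
    test <- perm[seq_len(n_test)]
    val <- perm[n_test + seq_len(n_val)]
    train <- perm[-(seq_len(n_test + n_val))]
    set_of <- function(cset) pairs$pair_id[pairs$i %in% cset]
    list(fold = fold, seed = fs,
         train_compounds = train, val_compounds = val, test_compounds = test,
         train_pairs = set_of(train), val_pairs = set_of(val),
         test_pairs = set_of(test))
  })
}

#' Export/import a pair list
#'
#' @param dataset An `ac_pair_dataset`.
#' @param csv_path Destination CSV for the pair table.
#' @param masks_path Optional JSON destination for the mask arrays, keyed by
#'   pair id.
#' @return `csv_path`, invisibly.
#' @export
export_pairs <- function(dataset, csv_path, masks_path = NULL) {
  out <- dataset$pairs[, c("pair_id", "i", "j", "delta_y",
                           "shared_fraction_i", "shared_fraction_j")]
  names(out)[2:3] <- c("id_i", "id_j")
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(masks_path)) {
    jsonlite::write_json(dataset$masks, masks_path, auto_unbox = FALSE)
  }
  invisible(csv_path)
}
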