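#' Specification of a synthetic congeneric-series benchmark
#'
#' Defines a family of amide-type scaffold templates, each carrying one
#' substitution site, decorated with single-heavy-atom substituents whose
#' additive activity effects are known exactly. Observed pIC50 is the
#' additive true activity plus Gaussian noise. Substituents are pairwise
#' MCS-unambiguous (distinct single heavy atoms of different elements), so
#' the ground-truth atom coloring of every same-scaffold cliff pair is
#' well defined by construction.
#'
#' @param scaffolds Data frame with columns `template` (SMILES containing
#'   one `{R}` placeholder) and `base` (scaffold base activity, log units).
#' @param substituents Data frame with columns `smiles` (attachable
#'   fragment) and `effect` (additive activity effect, log units).
#' @param noise_sd Gaussian noise standard deviation on observed pIC50.
#' @param n_compounds Number of (scaffold, substituent) combinations drawn.
#' @param seed Seed governing sampling and noise.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(scaffolds = NULL, substituents = NULL,
                           noise_sd = 0.1, n_compounds = 60, seed = 17) {
  if (is.null(scaffolds)) {
    scaffolds <- data.frame(
      template = c("NC(=O)c1ccc({R})cc1",
                   "NC(=O)c1cccc({R})c1",
                   "CC(=O)Nc1ccc({R})cc1",
                   "NC(=O)c1ccc({R})cn1",
                   "NC(=O)c1ccc({R})cc1F",
                   "COC(=O)c1ccc({R})cc1",
                   "NC(=O)c1ccc({R})s1",
                   "CNC(=O)c1ccc({R})cc1"),
      base = c(5.0, 5.2, 5.45, 5.1, 5.3, 5.55, 5.15, 5.4),
      stringsAsFactors = FALSE)
  }
  if (is.null(substituents)) {
    substituents <- data.frame(
      smiles = c("F", "Cl", "Br", "I", "C", "N", "O", "S"),
      effect = round(seq(0, 3, length.out = 8), 4),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(grepl("{R}", scaffolds$template, fixed = TRUE)),
            noise_sd >= 0, n_compounds >= 2)
  structure(list(scaffolds = scaffolds, substituents = substituents,
                 noise_sd = noise_sd, n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic activity-cliff benchmark
#'
#' Samples `n_compounds` distinct (scaffold, substituent) assignments,
#' assembles their SMILES by fragment attachment, and draws observed pIC50
#' as true activity (scaffold base + substituent effect) plus Gaussian
#' noise. Every assembled SMILES is validated by parsing. The run fails
#' with instructions when the drawn set cannot yield the requested minimum
#' number of cliff pairs.
#'
#' @param spec A [synthetic_spec()].
#' @param min_pairs Minimum number of cliff pairs (|delta| of observed
#'   activity >= `cliff_threshold`) the generated set must admit.
#' @param cliff_threshold Cliff threshold in log units.
#' @return List with `records` (compound table: compound_id, smiles,
#'   activity) and `truth` (`compounds`: per-compound scaffold index,
#'   substituent SMILES/element, true noiseless activity; `substituents`:
#'   the effects table; `spec`).
#' @export
generate_benchmark <- function(spec = synthetic_spec(), min_pairs = 50,
                               cliff_threshold = 1.0) {
  sc <- spec$scaffolds
  su <- spec$substituents
  combos <- expand.grid(scaffold = seq_len(nrow(sc)),
                        substituent = seq_len(nrow(su)))
  if (spec$n_compounds > nrow(combos)) {
    stop(sprintf("n_compounds (%d) exceeds available combinations (%d)",
                 spec$n_compounds, nrow(combos)))
  }
  out <- withr::with_seed(spec$seed, {
    pick <- sort(sample.int(nrow(combos), spec$n_compounds))
    chosen <- combos[pick, , drop = FALSE]
    true_act <- sc$base[chosen$scaffold] + su$effect[chosen$substituent]
    obs <- true_act + stats::rnorm(nrow(chosen), 0, spec$noise_sd)
    list(chosen = chosen, true_act = true_act, obs = obs)
  })
  chosen <- out$chosen
  smiles <- vapply(seq_len(nrow(chosen)), function(r) {
    sub("{R}", su$smiles[chosen$substituent[r]],
        sc$template[chosen$scaffold[r]], fixed = TRUE)
  }, character(1))
  ids <- sprintf("S%02dR%02d", chosen$scaffold, chosen$substituent)
  for (r in seq_len(length(smiles))) {
    tryCatch(parse_smiles(smiles[r], ids[r]),
             error = function(e) {
               stop(sprintf("invalid substituent attachment for %s: %s",
                            ids[r], conditionMessage(e)))
             })
  }
  records <- data.frame(compound_id = ids, smiles = smiles,
                        activity = out$obs, stringsAsFactors = FALSE)
  n_cliff <- sum(abs(outer(out$obs, out$obs, "-")[upper.tri(diag(length(out$obs)))]) >=
                   cliff_threshold)
  if (n_cliff < min_pairs) {
    stop(sprintf(paste0(
      "generated set admits only %d cliff pair(s) (need >= %d); widen the ",
      "substituent effect range or increase n_compounds"), n_cliff, min_pairs))
  }
  truth_compounds <- data.frame(
    compound_id = ids, scaffold = chosen$scaffold,
    substituent = su$smiles[chosen$substituent],
    substituent_element = sub("^\\[?([A-Z][a-z]?).*$", "\\1",
                              su$smiles[chosen$substituent]),
    effect = su$effect[chosen$substituent],
    true_activity = out$true_act, stringsAsFactors = FALSE)
  list(records = records,
       truth = list(compounds = truth_compounds, substituents = su,
                    spec = spec))
}

#' Check that the MCS pipeline recovers the constructed ground truth
#'
#' For every same-scaffold pair of an assembled dataset the pipeline should
#' mark exactly the substituent atom as uncommon (the scaffold as common)
#' on both sides. Cross-scaffold pairs have no constructed coloring and are
#' excluded from the agreement denominator, as are pairs whose two
#' compounds carry the same substituent.
#'
#' @param truth The `truth` component of [generate_benchmark()].
#' @param dataset An `ac_pair_dataset` assembled from the generated records.
#' @return List with `n_checked`, `n_agree`, `agreement` rate,
#'   `n_excluded` and ids of disagreeing pairs.
#' @export
validate_against_pipeline <- function(truth, dataset) {
  tc <- truth$compounds
  pr <- dataset$pairs
  if (nrow(pr) == 0) {
    return(list(n_checked = 0L, n_agree = 0L, agreement = NA_real_,
                n_excluded = 0L, disagreeing = character(0)))
  }
  n_checked <- 0L; n_agree <- 0L; n_excluded <- 0L
  bad <- character(0)
  for (r in seq_len(nrow(pr))) {
    ti <- tc[tc$compound_id == pr$i[r], ]
    tj <- tc[tc$compound_id == pr$j[r], ]
    if (ti$scaffold != tj$scaffold || ti$substituent == tj$substituent) {
      n_excluded <- n_excluded + 1L
      next
    }
    n_checked <- n_checked + 1L
    mk <- dataset$masks[[pr$pair_id[r]]]
    gi <- dataset$graphs[[pr$i[r]]]
    gj <- dataset$graphs[[pr$j[r]]]
    ok <- sum(mk$mask_uncommon_i) == 1 && sum(mk$mask_uncommon_j) == 1 &&
      gi$atoms$symbol[which(mk$mask_uncommon_i == 1)] == ti$substituent_element &&
      gj$atoms$symbol[which(mk$mask_uncommon_j == 1)] == tj$substituent_element
    if (ok) n_agree <- n_agree + 1L else bad <- c(bad, pr$pair_id[r])
  }
  list(n_checked = n_checked, n_agree = n_agree,
       agreement = if (n_checked > 0) n_agree / n_checked else NA_real_,
       n_excluded = n_excluded, disagreeing = bad)
}
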