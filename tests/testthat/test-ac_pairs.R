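test_that("MCS of identical molecules covers all atoms", {
  g <- featurize(parse_smiles("NC(=O)c1ccc(Cl)cc1", "x"))
  m <- find_mcs(g, g)
  expect_equal(m$n_atoms, g$n_atoms)
  mk <- compute_masks(m, g, g)
  expect_equal(mk$shared_fraction_i, 1)
  expect_true(all(mk$mask_uncommon_i == 0))
})

test_that("toluene/ethylbenzene MCS is the 7-atom toluene skeleton", {
  tol <- featurize(parse_smiles("Cc1ccccc1", "tol"))
  ebz <- featurize(parse_smiles("CCc1ccccc1", "ebz"))
  m <- find_mcs(tol, ebz)
  expect_equal(m$n_atoms, 7L)
  mk <- compute_masks(m, tol, ebz)
  expect_equal(mk$shared_fraction_i, 7 / 7)
  expect_equal(mk$shared_fraction_j, 7 / 8)
  expect_equal(sum(mk$mask_uncommon_j), 1)  # terminal CH3 of the ethyl
})

test_that("dissimilar molecules share almost nothing", {
  meth <- featurize(parse_smiles("C", "m"))
  bz <- featurize(parse_smiles("c1ccccc1", "b"))
  m <- find_mcs(meth, bz)
  expect_lte(m$n_atoms, 1L)
  mk <- compute_masks(m, meth, bz)
  expect_lt(mk$shared_fraction_j, 0.5)
})

test_that("branch-and-bound MCS equals exhaustive enumeration on small graphs", {
  withr::with_seed(7, {
    for (r in 1:20) {
      g1 <- random_graph(8)
      g2 <- random_graph(8)
      expect_equal(find_mcs(g1, g2)$n_atoms, mcs_oracle_size(g1, g2),
                   info = sprintf("random pair %d", r))
    }
  })
})

test_that("masks always partition the atoms", {
  ds <- small_dataset()
  for (pid in names(ds$masks)) {
    mk <- ds$masks[[pid]]
    expect_true(all(mk$mask_common_i + mk$mask_uncommon_i == 1))
    expect_true(all(mk$mask_common_j + mk$mask_uncommon_j == 1))
  }
})

test_that("activity-cliff rule is inclusive at the threshold", {
  expect_true(is_activity_cliff(5, 8.85))   # |delta| = 3.85
  expect_false(is_activity_cliff(5, 5.5))
  expect_true(is_activity_cliff(5, 6))      # boundary |delta| = 1.0
  expect_true(is_activity_cliff(6, 5))
  expect_error(is_activity_cliff(NA, 5))
})

test_that("ground-truth coloring follows the activity direction", {
  pair <- list(delta_y = 1.5,
               mask_common_i = c(1, 1, 0), mask_uncommon_i = c(0, 0, 1),
               mask_common_j = c(1, 0), mask_uncommon_j = c(0, 1))
  col <- ground_truth_coloring(pair)
  expect_equal(col$labels_i, c(0L, 0L, 1L))
  expect_equal(col$labels_j, c(0L, -1L))

  pair$delta_y <- -1.5
  col2 <- ground_truth_coloring(pair)
  expect_equal(col2$labels_i, c(0L, 0L, -1L))
  expect_equal(col2$labels_j, c(0L, 1L))

  pair$delta_y <- 0
  expect_error(ground_truth_coloring(pair), "not a cliff")
})

test_that("pair order flip negates delta and swaps colorings", {
  ds <- small_dataset()
  pid <- ds$pairs$pair_id[1]
  mk <- ds$masks[[pid]]
  fwdp <- list(delta_y = ds$pairs$delta_y[1],
               mask_uncommon_i = mk$mask_uncommon_i,
               mask_uncommon_j = mk$mask_uncommon_j,
               mask_common_i = mk$mask_common_i,
               mask_common_j = mk$mask_common_j)
  revp <- list(delta_y = -fwdp$delta_y,
               mask_uncommon_i = fwdp$mask_uncommon_j,
               mask_uncommon_j = fwdp$mask_uncommon_i,
               mask_common_i = fwdp$mask_common_j,
               mask_common_j = fwdp$mask_common_i)
  cf <- ground_truth_coloring(fwdp)
  cr <- ground_truth_coloring(revp)
  # the reversed pair keeps each compound's labels: uncommon atoms of the
  # more active compound stay +1 regardless of pair orientation
  expect_equal(cr$labels_i, cf$labels_j)
  expect_equal(cr$labels_j, cf$labels_i)
})

test_that("pair assembly matches the brute-force qualifying count", {
  comp <- small_compounds()
  ds <- small_dataset()
  graphs <- ds$graphs
  count <- 0L
  for (a in 1:(nrow(comp) - 1)) {
    for (b in (a + 1):nrow(comp)) {
      if (abs(comp$activity[a] - comp$activity[b]) < 1) next
      m <- find_mcs(graphs[[comp$compound_id[a]]], graphs[[comp$compound_id[b]]])
      mk <- compute_masks(m, graphs[[comp$compound_id[a]]],
                          graphs[[comp$compound_id[b]]])
      if (mk$shared_fraction_i >= 0.5 && mk$shared_fraction_j >= 0.5) {
        count <- count + 1L
      }
    }
  }
  expect_equal(nrow(ds$pairs), count)
  expect_equal(ds$pairs$delta_y,
               comp$activity[match(ds$pairs$i, comp$compound_id)] -
                 comp$activity[match(ds$pairs$j, comp$compound_id)])
})

test_that("degenerate inputs yield an empty, diagnosed dataset", {
  one <- small_compounds()[1, ]
  expect_message(ds <- assemble_pair_dataset(one, min_pairs = 1), "rejected")
  expect_equal(nrow(ds$pairs), 0L)
  expect_true(ds$diagnostics$rejected)

  flat <- small_compounds()
  flat$activity <- rep(5, 4)  # no cliffs possible
  expect_message(ds2 <- assemble_pair_dataset(flat, min_pairs = 1), "rejected")
  expect_equal(nrow(ds2$pairs), 0L)
})

test_that("raising the MCS threshold only removes pairs (nesting)", {
  ds <- bench_dataset()$dataset
  prev <- rep(TRUE, nrow(ds$pairs))
  for (t in seq(0.50, 0.95, by = 0.05)) {
    keep <- pairs_at_threshold(ds, t)
    expect_true(all(keep <= prev))  # subset of the previous set
    prev <- keep
  }
})

test_that("fold splits are deterministic, sized and leakage-free", {
  ds <- small_dataset()
  ten <- data.frame(compound_id = sprintf("c%02d", 1:10),
                    smiles = "C", activity = 1:10)
  pairs <- data.frame(pair_id = "p1", i = "c01", j = "c02",
                      delta_y = 1, stringsAsFactors = FALSE)
  s1 <- make_fold_splits(ten, pairs, k = 2, seed = 3)
  s2 <- make_fold_splits(ten, pairs, k = 2, seed = 3)
  expect_identical(s1, s2)
  expect_equal(length(s1[[1]]$train_compounds), 7L)
  expect_equal(length(s1[[1]]$val_compounds), 1L)
  expect_equal(length(s1[[1]]$test_compounds), 2L)

  sp <- make_fold_splits(ds$compounds, ds$pairs, k = 3, seed = 11)
  for (s in sp) {
    expect_length(intersect(s$train_compounds, s$test_compounds), 0)
    expect_length(intersect(s$train_compounds, s$val_compounds), 0)
    firsts <- ds$pairs$i[ds$pairs$pair_id %in% s$test_pairs]
    expect_length(intersect(firsts, s$train_compounds), 0)
  }
  expect_error(make_fold_splits(ten, pairs, fractions = c(0.5, 0.1, 0.2)),
               "sum to 1")
})

test_that("pair export round-trips through CSV", {
  ds <- small_dataset()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_pairs(ds, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(ds$pairs))
  expect_equal(back$delta_y, ds$pairs$delta_y)
  masks <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_setequal(names(masks), ds$pairs$pair_id)
})
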