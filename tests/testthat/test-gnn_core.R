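test_that("single-atom graphs propagate self-features only, without NaN", {
  st <- init_model_state(model_config(), 1)
  g <- featurize(parse_smiles("C", "methane"))
  H <- embed_and_propagate(st, g)
  expect_equal(dim(H), c(1L, 32L))
  expect_true(all(is.finite(H)))
  expect_true(is.finite(predict_affinity(st, g)))
})

test_that("node embeddings are permutation-equivariant, outputs invariant", {
  # hand-build the same molecule with two different atom orders
  g1 <- make_graph(c("C", "O", "N"),
                   data.frame(a = c(1, 2), b = c(2, 3),
                              order = c("single", "double")))
  g2 <- make_graph(c("N", "O", "C"),
                   data.frame(a = c(3, 2), b = c(2, 1),
                              order = c("single", "double")))
  perm <- c(3L, 2L, 1L)  # g1 atom k sits at position perm[k] in g2
  for (bb in c("edge_conditioned", "gin", "gat")) {
    st <- init_model_state(model_config(bb), 4)
    H1 <- embed_and_propagate(st, g1)
    H2 <- embed_and_propagate(st, g2)
    expect_equal(H2[perm, ], H1, tolerance = 1e-12)
    expect_equal(predict_affinity(st, g2), predict_affinity(st, g1),
                 tolerance = 1e-12)
  }
})

test_that("masked readout pools selected rows only", {
  h <- matrix(0, 3, 32)
  h[, 1] <- c(1, 2, 3)
  expect_equal(masked_readout(h, c(1, 0, 1), "sum")[1], 4)
  expect_equal(masked_readout(h, c(0, 1, 0), "sum"), h[2, ])
  expect_equal(masked_readout(h, c(0, 1, 0), "mean"), h[2, ])
  expect_equal(masked_readout(h, c(0, 1, 0), "max"), h[2, ])
  # mean over k identical selected rows is that row
  hh <- matrix(rep(h[2, ], 3), 3, byrow = TRUE)
  expect_equal(masked_readout(hh, c(1, 1, 1), "mean"), h[2, ])
  # mean divides by the number of selected nodes, not n
  expect_equal(masked_readout(h, c(1, 0, 1), "mean")[1], 2)
  # empty mask gives the zero vector for every pooling
  for (p in c("mean", "sum", "max")) {
    expect_equal(masked_readout(h, c(0, 0, 0), p), rep(0, 32))
  }
  expect_equal(masked_readout(h, c(0, 0, 0), "attention", gate = rep(1, 32)),
               rep(0, 32))
})

test_that("affinity head is linear with the bias as zero-input value", {
  st <- init_model_state(model_config(), 2)
  st$params$by <- 0.7
  z <- rep(0, 16)
  expect_equal(affinity_head(z, z, st), 0.7)
  g1 <- runif(16); g2 <- runif(16)
  base <- affinity_head(g1, g2, st) - 0.7
  st2 <- st
  st2$params$wy <- 2 * st$params$wy
  st2$params$by <- 0
  expect_equal(affinity_head(g1, g2, st2), 2 * base, tolerance = 1e-12)
})

test_that("subgraph deltas cancel biases and match hand arithmetic", {
  st <- init_model_state(model_config(), 3)
  g <- runif(16)
  d0 <- subgraph_delta(g, g, g, g, st)
  expect_equal(d0$delta_cn, 0)
  expect_equal(d0$delta_ucn, 0)

  st$params$beta_cn <- c(1, rep(0, 15))
  gi <- c(3, runif(15)); gj <- c(1, gi[-1])
  d <- subgraph_delta(gi, g, gj, g, st)
  expect_equal(d$delta_cn, 2)

  st2 <- st
  st2$params$bhead_cn <- st$params$bhead_cn + 5  # bias shift changes nothing
  d2 <- subgraph_delta(gi, g, gj, g, st2)
  expect_equal(d2$delta_cn, d$delta_cn)
})

test_that("forward_pair of an identical-compound pair gives zero deltas", {
  ds <- small_dataset()
  # fabricate a pair of a compound with itself
  cid <- ds$compounds$compound_id[1]
  n <- ds$graphs[[cid]]$n_atoms
  ds$pairs <- data.frame(pair_id = "self", i = cid, j = cid, delta_y = 0,
                         shared_fraction_i = 1, shared_fraction_j = 1,
                         stringsAsFactors = FALSE)
  ds$masks <- list(self = list(mask_common_i = rep(1L, n),
                               mask_uncommon_i = rep(0L, n),
                               mask_common_j = rep(1L, n),
                               mask_uncommon_j = rep(0L, n)))
  st <- init_model_state(model_config(), 5)
  out <- forward_pair(st, ds, "self")
  expect_equal(out$yhat_i, out$yhat_j, tolerance = 1e-12)
  expect_equal(out$delta_cn, 0, tolerance = 1e-12)
  expect_equal(out$delta_ucn, 0, tolerance = 1e-12)
  expect_true(all(is.finite(c(out$yhat_i, unlist(out$g_cn)))))
})

test_that("fully-shared pairs (empty uncommon masks) never produce NaN", {
  ds <- small_dataset()
  cid <- ds$compounds$compound_id[1]
  n <- ds$graphs[[cid]]$n_atoms
  ds$pairs <- data.frame(pair_id = "full", i = cid, j = cid, delta_y = 0,
                         shared_fraction_i = 1, shared_fraction_j = 1,
                         stringsAsFactors = FALSE)
  ds$masks <- list(full = list(mask_common_i = rep(1L, n),
                               mask_uncommon_i = rep(0L, n),
                               mask_common_j = rep(1L, n),
                               mask_uncommon_j = rep(0L, n)))
  for (pool in c("mean", "sum", "max", "attention")) {
    st <- init_model_state(model_config(pooling = pool), 6)
    out <- forward_pair(st, ds, "full")
    expect_true(all(is.finite(c(out$yhat_i, out$yhat_j, out$delta_cn,
                                out$delta_ucn))))
  }
})

test_that("mask/graph length mismatches are reported with the pair id", {
  ds <- small_dataset()
  pid <- ds$pairs$pair_id[1]
  ds$masks[[pid]]$mask_common_i <- c(ds$masks[[pid]]$mask_common_i, 1L)
  expect_error(forward_pair(init_model_state(model_config(), 1), ds, pid),
               pid, fixed = TRUE)
})

test_that("feature-width mismatches raise a shape error", {
  st <- init_model_state(model_config(), 1)
  g <- featurize(parse_smiles("CC", "x"))
  g$node_features <- g$node_features[, 1:49]
  expect_error(embed_and_propagate(st, g), "width")
})

test_that("checkpoints round-trip through JSON", {
  ds <- small_dataset()
  st <- init_model_state(model_config(), 9)
  path <- withr::local_tempfile(fileext = ".json")
  cliffgnn:::save_checkpoint(st, path)
  st2 <- cliffgnn:::load_checkpoint(path)
  g <- ds$graphs[[1]]
  expect_equal(predict_affinity(st2, g), predict_affinity(st, g),
               tolerance = 1e-12)
})
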