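test_that("on a linear model Gradient x Input equals IG equals w * x", {
  # identity activation + an edge-free graph make the network exactly linear
  # in the node features
  cfg <- model_config(activation = "identity")
  st <- init_model_state(cfg, 7)
  g <- make_graph(c("C", "N", "O"))   # three isolated atoms, no edges
  gxi <- attribute(st, g, "gradient_x_input")
  ig <- attribute(st, g, "integrated_gradients", list(steps = 8))
  expect_equal(ig$node_scores, gxi$node_scores, tolerance = 1e-10)

  # closed form: per-node score is x_v . w_eff for the effective linear map
  bk <- cliffgnn:::backward_batch(
    st, cliffgnn:::build_single_batch(g),
    cliffgnn:::forward_batch(st, cliffgnn:::build_single_batch(g),
                             training = FALSE),
    dyhat = 1, want_input_grads = TRUE)
  expect_equal(gxi$node_scores, rowSums(g$node_features * bk$dX),
               tolerance = 1e-12)

  m <- featurize(parse_smiles("C", "methane"))
  expect_equal(attribute(st, m, "gradient_x_input")$node_scores,
               attribute(st, m, "integrated_gradients",
                         list(steps = 16))$node_scores,
               tolerance = 1e-10)
})

test_that("IG satisfies completeness against the zero baseline", {
  g <- featurize(parse_smiles("NC(=O)c1ccc(Cl)cc1", "x"))
  # identity activation: the model is still nonlinear (edge-conditioned
  # messages are bilinear in the inputs), so this genuinely exercises the
  # quadrature; the smooth integrand keeps the 128-step trapezoid well
  # inside the 1e-3 axiom tolerance
  st_smooth <- init_model_state(model_config(activation = "identity"), 11)
  expect_lt(ig_completeness_error(st_smooth, g, 128), 1e-3)
  # with ReLU kinks along the path the trapezoid rule is an approximation;
  # the error stays small (percent scale) at 128 steps
  st_relu <- init_model_state(model_config(), 11)
  expect_lt(ig_completeness_error(st_relu, g, 128), 0.02)
})

test_that("IG converges as the step count doubles", {
  st <- init_model_state(model_config(), 12)
  g <- featurize(parse_smiles("OCc1ccccc1", "x"))
  ig <- function(k) attribute(st, g, "integrated_gradients",
                              list(steps = k))$node_scores
  d1 <- max(abs(ig(16) - ig(8)))
  d2 <- max(abs(ig(32) - ig(16)))
  d3 <- max(abs(ig(64) - ig(32)))
  expect_lt(d2, d1)
  expect_lt(d3, d2)
})

test_that("a zero-weight affinity readout yields all-zero maps", {
  st <- init_model_state(model_config(), 13)
  st$params$wy[] <- 0
  g <- featurize(parse_smiles("CCO", "x"))
  for (m in c("cam", "grad_cam", "gradient_x_input")) {
    expect_equal(attribute(st, g, m)$node_scores, rep(0, 3))
  }
  ig <- attribute(st, g, "integrated_gradients", list(steps = 8))
  expect_equal(ig$node_scores, rep(0, 3))
  expect_equal(ig$edge_scores, rep(0, 4))
})

test_that("edge redistribution conserves attribution mass", {
  g <- featurize(parse_smiles("CCO", "x"))
  map <- structure(list(compound_id = "x", method = "gradient_x_input",
                        node_scores = c(1, 2, 3),
                        edge_scores = c(2, 2, 0, 0), options = list()),
                   class = "attribution_map")
  out <- redistribute_edge_to_nodes(map, g)
  # bond 1 (atoms 1-2) has score 2: +1 to each endpoint; bond 2 scores 0
  expect_equal(out$node_scores, c(2, 3, 3))
  expect_null(out$edge_scores)

  withr::with_seed(3, {
    g2 <- featurize(parse_smiles("NC(=O)c1ccc(Cl)cc1", "y"))
    es <- rnorm(nrow(g2$edge_features))
    ns <- rnorm(g2$n_atoms)
    map2 <- structure(list(compound_id = "y", method = "gradient_x_input",
                           node_scores = ns, edge_scores = es,
                           options = list()), class = "attribution_map")
    out2 <- redistribute_edge_to_nodes(map2, g2)
    bond_scores <- (es[seq(1, length(es), 2)] + es[seq(2, length(es), 2)]) / 2
    expect_equal(sum(out2$node_scores), sum(ns) + sum(bond_scores),
                 tolerance = 1e-12)
  })
  # zero edge scores leave node scores unchanged
  map$edge_scores <- rep(0, 4)
  expect_equal(redistribute_edge_to_nodes(map, g)$node_scores, c(1, 2, 3))
})

test_that("attribution maps are permutation-equivariant and deterministic", {
  g1 <- make_graph(c("C", "O", "N"),
                   data.frame(a = c(1, 2), b = c(2, 3),
                              order = c("single", "double")))
  g2 <- make_graph(c("N", "O", "C"),
                   data.frame(a = c(3, 2), b = c(2, 1),
                              order = c("single", "double")))
  perm <- c(3L, 2L, 1L)
  st <- init_model_state(model_config(), 14)
  for (m in c("cam", "grad_cam", "gradient_x_input")) {
    s1 <- attribute(st, g1, m)$node_scores
    s2 <- attribute(st, g2, m)$node_scores
    expect_equal(s2[perm], s1, tolerance = 1e-12)
    expect_identical(attribute(st, g1, m)$node_scores, s1)
  }
})

test_that("attribution option validation", {
  st <- init_model_state(model_config(), 1)
  g <- featurize(parse_smiles("CC", "x"))
  expect_error(attribute(st, g, "integrated_gradients", list(steps = 1)),
               "steps")
  expect_error(attribute(st, g, "nonsense"))
  st_max <- init_model_state(model_config(pooling = "max"), 1)
  expect_error(attribute(st_max, g, "cam"), "pooling")
})

test_that("node-level linear heads are exposed without entering prediction", {
  st <- init_model_state(model_config(), 15)
  g <- featurize(parse_smiles("CCO", "x"))
  hs <- node_head_scores(st, g)
  expect_equal(dim(hs), c(3L, 2L))
  st2 <- st
  st2$params$cam_w_cn[] <- 0  # zeroing the heads must not move predictions
  expect_equal(predict_affinity(st2, g), predict_affinity(st, g))
})
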