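test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3)
  expect_equal(unname(regression_metrics(y, y)), c(0, 1))
  expect_equal(unname(regression_metrics(c(1, 2, 5), y)["rmse"]),
               sqrt(4 / 3))
  z <- c(-1, 0, 1)
  expect_equal(unname(regression_metrics(-z, z)["pcc"]), -1)
  expect_warning(out <- regression_metrics(c(2, 2, 2), y), "zero-variance")
  expect_true(is.na(out["pcc"]))
})

test_that("global direction compares mean uncommon attributions", {
  mu <- c(0, 1, 1)
  expect_equal(global_direction(1, c(9, 2, 2), c(9, 1, 1), mu, mu), 1)
  expect_equal(global_direction(1, c(9, 1, 1), c(9, 2, 2), mu, mu), 0)
  expect_equal(global_direction(1, c(9, 2, 2), c(9, 2, 2), mu, mu), 0) # tie
  expect_error(global_direction(0, c(1), c(1), c(1), c(1)), "not a cliff")
  expect_error(global_direction(1, c(1), c(1), c(0), c(0)), "no uncommon")
  # one empty side contributes mean 0
  expect_equal(global_direction(1, c(5, 5), c(-1), c(0, 0), c(1)), 1)
})

test_that("gdir matches a brute-force sign comparison on random fixtures", {
  withr::with_seed(31, {
    for (r in 1:300) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      mu1 <- rbinom(n1, 1, 0.6); mu2 <- rbinom(n2, 1, 0.6)
      if (sum(mu1) + sum(mu2) == 0) mu1[1] <- 1
      s1 <- rnorm(n1); s2 <- rnorm(n2)
      dy <- rnorm(1); if (dy == 0) dy <- 1
      expect_equal(global_direction(dy, s1, s2, mu1, mu2),
                   gdir_bruteforce(dy, s1, s2, mu1, mu2))
    }
  })
})

test_that("gdir curve filters by threshold with nested pair sets", {
  ds <- list(pairs = data.frame(
    pair_id = c("p1", "p2", "p3", "p4"),
    i = c("a", "a", "b", "c"), j = c("b", "c", "c", "d"),
    delta_y = c(2, -1.5, 1.2, 3),
    shared_fraction_i = c(0.95, 0.80, 0.60, 0.52),
    shared_fraction_j = c(0.90, 0.85, 0.55, 0.95),
    stringsAsFactors = FALSE),
    masks = list(
      p1 = list(mask_uncommon_i = c(1, 0), mask_uncommon_j = c(0, 1)),
      p2 = list(mask_uncommon_i = c(0, 1), mask_uncommon_j = c(1, 0)),
      p3 = list(mask_uncommon_i = c(1, 1), mask_uncommon_j = c(1, 0)),
      p4 = list(mask_uncommon_i = c(0, 1), mask_uncommon_j = c(1, 1))))
  maps <- list(a = c(5, -1), b = c(0, 0), c = c(1, 1), d = c(9, 9))
  curve <- gdir_curve(ds, maps)
  # hand filtering: at 0.50 all 4 pairs qualify; at 0.55 pairs p1,p2,p3; at
  # 0.60 p1,p2,p3 (p3 fractions 0.60/0.55 -> drops at 0.65); etc.
  g <- vapply(c("p1", "p2", "p3", "p4"), function(p) {
    r <- ds$pairs[ds$pairs$pair_id == p, ]
    global_direction(r$delta_y, maps[[r$i]], maps[[r$j]],
                     ds$masks[[p]]$mask_uncommon_i,
                     ds$masks[[p]]$mask_uncommon_j)
  }, numeric(1))
  expect_equal(unname(curve[["0.50"]]), mean(g))
  expect_equal(unname(curve[["0.55"]]), mean(g[1:3]))
  expect_equal(unname(curve[["0.65"]]), mean(g[1:2]))
  expect_equal(unname(curve[["0.95"]]), NA_real_)  # p1 has 0.90 on one side
  expect_named(curve, sprintf("%.2f", seq(0.50, 0.95, 0.05)))
})

make_eval_fixture <- function(scores_by_compound, labels) {
  # one pair, compound "u" vs "v"; labels over uncommon atoms
  ds <- list(pairs = data.frame(pair_id = "p", i = "u", j = "v",
                                delta_y = 2, shared_fraction_i = 0.5,
                                shared_fraction_j = 0.5,
                                stringsAsFactors = FALSE),
             colorings = list(p = labels))
  list(ds = ds, maps = scores_by_compound)
}

test_that("coloring metrics implement the stated sign rules", {
  fx <- make_eval_fixture(list(u = c(1, 1), v = c(1, -1)),
                          list(labels_i = c(1L, 1L),
                               labels_j = c(-1L, -1L)))
  cm <- coloring_metrics(fx$ds, fx$maps)
  expect_equal(unname(cm["accuracy"]), 0.75)  # labels +,+,-,-; preds +,+,+,-
  # perfect scores
  fx2 <- make_eval_fixture(list(u = c(2, 3), v = c(-1, -2)),
                           list(labels_i = c(1L, 1L),
                                labels_j = c(-1L, -1L)))
  expect_equal(unname(coloring_metrics(fx2$ds, fx2$maps)),
               c(1, 1))
  # all-zero scores count as misclassified
  fx3 <- make_eval_fixture(list(u = c(0, 0), v = c(0, 0)),
                           list(labels_i = c(1L, 1L),
                                labels_j = c(-1L, -1L)))
  expect_equal(unname(coloring_metrics(fx3$ds, fx3$maps)["accuracy"]), 0)
})

test_that("Spearman alignment matches rank-based computation", {
  fx <- make_eval_fixture(list(u = c(3, 2), v = c(1, 0)),
                          list(labels_i = c(1L, 1L),
                               labels_j = c(-1L, -1L)))
  rho <- spearman_alignment(fx$ds, fx$maps)
  score <- c(3, 2, 1, 0); label <- c(1, 1, -1, -1)
  expect_equal(rho, stats::cor(rank(score), rank(label)))
  expect_gt(rho, 0)
  # one class absent -> missing with warning
  fx2 <- make_eval_fixture(list(u = c(3, 2), v = c(1, 0)),
                           list(labels_i = c(1L, 1L),
                                labels_j = c(1L, 1L)))
  expect_warning(r2 <- spearman_alignment(fx2$ds, fx2$maps), "both classes")
  expect_true(is.na(r2))
})

test_that("directional AUROC equals the brute-force pairwise estimator", {
  fx <- make_eval_fixture(list(u = c(3, 2), v = c(1, 0)),
                          list(labels_i = c(1L, 1L),
                               labels_j = c(-1L, -1L)))
  au <- directional_auroc(fx$ds, fx$maps)
  expect_equal(unname(au), c(1, 1))

  withr::with_seed(17, {
    for (r in 1:200) {
      n <- sample(4:50, 1)
      score <- rnorm(n)
      if (runif(1) < 0.3) score <- round(score)  # force ties sometimes
      lab <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(lab)) < 2) lab[1:2] <- c(-1, 1)
      expect_equal(cliffgnn:::.auroc_midrank(score, lab == 1),
                   auroc_bruteforce(score, lab == 1))
      expect_equal(cliffgnn:::.auroc_midrank(-score, lab == -1),
                   auroc_bruteforce(-score, lab == -1))
    }
  })
  # constant scores are uninformative
  expect_equal(auroc_bruteforce(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
})

test_that("paired tests give exact Wilcoxon and conventional edge cases", {
  a <- c(1, 2, 3, 4, 5); b <- rep(0, 5)
  pt <- paired_tests(a, b)
  expect_equal(unname(pt["wilcoxon_p"]), 2 / 32)  # exact enumeration of 2^5
  expect_lt(unname(pt["t_p"]), 0.05)
  # identical vectors
  eq <- paired_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(eq["t_p"]), 1)
  expect_true(is.na(eq["wilcoxon_p"]))
  # two-sided symmetry
  x <- c(0.1, 0.5, 0.3, 0.9); y <- c(0.2, 0.4, 0.8, 0.1)
  expect_equal(paired_tests(x, y), paired_tests(y, x))
})

test_that("edge dropout at rate 0 reproduces attributions exactly", {
  ds <- small_dataset()
  st <- init_model_state(model_config(), 19)
  rho <- suppressWarnings(
    perturbation_stability(st, ds, "gradient_x_input", seed = 5))
  expect_named(rho, c("0", "0.05", "0.1", "0.2", "0.3"))
  maps <- attribute_all(st, ds, "gradient_x_input")
  base <- suppressWarnings(spearman_alignment(ds, maps))
  expect_identical(unname(rho[["0"]]), base)
  rho2 <- suppressWarnings(
    perturbation_stability(st, ds, "gradient_x_input", seed = 5))
  expect_identical(rho, rho2)  # seeded dropout is reproducible
})
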