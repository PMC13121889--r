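# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoized for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small congeneric table: decorated benzenes with activities spanning cliffs
small_compounds <- function() {
  data.frame(
    compound_id = c("tol", "ebz", "bzalc", "clbz"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1", "Clc1ccccc1"),
    activity = c(5.0, 7.5, 6.2, 8.1),
    stringsAsFactors = FALSE)
}

small_dataset <- function() {
  memo("small_dataset", {
    assemble_pair_dataset(small_compounds(), min_pairs = 1)
  })
}

small_batch <- function() {
  memo("small_batch", {
    ds <- small_dataset()
    acts <- stats::setNames(ds$compounds$activity, ds$compounds$compound_id)
    cliffgnn:::build_pair_batch(ds$pairs, ds$masks, ds$graphs, acts)
  })
}

# default synthetic benchmark, assembled once (used by split/acceptance tests)
bench_dataset <- function() {
  memo("bench_dataset", {
    bench <- generate_benchmark()
    list(bench = bench,
         dataset = assemble_pair_dataset(bench$records, min_pairs = 50))
  })
}

# --- hand-built molecular graphs (no SMILES round trip) ------------------

# Construct a featurized molecular_graph directly from symbols and a bond
# data frame; used for random-graph oracles and edge-free linear fixtures.
make_graph <- function(symbols, bonds = NULL, compound_id = "fixture") {
  n <- length(symbols)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = character(0),
                        stereo = character(0), ring = logical(0),
                        conjugated = logical(0), stringsAsFactors = FALSE)
  } else {
    if (is.null(bonds$stereo)) bonds$stereo <- "NONE"
    if (is.null(bonds$ring)) bonds$ring <- FALSE
    if (is.null(bonds$conjugated)) bonds$conjugated <- FALSE
  }
  deg <- rep(0L, n)
  if (nrow(bonds) > 0) {
    tab <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  g <- structure(list(
    compound_id = compound_id, n_atoms = n,
    atoms = data.frame(symbol = symbols, charge = 0L, aromatic = FALSE,
                       ring = FALSE, degree = deg, n_h = 0L,
                       stringsAsFactors = FALSE),
    bonds = bonds, node_features = NULL, edge_features = NULL,
    edge_index = NULL), class = "molecular_graph")
  featurize(g)
}

# random connected molecule-like graph with <= max_atoms atoms
random_graph <- function(max_atoms = 8, elements = c("C", "N", "O"),
                         orders = c("single", "double")) {
  n <- sample(2:max_atoms, 1)
  syms <- sample(elements, n, replace = TRUE)
  a <- integer(0); b <- integer(0)
  for (v in 2:n) {             # spanning tree keeps it connected
    a <- c(a, sample(v - 1, 1)); b <- c(b, v)
  }
  extra <- which(stats::runif(n * (n - 1) / 2) < 0.15)
  cmb <- utils::combn(n, 2)
  for (k in extra) {
    u <- cmb[1, k]; w <- cmb[2, k]
    if (!any((a == u & b == w) | (a == w & b == u))) {
      a <- c(a, u); b <- c(b, w)
    }
  }
  make_graph(syms, data.frame(a = a, b = b,
                              order = sample(orders, length(a), replace = TRUE),
                              stringsAsFactors = FALSE))
}

# --- exhaustive MCS oracle ----------------------------------------------

# Largest connected common substructure by enumerating atom subsets of g1
# (largest first) and searching for a bond-compatible injection into g2.
# Independent of the package's branch-and-bound search order.
mcs_oracle_size <- function(g1, g2) {
  lab <- function(g) {
    A <- matrix(0L, g$n_atoms, g$n_atoms)
    if (nrow(g$bonds) > 0) {
      o <- match(g$bonds$order, c("single", "double", "triple", "aromatic"))
      l <- o * 10L + as.integer(g$bonds$ring)
      A[cbind(g$bonds$a, g$bonds$b)] <- l
      A[cbind(g$bonds$b, g$bonds$a)] <- l
    }
    A
  }
  A1 <- lab(g1); A2 <- lab(g2)
  s1 <- g1$atoms$symbol; s2 <- g2$atoms$symbol
  n1 <- g1$n_atoms; n2 <- g2$n_atoms

  # can `subset` of g1 map into g2 with matched bonds forming a connected
  # graph? depth-first over injective assignments
  embeds <- function(subset) {
    k <- length(subset)
    assign_next <- function(pos, mapping, used2) {
      if (pos > k) {
        # connectivity of the matched-bond graph over the subset
        if (k == 1) return(TRUE)
        adj <- matrix(FALSE, k, k)
        for (x in 1:(k - 1)) for (y in (x + 1):k) {
          l1 <- A1[subset[x], subset[y]]
          if (l1 != 0 && l1 == A2[mapping[x], mapping[y]]) {
            adj[x, y] <- adj[y, x] <- TRUE
          }
        }
        seen <- c(1L); frontier <- c(1L)
        while (length(frontier) > 0) {
          nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)),
                         seen)
          seen <- c(seen, nxt); frontier <- nxt
        }
        return(length(seen) == k)
      }
      for (cand in seq_len(n2)) {
        # only element compatibility constrains the injection: mapped atom
        # pairs with mismatched bonds are allowed (such bonds simply stay
        # outside the common subgraph), connectivity is checked at the end
        if (used2[cand] || s2[cand] != s1[subset[pos]]) next
        used2[cand] <- TRUE
        mapping[pos] <- cand
        if (assign_next(pos + 1, mapping, used2)) return(TRUE)
        used2[cand] <- FALSE
      }
      FALSE
    }
    assign_next(1L, integer(k), logical(n2))
  }

  subsets <- unlist(lapply(seq_len(n1), function(k) {
    utils::combn(n1, k, simplify = FALSE)
  }), recursive = FALSE)
  sizes <- vapply(subsets, length, integer(1))
  for (k in sort(unique(sizes), decreasing = TRUE)) {
    for (sub in subsets[sizes == k]) {
      if (embeds(sub)) return(k)
    }
  }
  0L
}

# --- brute-force metric oracles -----------------------------------------

auroc_bruteforce <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

gdir_bruteforce <- function(delta_y, scores_i, scores_j, mu_i, mu_j) {
  r_i <- if (sum(mu_i) > 0) mean(scores_i[mu_i > 0]) else 0
  r_j <- if (sum(mu_j) > 0) mean(scores_j[mu_j > 0]) else 0
  as.numeric(sign(r_i - r_j) == sign(delta_y))
}

# finite-difference gradient check on a subsample of coordinates; relative
# error with an absolute floor that ignores pure round-off on ~zero entries
fd_max_rel_error <- function(state, batch, lcfg, n_coords = 60, eps = 1e-5,
                             coord_seed = 42) {
  obj <- total_objective(state, batch, lcfg, training = TRUE,
                         with_grads = TRUE)
  g <- cliffgnn:::flatten_params(obj$grads)
  th <- cliffgnn:::flatten_params(state$params)
  idx <- withr::with_seed(coord_seed,
                          sort(sample(length(th), min(n_coords, length(th)))))
  fd <- vapply(idx, function(i) {
    stp <- state
    tp <- th; tp[i] <- th[i] + eps
    stp$params <- cliffgnn:::unflatten_params(tp, state$params)
    v1 <- total_objective(stp, batch, lcfg, training = TRUE)$value
    tp[i] <- th[i] - eps
    stp$params <- cliffgnn:::unflatten_params(tp, state$params)
    v0 <- total_objective(stp, batch, lcfg, training = TRUE)$value
    (v1 - v0) / (2 * eps)
  }, numeric(1))
  max(abs(fd - g[idx]) / pmax(abs(fd) + abs(g[idx]), 1e-4))
}

# IG completeness: relative error of the score total against yhat - yhat0
ig_completeness_error <- function(st, g, steps) {
  map <- attribute(st, g, "integrated_gradients", list(steps = steps))
  batch <- cliffgnn:::build_single_batch(g)
  yhat <- cliffgnn:::forward_batch(st, batch, training = FALSE)$yhat[1]
  b0 <- batch
  b0$X <- 0 * b0$X; b0$E <- 0 * b0$E; b0$E_unique <- 0 * b0$E_unique
  y0 <- cliffgnn:::forward_batch(st, b0, training = FALSE)$yhat[1]
  total <- sum(map$node_scores) + sum(map$edge_scores)
  abs(total - (yhat - y0)) / abs(yhat - y0)
}
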