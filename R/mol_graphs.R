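#' @useDynLib cliffgnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed 35-symbol element vocabulary; anything else maps to the "other" slot.
ELEMENT_VOCAB <- c(
  "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
  "Si", "Se", "As", "Li", "Na", "K", "Mg", "Ca", "Fe", "Zn",
  "Cu", "Mn", "Co", "Ni", "Cr", "Sn", "Al", "Te", "V", "Mo",
  "W", "Pd", "Pt", "Hg", "Ge"
)

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_STEREO <- c("Z", "E", "ANY", "NONE")

# Lowest standard valences; multivalent elements list all accessible states.
.VALENCES <- list(
  C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5), F = 1, Cl = 1,
  Br = 1, I = 1, B = 3, Si = 4, Se = c(2, 4, 6), As = c(3, 5)
)

#' Atom and bond feature layout manifest
#'
#' Returns the documented, versioned column layout of the 50-dimensional atom
#' feature vector and the 10-dimensional bond feature vector. The layout is
#' identical for every molecule, which makes feature matrices comparable
#' across compounds and lets attribution scores be traced back to named
#' descriptors.
#'
#' @return A list with character vectors `node` (length 50) and `edge`
#'   (length 10) naming each feature column, and a `version` string.
#' @export
feature_layout <- function() {
  node <- c(
    paste0("element_", c(ELEMENT_VOCAB, "other")),    # 36
    paste0("degree_", 0:5),                           # 6
    paste0("n_implicit_h_", 0:4),                     # 5
    "formal_charge",                                  # 1, clipped to [-1, 1]
    "aromatic",                                       # 1
    "in_ring"                                         # 1
  )
  edge <- c(
    paste0("bond_", BOND_ORDERS),                     # 4
    paste0("stereo_", BOND_STEREO),                   # 4
    "conjugated",                                     # 1
    "in_ring"                                         # 1
  )
  stopifnot(length(node) == 50L, length(edge) == 10L)
  list(node = node, edge = edge, version = "1")
}

.sdf_charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                       `5` = -1L, `6` = -2L, `7` = -3L)

# The OpenBabel SMILES reader is lenient (e.g. it silently reads "C(" as
# methane), so reject structurally malformed strings up front: unbalanced
# branches/brackets, unmatched ring-closure digits, dangling bond symbols.
.check_smiles_syntax <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L; in_bracket <- FALSE
  ring <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "]") in_bracket <- FALSE
      if (ch == "[") return(FALSE)
      i <- i + 1L; next
    }
    if (ch == "[") in_bracket <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    else if (ch == "%") {
      if (i + 2L > length(chars) || !grepl("^[0-9]{2}$",
          paste0(chars[i + 1L], chars[i + 2L]))) return(FALSE)
      d <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ring[as.character(d)] <- (if (is.na(ring[as.character(d)])) 0L else ring[[as.character(d)]]) + 1L
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      ring[ch] <- (if (is.na(ring[ch])) 0L else ring[[ch]]) + 1L
    } else if (!grepl("[-A-Za-z@+=#:/\\\\.*~$]", ch)) return(FALSE)
    i <- i + 1L
  }
  if (in_bracket || depth != 0L) return(FALSE)
  if (length(ring) > 0L && any(ring %% 2L != 0L)) return(FALSE)
  if (grepl("[=#:/\\\\(\\[]$", smiles)) return(FALSE)
  TRUE
}

# Minimal V2000 molblock reader (symbols, charge codes, bonds, M CHG lines).
# Needed because the higher-level SDF reader cannot represent zero-bond
# molecules; the chemistry itself still comes from the OpenBabel conversion.
.read_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  m <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n) || is.na(m) || n < 1L) return(NULL)
  atom_lines <- lines[4L + seq_len(n)]
  symbols <- trimws(substr(atom_lines, 32, 34))
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charges <- unname(.sdf_charge_codes[as.character(charge_code)])
  charges[is.na(charges)] <- 0L
  bonds <- NULL
  if (m > 0L) {
    bond_lines <- lines[4L + n + seq_len(m)]
    bonds <- data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order_num = as.integer(substr(bond_lines, 7, 9)),
      stereo_code = suppressWarnings(as.integer(substr(bond_lines, 10, 12))))
    bonds$stereo_code[is.na(bonds$stereo_code)] <- 0L
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charges[f[2 * j]] <- f[2 * j + 1L]
  }
  list(n = n, symbols = symbols, charges = as.integer(charges), bonds = bonds)
}

.implicit_h <- function(symbol, charge, bond_order_sum) {
  vals <- .VALENCES[[symbol]]
  if (is.null(vals)) return(0L)
  need <- bond_order_sum - charge
  v <- vals[vals >= need]
  if (length(v) == 0L) return(0L)
  as.integer(max(0, v[1] + charge - bond_order_sum))
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Uses the OpenBabel toolkit (through ChemmineR/ChemmineOB) to interpret the
#' SMILES, then perceives aromaticity, ring membership (ring bonds are the
#' non-bridge bonds of the heavy-atom graph), conjugation and implicit
#' hydrogen counts. Hydrogens stay implicit; atom order follows the SMILES
#' input order, so identical input gives an identical graph.
#'
#' @param smiles A single non-empty SMILES string.
#' @param compound_id Identifier stored on the graph.
#' @return A `molecular_graph` object: lists of atoms and bonds plus (after
#'   [featurize()]) node/edge feature matrices and a directed edge index.
#'   Every undirected bond appears as two directed edges with identical
#'   feature rows.
#' @export
parse_smiles <- function(smiles, compound_id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  if (!.check_smiles_syntax(smiles)) {
    stop(sprintf("SMILES parse error for %s: '%s'", compound_id, smiles),
         call. = FALSE)
  }
  molblock <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = smiles)),
    error = function(e) {
      stop(sprintf("SMILES parse error for %s: '%s' (%s)", compound_id,
                   smiles, conditionMessage(e)), call. = FALSE)
    })
  parsed <- .read_molblock(molblock)
  if (is.null(parsed)) {
    stop(sprintf("SMILES parse error for %s: '%s'", compound_id, smiles),
         call. = FALSE)
  }
  n <- parsed$n
  symbols <- parsed$symbols
  charges <- parsed$charges

  if (is.null(parsed$bonds)) {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        order = character(0), stereo = character(0),
                        ring = logical(0), conjugated = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- parsed$bonds
    if (any(bonds$a == bonds$b)) {
      stop(sprintf("self-loop bond in %s", compound_id))
    }
  }

  aromatic_atom <- rep(FALSE, n)
  if (nrow(bonds) > 0L) {
    sdf <- suppressWarnings(
      ChemmineR::read.SDFset(strsplit(molblock, "\n", fixed = TRUE)[[1]]))
    ri <- tryCatch(ChemmineR::rings(sdf[[1]], upper = 20, type = "all",
                                    arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    if (length(ri$RINGS) > 0L) {
      for (k in seq_along(ri$RINGS)) {
        if (isTRUE(ri$AROMATIC[[k]])) {
          idx <- as.integer(sub("^.*_", "", ri$RINGS[[k]]))
          aromatic_atom[idx] <- TRUE
        }
      }
    }
    g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_bond <- rep(TRUE, nrow(bonds))
    ring_bond[as.integer(br)] <- FALSE
    aromatic_bond <- ring_bond & aromatic_atom[bonds$a] & aromatic_atom[bonds$b]
    order_chr <- BOND_ORDERS[pmin(bonds$order_num, 3L)]
    order_chr[bonds$order_num == 4L | aromatic_bond] <- "aromatic"
    stereo <- ifelse(bonds$stereo_code == 3L, "ANY", "NONE")
    # conjugation: aromatic bonds, or any bond whose two endpoints each carry
    # some other multiple/aromatic bond (classic alternating-pi heuristic)
    multi <- bonds$order_num >= 2L | order_chr == "aromatic"
    has_pi <- rep(FALSE, n)
    has_pi[bonds$a[multi]] <- TRUE
    has_pi[bonds$b[multi]] <- TRUE
    conj <- order_chr == "aromatic" | (multi & FALSE)
    for (t in seq_len(nrow(bonds))) {
      if (conj[t]) next
      a <- bonds$a[t]; b <- bonds$b[t]
      pi_a <- any(multi & (bonds$a == a | bonds$b == a) & seq_len(nrow(bonds)) != t)
      pi_b <- any(multi & (bonds$a == b | bonds$b == b) & seq_len(nrow(bonds)) != t)
      conj[t] <- (multi[t] && (pi_a || pi_b)) || (!multi[t] && pi_a && pi_b)
    }
    bonds <- data.frame(a = bonds$a, b = bonds$b, order = order_chr,
                        stereo = stereo, ring = ring_bond,
                        conjugated = conj, kekule_order = bonds$order_num,
                        stringsAsFactors = FALSE)
  }

  degree <- rep(0L, n)
  bond_sum <- rep(0, n)
  if (nrow(bonds) > 0L) {
    tab <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n)))
    degree <- as.integer(tab)
    # kekulized orders (as emitted in the molblock) drive implicit-H counting;
    # an explicit order-4 aromatic marker falls back to 1.5 per bond
    kek <- ifelse(bonds$kekule_order == 4L, 1.5, bonds$kekule_order)
    for (t in seq_len(nrow(bonds))) {
      bond_sum[bonds$a[t]] <- bond_sum[bonds$a[t]] + kek[t]
      bond_sum[bonds$b[t]] <- bond_sum[bonds$b[t]] + kek[t]
    }
  }
  n_h <- vapply(seq_len(n), function(i) {
    .implicit_h(symbols[i], charges[i], as.integer(ceiling(bond_sum[i])))
  }, integer(1))

  atoms <- data.frame(
    symbol = symbols, charge = charges, aromatic = aromatic_atom,
    ring = rep(FALSE, n), degree = degree, n_h = n_h,
    stringsAsFactors = FALSE)
  if (nrow(bonds) > 0L) {
    atoms$ring[unique(c(bonds$a[bonds$ring], bonds$b[bonds$ring]))] <- TRUE
  }

  structure(list(
    compound_id = compound_id, n_atoms = n, atoms = atoms, bonds = bonds,
    node_features = NULL, edge_features = NULL, edge_index = NULL
  ), class = "molecular_graph")
}

#' Populate fixed-width feature matrices of a molecular graph
#'
#' Fills `node_features` (n x 50) and `edge_features` (2m x 10) following the
#' layout of [feature_layout()]. Each undirected bond contributes two directed
#' edges (rows 2t-1 and 2t for bond t) with identical feature rows; the
#' directed edge index column 1 is the source atom and column 2 the target.
#' Elements outside the 35-symbol vocabulary land in the "other" slot with a
#' warning.
#'
#' @param graph A `molecular_graph` from [parse_smiles()].
#' @return The graph with feature matrices and `edge_index` populated.
#' @export
featurize <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  layout <- feature_layout()
  n <- graph$n_atoms
  at <- graph$atoms
  X <- matrix(0, n, 50L, dimnames = list(NULL, layout$node))
  slot <- match(at$symbol, ELEMENT_VOCAB)
  if (anyNA(slot)) {
    warning(sprintf("element(s) outside vocabulary mapped to 'other': %s",
                    paste(unique(at$symbol[is.na(slot)]), collapse = ", ")))
  }
  slot[is.na(slot)] <- length(ELEMENT_VOCAB) + 1L
  X[cbind(seq_len(n), slot)] <- 1
  X[cbind(seq_len(n), 36L + 1L + pmin(at$degree, 5L))] <- 1
  X[cbind(seq_len(n), 42L + 1L + pmin(at$n_h, 4L))] <- 1
  X[, "formal_charge"] <- pmax(-1, pmin(1, at$charge))
  X[, "aromatic"] <- as.numeric(at$aromatic)
  X[, "in_ring"] <- as.numeric(at$ring)

  m <- nrow(graph$bonds)
  E <- matrix(0, 2L * m, 10L, dimnames = list(NULL, layout$edge))
  idx <- matrix(0L, 2L * m, 2L, dimnames = list(NULL, c("src", "dst")))
  if (m > 0L) {
    bo <- match(graph$bonds$order, BOND_ORDERS)
    st <- match(graph$bonds$stereo, BOND_STEREO)
    for (t in seq_len(m)) {
      row <- numeric(10L)
      row[bo[t]] <- 1
      row[4L + st[t]] <- 1
      row[9L] <- as.numeric(graph$bonds$conjugated[t])
      row[10L] <- as.numeric(graph$bonds$ring[t])
      E[2L * t - 1L, ] <- row
      E[2L * t, ] <- row
      idx[2L * t - 1L, ] <- c(graph$bonds$a[t], graph$bonds$b[t])
      idx[2L * t, ] <- c(graph$bonds$b[t], graph$bonds$a[t])
    }
  }
  graph$node_features <- X
  graph$edge_features <- E
  graph$edge_index <- idx
  # precomputed feature-row keys let batches group identical edge types fast
  graph$edge_key <- if (nrow(E) > 0) {
    apply(E, 1, paste, collapse = ",")
  } else character(0)
  graph
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph %s: %d atoms, %d bonds%s>\n",
              x$compound_id, x$n_atoms, nrow(x$bonds),
              if (is.null(x$node_features)) " (unfeaturized)" else ""))
  invisible(x)
}

#' Load a compound table from CSV
#'
#' Reads a CSV with compound id, SMILES and activity columns and converts
#' activities to pIC50 (= -log10 of IC50 in molar) when they are given as
#' IC50 values. Rows with missing or non-finite activity are dropped with a
#' message.
#'
#' @param path CSV file (UTF-8, header row).
#' @param activity_column Name of the activity column.
#' @param activity_kind One of `"pIC50"` (pass-through), `"IC50_nM"`
#'   (nanomolar, the BindingDB convention and the default unit interpretation)
#'   or `"IC50_M"` (molar).
#' @param id_column,smiles_column Column names for compound id and SMILES.
#' @return A data frame of compound records with columns `compound_id`,
#'   `smiles`, `activity` (pIC50, log10 units).
#' @export
load_compound_table <- function(path, activity_column = "activity",
                                activity_kind = c("pIC50", "IC50_nM", "IC50_M"),
                                id_column = "compound_id",
                                smiles_column = "smiles") {
  activity_kind <- match.arg(activity_kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c(id_column, smiles_column, activity_column)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- as.character(df[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate compound_id(s): %s", paste(dup, collapse = ", ")))
  }
  raw <- suppressWarnings(as.numeric(df[[activity_column]]))
  activity <- switch(activity_kind,
    pIC50 = raw,
    IC50_nM = -log10(raw * 1e-9),
    IC50_M = -log10(raw))
  keep <- is.finite(activity)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing/non-finite activity",
                    sum(!keep)))
  }
  data.frame(compound_id = ids[keep], smiles = as.character(df[[smiles_column]])[keep],
             activity = activity[keep], stringsAsFactors = FALSE)
}

#' Parse and featurize every compound of a record table
#'
#' @param records Data frame with `compound_id` and `smiles` columns.
#' @return Named list of featurized `molecular_graph` objects.
#' @export
build_graphs <- function(records) {
  graphs <- lapply(seq_len(nrow(records)), function(i) {
    featurize(parse_smiles(records$smiles[i], records$compound_id[i]))
  })
  names(graphs) <- records$compound_id
  graphs
}
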