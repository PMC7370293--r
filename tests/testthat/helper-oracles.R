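# Independent oracles used across the suite. These deliberately share no
# code with the package internals: subsets are enumerated exhaustively
# and distances recomputed with plain double loops.

# all maximal cliques (size >= 2) of a contact_graph by testing every
# vertex subset for clique-ness, then for maximality
oracle_max_cliques <- function(graph) {
  n <- graph$n_nodes
  adj <- matrix(FALSE, n, n)
  e <- graph$edges
  if (nrow(e) > 0L) {
    adj[e] <- TRUE
    adj[e[, c(2, 1), drop = FALSE]] <- TRUE
  }
  is_clique <- function(s) {
    if (length(s) < 2L) return(TRUE)
    all(adj[t(combn(s, 2L))])
  }
  cliques <- list()
  for (k in 2:n) {
    cmb <- combn(n, k)
    for (c_i in seq_len(ncol(cmb))) {
      s <- cmb[, c_i]
      if (!is_clique(s)) next
      extendable <- any(vapply(setdiff(seq_len(n), s), function(v) {
        all(adj[v, s])
      }, logical(1)))
      if (!extendable) cliques[[length(cliques) + 1L]] <- s
    }
  }
  cliques
}

# RCC counts from the oracle clique list, classifying by hand
oracle_rcc_counts <- function(graph) {
  counts <- integer(26)
  tab <- rcc_class_table()
  for (cl in oracle_max_cliques(graph)) {
    k <- length(cl)
    if (k < 3L || k > 6L) next
    p <- sort(graph$seq_indices[cl])
    runs <- integer(0)
    len <- 1L
    for (i in seq_along(p)[-1L]) {
      if (p[i] == p[i - 1L] + 1L) len <- len + 1L
      else { runs <- c(runs, len); len <- 1L }
    }
    runs <- sort(c(runs, len), decreasing = TRUE)
    key <- paste(runs, collapse = ",")
    idx <- tab$class[tab$size == k & tab$partition == key]
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# contact edges by an independent double loop over residue and atom pairs
brute_contact_edges <- function(structure, cutoff, mode) {
  at <- structure$atoms
  if (mode == "noSC") at <- at[at$is_backbone, , drop = FALSE]
  n <- structure$n_residues
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    ai <- at[at$res_node == i, c("x", "y", "z"), drop = FALSE]
    for (j in seq(i + 1L, n)) {
      aj <- at[at$res_node == j, c("x", "y", "z"), drop = FALSE]
      dmin <- Inf
      for (r in seq_len(nrow(ai))) for (s in seq_len(nrow(aj))) {
        dmin <- min(dmin, sqrt(sum((ai[r, ] - aj[s, ])^2)))
      }
      if (dmin <= cutoff) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(0), ncol = 2L) else edges
}

# tiny hand-written PDB fixture: three alanines on a line, chain A
fixture_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.500   0.500   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       0.000  -1.500   0.000  1.00  0.00           C",
    "ATOM      6  N   ALA A   2       3.800   1.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       5.300   0.500   0.000  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.800  -1.500   0.000  1.00  0.00           C",
    "ATOM     11  N   ALA A   3       7.600   1.000   0.000  1.00  0.00           N",
    "ATOM     12  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM     13  C   ALA A   3       8.600   0.000   0.000  1.00  0.00           C",
    "ATOM     14  O   ALA A   3       9.100   0.500   0.000  1.00  0.00           O",
    "ATOM     15  CB  ALA A   3       7.600  -1.500   0.000  1.00  0.00           C",
    "END"
  )
}

write_fixture_lines <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}
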