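# Residue contact graphs: nodes are residues, an edge joins two residues
# whose closest selected-atom pair lies within the distance cutoff.

#' Construct a contact graph object
#' @keywords internal
new_contact_graph <- function(n_nodes, seq_indices, edges, cutoff, atom_mode) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("i", "j")
  structure(
    list(
      n_nodes = as.integer(n_nodes),
      seq_indices = as.integer(seq_indices),
      edges = edges,
      cutoff = cutoff,
      atom_mode = atom_mode
    ),
    class = "contact_graph"
  )
}

#' Build the residue contact graph of a structure
#'
#' An edge joins residues i and j (i != j) when the minimum Euclidean
#' distance over all selected atom pairs is less than or equal to `cutoff`
#' (inclusive boundary). Sequence-adjacent residues are eligible like any
#' other pair.
#'
#' @param structure A `protein_structure`.
#' @param cutoff Distance cutoff in Angstrom (the study grid spans 4-15).
#' @param atom_mode `"SC"` (all heavy atoms) or `"noSC"` (backbone only).
#' @return A `contact_graph`: node count, per-node sequence positions, an
#'   edge matrix (i < j), and the provenance fields `cutoff`/`atom_mode`.
#' @examples
#' s <- generate_chain(chain_spec(8, seed = 3))
#' g <- build_contact_graph(s, cutoff = 7, atom_mode = "noSC")
#' nrow(g$edges)
#' @export
build_contact_graph <- function(structure, cutoff, atom_mode = c("SC", "noSC")) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(structure, "protein_structure"))
  if (structure$n_residues < 1L) stop("empty chain")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive number")
  }
  at <- select_atoms(structure, atom_mode)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  res <- at$res_node
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  ri <- res[hit[, 1L]]
  rj <- res[hit[, 2L]]
  keep <- ri != rj
  e <- unique(cbind(pmin(ri[keep], rj[keep]), pmax(ri[keep], rj[keep])))
  if (nrow(e) > 0L) e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  new_contact_graph(structure$n_residues, structure$seq_positions, e,
                    cutoff = cutoff, atom_mode = atom_mode)
}

#' Contact graph from an explicit adjacency matrix
#'
#' Bypasses geometry: wraps a precomputed symmetric boolean adjacency and
#' per-node sequence indices into a `contact_graph` (provenance recorded as
#' `"external"`).
#'
#' @param adjacency Square, symmetric logical/0-1 matrix with zero diagonal.
#' @param seq_indices Strictly increasing integer sequence positions, one
#'   per node.
#' @return A `contact_graph`.
#' @export
graph_from_adjacency <- function(adjacency, seq_indices) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix")
  }
  adjacency <- adjacency != 0
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency))) stop("adjacency must have a zero diagonal")
  n <- nrow(adjacency)
  seq_indices <- as.integer(seq_indices)
  if (length(seq_indices) != n) {
    stop("seq_indices length must equal the node count")
  }
  if (n > 1L && any(diff(seq_indices) <= 0L)) {
    stop("seq_indices must be strictly increasing")
  }
  hit <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  e <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  new_contact_graph(n, seq_indices, e, cutoff = NA_real_,
                    atom_mode = "external")
}

#' Adjacency list of a contact graph
#' @keywords internal
adjacency_list <- function(graph) {
  adj <- rep(list(integer(0)), graph$n_nodes)
  e <- graph$edges
  if (nrow(e) > 0L) {
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1L]; j <- e[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("contact_graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges",
      if (!is.na(x$cutoff)) paste0("(cutoff ", x$cutoff, " A, ", x$atom_mode, ")")
      else paste0("(", x$atom_mode, ")"), "\n")
  invisible(x)
}
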