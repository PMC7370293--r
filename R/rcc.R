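# The residue cluster class (RCC) featurizer: maximal cliques of the
# contact graph, sizes 3-6, classified by the integer partition induced by
# runs of sequence-consecutive residues. 26 classes in total:
# 3 of size 3, 5 of size 4, 7 of size 5, 11 of size 6.

#' Integer partitions of k in descending lexicographic order
#'
#' Partitions are non-increasing integer sequences summing to k, ordered
#' with `[k]` first and `[1,...,1]` last.
#'
#' @param k Positive integer.
#' @param max_part Largest allowed part (internal recursion).
#' @return A list of integer vectors.
#' @export
integer_partitions <- function(k, max_part = k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (first in seq(min(k, max_part), 1L)) {
    for (rest in integer_partitions(k - first, first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' The canonical 26-class partition table
#'
#' Maps each (clique size, sequence-proximity partition) pair to a class
#' index 1..26. Sizes 3, 4, 5, 6 contribute 3, 5, 7 and 11 classes; within
#' a size, partitions run in descending lexicographic order, so class 1 is
#' (3, \[3\]) and class 26 is (6, \[1,1,1,1,1,1\]).
#'
#' @return A data frame with columns `class`, `size`, `partition` (comma
#'   separated string).
#' @examples
#' tab <- rcc_class_table()
#' table(tab$size)
#' @export
rcc_class_table <- function() {
  tab <- .rcc_env$class_table
  if (is.null(tab)) {
    rows <- list()
    for (k in 3:6) {
      for (p in integer_partitions(k)) {
        rows[[length(rows) + 1L]] <-
          data.frame(size = k, partition = paste(p, collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- cbind(class = seq_len(nrow(tab)), tab)
    .rcc_env$class_table <- tab
  }
  tab
}

.rcc_env <- new.env(parent = emptyenv())

#' Sequence-proximity partition of a residue set
#'
#' Groups sequence positions into maximal runs of consecutive integers
#' (difference exactly 1) and returns the run lengths sorted
#' non-increasing. Residues two or more positions apart belong to
#' different runs, so e.g. positions {2, 4, 6} give `[1, 1, 1]` and
#' {5, 6, 9} give `[2, 1]`.
#'
#' @param seq_positions Distinct integer sequence positions.
#' @return Non-increasing integer vector summing to `length(seq_positions)`.
#' @export
sequence_partition <- function(seq_positions) {
  if (length(seq_positions) == 0L) stop("seq_positions must be non-empty")
  p <- sort(as.integer(seq_positions))
  if (anyDuplicated(p)) stop("duplicate sequence positions")
  runs <- cumsum(c(1L, as.integer(diff(p) != 1L)))
  sort(as.integer(table(runs)), decreasing = TRUE)
}

#' Class index of a (size, partition) pair
#'
#' @param k Clique size, one of 3, 4, 5, 6.
#' @param partition Non-increasing integer vector summing to `k`.
#' @return Integer class index in 1..26.
#' @export
class_index <- function(k, partition) {
  if (!k %in% 3:6) stop("unsupported clique size: ", k)
  if (sum(partition) != k) {
    stop("partition must sum to the clique size")
  }
  tab <- rcc_class_table()
  key <- paste(sort(as.integer(partition), decreasing = TRUE), collapse = ",")
  idx <- tab$class[tab$size == k & tab$partition == key]
  if (length(idx) != 1L) stop("partition not found in class table")
  idx
}

#' Enumerate the maximal cliques of a contact graph
#'
#' Bron-Kerbosch with max-degree pivoting over a degeneracy ordering.
#' Returns every maximal clique of size >= 2 exactly once (isolated
#' vertices, which are maximal singletons, are discarded), in a
#' deterministic order sorted by member tuples.
#'
#' @param graph A `contact_graph`.
#' @return List of integer vectors (sorted node ids).
#' @export
enumerate_maximal_cliques <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- graph$n_nodes
  adj <- adjacency_list(graph)
  acc <- new.env(parent = emptyenv())
  acc$cliques <- vector("list", 64L)
  acc$n <- 0L

  push <- function(cl) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$cliques)) {
      length(acc$cliques) <- 2L * length(acc$cliques)
    }
    acc$cliques[[acc$n]] <- cl
  }

  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      if (length(R) >= 2L) push(sort(R))
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(P, X)
    best <- cand[1L]; best_cnt <- -1L
    for (u in cand) {
      cnt <- length(intersect(P, adj[[u]]))
      if (cnt > best_cnt) { best <- u; best_cnt <- cnt }
    }
    for (v in setdiff(P, adj[[best]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }

  # degeneracy ordering: repeatedly remove a minimum-degree vertex
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  ordering <- integer(n)
  for (t in seq_len(n)) {
    v <- which(alive)[which.min(deg[alive])]
    ordering[t] <- v
    alive[v] <- FALSE
    nb <- adj[[v]]
    deg[nb[alive[nb]]] <- deg[nb[alive[nb]]] - 1L
  }
  pos <- integer(n)
  pos[ordering] <- seq_len(n)
  for (v in ordering) {
    nb <- adj[[v]]
    bk(v, nb[pos[nb] > pos[v]], nb[pos[nb] < pos[v]])
  }

  cliques <- acc$cliques[seq_len(acc$n)]
  if (length(cliques) == 0L) return(list())
  keys <- vapply(cliques, function(cl) {
    paste(formatC(cl, width = 6, flag = "0"), collapse = "-")
  }, character(1))
  cliques[order(keys)]
}

#' Compute the 26-dimensional RCC vector of a contact graph
#'
#' Counts the maximal cliques of size 3-6, each classified by
#' [sequence_partition()] of its members' sequence positions via
#' [class_index()]. Maximal cliques of size > 6 fall outside the class
#' table and are discarded whole; their number is kept in the
#' `n_discarded` field.
#'
#' @param graph A `contact_graph`.
#' @param structure_id Identifier recorded in the output provenance.
#' @return An `rcc_vector`: named integer `counts` (RCC1..RCC26) plus the
#'   provenance fields `cutoff`, `atom_mode`, `structure_id` and
#'   `n_discarded`.
#' @export
compute_rcc <- function(graph, structure_id = NA_character_) {
  stopifnot(inherits(graph, "contact_graph"))
  cliques <- enumerate_maximal_cliques(graph)
  counts <- integer(26L)
  n_disc <- 0L
  for (cl in cliques) {
    k <- length(cl)
    if (k < 3L) next
    if (k > 6L) { n_disc <- n_disc + 1L; next }
    part <- sequence_partition(graph$seq_indices[cl])
    ci <- class_index(k, part)
    counts[ci] <- counts[ci] + 1L
  }
  names(counts) <- paste0("RCC", 1:26)
  structure(
    list(counts = counts, cutoff = graph$cutoff,
         atom_mode = graph$atom_mode, structure_id = structure_id,
         n_discarded = n_disc),
    class = "rcc_vector"
  )
}

#' RCC vector straight from a structure
#'
#' Composition of [build_contact_graph()] and [compute_rcc()] with the
#' provenance fields filled in.
#'
#' @inheritParams build_contact_graph
#' @return An `rcc_vector`.
#' @examples
#' s <- generate_chain(chain_spec(10, seed = 2, geometry = "helix"))
#' rcc_from_structure(s, cutoff = 7, atom_mode = "noSC")
#' @export
rcc_from_structure <- function(structure, cutoff, atom_mode = c("SC", "noSC")) {
  atom_mode <- match.arg(atom_mode)
  g <- build_contact_graph(structure, cutoff, atom_mode)
  compute_rcc(g, structure_id = structure$structure_id)
}

#' RCC vectors over a cutoff-by-atom-mode grid
#'
#' The per-protein configuration grid of the study: 12 cutoffs (4-15 A)
#' crossed with the two atom modes gives 24 RCC vectors per structure.
#'
#' @param structure A `protein_structure`.
#' @param cutoffs Numeric vector of cutoffs in Angstrom.
#' @param atom_modes Character vector from `c("SC", "noSC")`.
#' @return A data frame: `structure_id`, `cutoff`, `atom_mode`,
#'   `RCC1`..`RCC26`.
#' @export
rcc_grid <- function(structure, cutoffs = 4:15, atom_modes = c("SC", "noSC")) {
  rows <- list()
  for (m in atom_modes) {
    for (cf in cutoffs) {
      v <- rcc_from_structure(structure, cf, m)
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = v$structure_id, cutoff = cf, atom_mode = m,
        as.list(v$counts), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.rcc_vector <- function(x, ...) {
  cat("rcc_vector", if (!is.na(x$structure_id)) x$structure_id else "",
      if (!is.na(x$cutoff)) paste0("(cutoff ", x$cutoff, " A, ", x$atom_mode, ")")
      else "", "\n")
  print(x$counts)
  if (x$n_discarded > 0L) {
    cat("(", x$n_discarded, "maximal clique(s) of size > 6 discarded )\n")
  }
  invisible(x)
}

#' @export
as.numeric.rcc_vector <- function(x, ...) as.numeric(x$counts)
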