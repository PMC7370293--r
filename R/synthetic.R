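# Desk-scale generators: polypeptide-like pseudo-CA chains, explicit
# random contact graphs, and labeled PPI count datasets with
# class-conditional mean shifts. Every generator is a pure function of
# its spec (seed included).

#' Specification for a synthetic pseudo-CA chain
#'
#' @param n_residues Number of residues (>= 1).
#' @param step Consecutive-residue spacing in Angstrom; 3.8 is the
#'   canonical CA-CA virtual bond length.
#' @param min_separation Excluded-volume radius: no two non-consecutive
#'   residues come closer than this (must be below `step`).
#' @param seed Integer RNG seed.
#' @param geometry `"random-walk"` (self-avoiding walk), `"helix"`
#'   (ideal alpha-helical CA trace: 2.3 A radius, 1.5 A rise, 100 degree
#'   turn per residue) or `"extended"` (a straight line).
#' @param sidechains If `TRUE`, each residue gains a pseudo-CB atom
#'   offset 1.5 A in a seeded random direction.
#' @return A `chain_spec`.
#' @export
chain_spec <- function(n_residues, step = 3.8, min_separation = 3.0,
                       seed = 1L, geometry = c("random-walk", "helix",
                                               "extended"),
                       sidechains = FALSE) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 1L, step > 0, min_separation < step)
  structure(list(n_residues = as.integer(n_residues), step = step,
                 min_separation = min_separation, seed = as.integer(seed),
                 geometry = geometry, sidechains = sidechains),
            class = "chain_spec")
}

#' Generate a polypeptide-like pseudo-CA chain
#'
#' Residues are single CA pseudo-atoms (alanine), placed with exact
#' consecutive spacing `spec$step` and, for the random walk, rejected
#' whenever a non-consecutive pair would fall below `spec$min_separation`.
#' Deterministic for a fixed spec.
#'
#' @param spec A [chain_spec()].
#' @return A `protein_structure` (chain "A", ids `synthchain`).
#' @examples
#' s <- generate_chain(chain_spec(10, seed = 4, geometry = "extended"))
#' rcc_from_structure(s, cutoff = 4, atom_mode = "noSC")$counts
#' @export
generate_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_residues
  set.seed(spec$seed)
  coords <- switch(spec$geometry,
    "extended" = cbind(spec$step * (seq_len(n) - 1L), 0, 0),
    "helix" = {
      # ideal alpha-helix CA trace; scale the rise so consecutive CA
      # spacing equals spec$step exactly
      r <- 2.3; turn <- 100 * pi / 180
      chord2 <- 2 * r^2 * (1 - cos(turn))
      rise <- sqrt(max(spec$step^2 - chord2, 0.25))
      t <- seq_len(n) - 1L
      cbind(r * cos(turn * t), r * sin(turn * t), rise * t)
    },
    "random-walk" = {
      for (attempt in seq_len(25L)) {
        xyz <- matrix(0, nrow = n, ncol = 3L)
        ok <- TRUE
        i <- 2L
        while (i <= n) {
          placed <- FALSE
          for (try in seq_len(200L)) {
            u <- stats::rnorm(3L)
            u <- u / sqrt(sum(u^2))
            cand <- xyz[i - 1L, ] + spec$step * u
            if (i <= 2L) { dmin <- Inf } else {
              dmin <- sqrt(min(rowSums(
                sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2L, cand)^2
              )))
            }
            if (dmin >= spec$min_separation) {
              xyz[i, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
          i <- i + 1L
        }
        if (ok) break
      }
      if (!ok) stop("chain generation failed; relax min_separation")
      xyz
    }
  )
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      res_node = i, author_number = i, insert = "", res_name = "ALA",
      atom_name = "CA", element = "C",
      x = coords[i, 1L], y = coords[i, 2L], z = coords[i, 3L],
      occupancy = 1, altloc = "", is_backbone = TRUE,
      stringsAsFactors = FALSE
    )
    if (spec$sidechains) {
      u <- stats::rnorm(3L); u <- 1.5 * u / sqrt(sum(u^2))
      rows[[length(rows) + 1L]] <- data.frame(
        res_node = i, author_number = i, insert = "", res_name = "ALA",
        atom_name = "CB", element = "C",
        x = coords[i, 1L] + u[1L], y = coords[i, 2L] + u[2L],
        z = coords[i, 3L] + u[3L],
        occupancy = 1, altloc = "", is_backbone = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(structure_id = paste0("synthchain", spec$seed, "_A"),
         chain_id = "A", atoms = do.call(rbind, rows),
         seq_positions = seq_len(n), n_residues = n),
    class = "protein_structure"
  )
}

#' Generate a seeded Erdos-Renyi contact graph
#'
#' @param n Node count.
#' @param edge_prob Edge probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A `contact_graph` with sequence indices 1..n.
#' @export
generate_contact_graph <- function(n, edge_prob, seed = 1L) {
  stopifnot(n >= 1L, edge_prob >= 0, edge_prob <= 1)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    set.seed(seed)
    up <- which(upper.tri(adj))
    adj[up] <- stats::runif(length(up)) < edge_prob
    adj <- adj | t(adj)
  }
  graph_from_adjacency(adj, seq_len(n))
}

#' Specification for a synthetic labeled PPI count dataset
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param dim Feature count, 26 (sum-style) or 52 (concatenation-style).
#' @param base_rates Per-feature Poisson means for the negative class;
#'   the default decays exponentially from 8, putting heavy mass at small
#'   counts as RCC count vectors do.
#' @param shift Class-conditional mean displacement added to the first
#'   `n_shift` non-sparse features for positives.
#' @param n_shift Number of shifted features (default 10).
#' @param sparsity Fraction of trailing features forced to zero in both
#'   classes (the structurally absent high-index classes).
#' @param seed Integer RNG seed.
#' @param train_fraction Fraction of each class assigned to training.
#' @return A `ppi_sim_spec`.
#' @export
ppi_sim_spec <- function(n_pos, n_neg, dim = 26L,
                         base_rates = 8 * exp(-0.25 * (seq_len(dim) - 1L)),
                         shift = 4, n_shift = 10L, sparsity = 0.15,
                         seed = 1L, train_fraction = 0.7) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, dim %in% c(26L, 52L),
            all(base_rates >= 0), length(base_rates) == dim,
            sparsity >= 0, sparsity <= 1, shift >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 dim = as.integer(dim), base_rates = base_rates,
                 shift = shift, n_shift = as.integer(n_shift),
                 sparsity = sparsity, seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "ppi_sim_spec")
}

#' Generate a labeled synthetic PPI dataset
#'
#' Feature counts are independent Poisson draws: means `base_rates` for
#' negatives and `base_rates + shift` on the first `n_shift` non-sparse
#' features for positives. The trailing `ceiling(sparsity * dim)`
#' features are structurally zero in both classes. The instances are
#' split per class into train/test at `train_fraction`, all seeded.
#'
#' @param spec A [ppi_sim_spec()].
#' @return List of `ppi_dataset`s: `train` and `test`.
#' @export
generate_ppi_dataset <- function(spec) {
  stopifnot(inherits(spec, "ppi_sim_spec"))
  d <- spec$dim
  n_zero <- ceiling(spec$sparsity * d)
  active <- seq_len(d - n_zero)
  set.seed(spec$seed)
  lam_neg <- spec$base_rates
  lam_pos <- lam_neg
  shift_idx <- utils::head(active, spec$n_shift)
  lam_pos[shift_idx] <- lam_pos[shift_idx] + spec$shift
  draw <- function(n, lam) {
    m <- matrix(0, nrow = n, ncol = d)
    for (j in active) m[, j] <- stats::rpois(n, lam[j])
    m
  }
  Xp <- draw(spec$n_pos, lam_pos)
  Xn <- draw(spec$n_neg, lam_neg)
  tr_p <- sort(sample.int(spec$n_pos, round(spec$train_fraction * spec$n_pos)))
  tr_n <- sort(sample.int(spec$n_neg, round(spec$train_fraction * spec$n_neg)))
  mk <- function(Xp_i, Xn_i) {
    ppi_dataset(rbind(Xp[Xp_i, , drop = FALSE], Xn[Xn_i, , drop = FALSE]),
                c(rep("positive", length(Xp_i)),
                  rep("negative", length(Xn_i))),
                provenance = list(sim_seed = spec$seed, shift = spec$shift))
  }
  list(train = mk(tr_p, tr_n),
       test = mk(setdiff(seq_len(spec$n_pos), tr_p),
                 setdiff(seq_len(spec$n_neg), tr_n)))
}

#' Write a structure as a minimal PDB fixture
#'
#' Emits legal fixed-width ATOM records (occupancy 1.00) that
#' [read_structure()] parses back; round-trips preserve residue count and
#' coordinates to 1e-3 Angstrom (the PDB coordinate precision).
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  lines <- character(nrow(at))
  for (r in seq_len(nrow(at))) {
    name <- at$atom_name[r]
    name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name)
                else sprintf("%-4s", name)
    lines[r] <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      r, name_fmt, substr(at$altloc[r], 1L, 1L), at$res_name[r],
      structure$chain_id, at$author_number[r],
      substr(at$insert[r], 1L, 1L),
      at$x[r], at$y[r], at$z[r], at$occupancy[r], 0, at$element[r]
    )
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
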