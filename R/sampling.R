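# Train/test construction and class-imbalance sampling: domain-aware
# splitting, random undersampling of the majority class, SMOTE
# oversampling of the minority class, redundancy removal, and enumeration
# of the study's 360-training-set / 24-test-set grids.

# deterministic small sub-seed from a base seed and string tags
#' @keywords internal
derive_seed <- function(base_seed, ...) {
  tag <- paste(..., sep = "|")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 1000003L
  as.integer((as.numeric(base_seed) * 2654435.0 + h) %% 2147483647)
}

#' Leakage-aware train/test split by domain annotation
#'
#' Groups positive pairs by the combined domain signature of their two
#' proteins and assigns, per group, the majority to training (a group of N
#' pairs sends at most floor(N/2) to test), largest groups first. A repair
#' pass then enforces that every domain's test multiplicity does not
#' exceed its training multiplicity, so each domain seen in test is also
#' seen (at least as often) in train. Negative pairs are copied into both
#' partitions (the redundant protocol: both sides share the negative set).
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param domain_annotations Data frame with columns `protein_id`,
#'   `domain_id` (several rows per protein allowed).
#' @return List with data frames `train` and `test`.
#' @export
split_by_domain <- function(pairs, domain_annotations) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)),
            all(c("protein_id", "domain_id") %in% names(domain_annotations)))
  pos <- pairs[pairs$label == "positive", , drop = FALSE]
  neg <- pairs[pairs$label == "negative", , drop = FALSE]
  dom_of <- split(as.character(domain_annotations$domain_id),
                  as.character(domain_annotations$protein_id))
  doms <- function(p) {
    d <- dom_of[[p]]
    if (is.null(d)) stop("missing domain annotation for protein: ", p)
    unique(d)
  }
  pair_doms <- lapply(seq_len(nrow(pos)), function(i) {
    sort(unique(c(doms(pos$id_a[i]), doms(pos$id_b[i]))))
  })
  sig <- vapply(pair_doms, paste, character(1), collapse = "+")
  groups <- split(seq_len(nrow(pos)), sig)
  groups <- groups[order(-lengths(groups), names(groups))]

  to_test <- logical(nrow(pos))
  for (g in groups) {
    n_test <- length(g) %/% 2L
    if (n_test > 0L) to_test[g[seq(length(g) - n_test + 1L, length(g))]] <- TRUE
  }
  # repair: per-domain test multiplicity must not exceed train multiplicity
  repeat {
    all_doms <- unique(unlist(pair_doms))
    cnt <- function(idx) {
      table(factor(unlist(pair_doms[idx]), levels = all_doms))
    }
    bad <- names(which(cnt(which(to_test)) > cnt(which(!to_test))))
    if (length(bad) == 0L) break
    offenders <- which(to_test & vapply(pair_doms, function(d) {
      any(d %in% bad)
    }, logical(1)))
    to_test[offenders[length(offenders)]] <- FALSE
  }
  list(
    train = rbind(pos[!to_test, , drop = FALSE], neg),
    test = rbind(pos[to_test, , drop = FALSE], neg)
  )
}

#' Undersample the positive (majority) class
#'
#' Keeps every negative instance and draws positives uniformly without
#' replacement down to exactly `ratio_pos_per_neg` times the negative
#' count (the 1:1, 2:1 and 3:1 designs). Deterministic for a fixed seed.
#'
#' @param dataset A `ppi_dataset` whose positives outnumber
#'   `ratio_pos_per_neg` times its negatives.
#' @param ratio_pos_per_neg Positives retained per negative: 1, 2 or 3.
#' @param seed Integer RNG seed.
#' @return A `ppi_dataset`.
#' @export
undersample <- function(dataset, ratio_pos_per_neg, seed) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  pos_idx <- which(dataset$labels == "positive")
  neg_idx <- which(dataset$labels == "negative")
  want <- ratio_pos_per_neg * length(neg_idx)
  if (length(pos_idx) < want) {
    stop("cannot satisfy ratio: need ", want, " positives, have ",
         length(pos_idx))
  }
  rs <- local({ set.seed(seed); sample(pos_idx, want) })
  keep <- sort(c(rs, neg_idx))
  prov <- dataset$provenance
  prov$sampling <- paste0("under_", ratio_pos_per_neg, ":1")
  prov$seed <- seed
  ppi_dataset(dataset$features[keep, , drop = FALSE],
              dataset$labels[keep], prov)
}

#' SMOTE oversampling of the negative (minority) class
#'
#' Synthetic Minority Oversampling TEchnique: each synthetic instance is
#' `x + u * (z - x)` for an original minority instance x, one of its
#' `k_neighbors` nearest minority neighbours z (Euclidean distance) and u
#' uniform on \[0, 1). `factor = 2` (the 1:2 design) doubles and
#' `factor = 3` triples the minority class; one unmodified copy of every
#' original minority instance is always retained.
#'
#' @param dataset A `ppi_dataset`.
#' @param factor Output minority size as a multiple of the original: 2 or 3.
#' @param k_neighbors Number of nearest minority neighbours (default 5).
#' @param seed Integer RNG seed.
#' @return A `ppi_dataset` with `(factor - 1) * n_neg` synthetic negatives
#'   appended.
#' @export
smote_oversample <- function(dataset, factor, k_neighbors = 5L, seed) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  min_idx <- which(dataset$labels == "negative")
  n_min <- length(min_idx)
  if (n_min <= k_neighbors) {
    stop("too few minority instances: need > ", k_neighbors, ", have ", n_min)
  }
  X <- dataset$features[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  n_new_per <- factor - 1L
  synth <- local({
    set.seed(seed)
    out <- matrix(0, nrow = n_new_per * n_min, ncol = ncol(X))
    row <- 0L
    for (i in seq_len(n_min)) {
      for (s in seq_len(n_new_per)) {
        z <- X[nn[i, sample.int(k_neighbors, 1L)], ]
        u <- stats::runif(1L)
        row <- row + 1L
        out[row, ] <- X[i, ] + u * (z - X[i, ])
      }
    }
    out
  })
  colnames(synth) <- colnames(dataset$features)
  prov <- dataset$provenance
  prov$sampling <- paste0(prov$sampling %||% "", "+over_1:", factor)
  prov$seed <- seed
  ppi_dataset(rbind(dataset$features, synth),
              c(as.character(dataset$labels), rep("negative", nrow(synth))),
              prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove duplicate and train-leaked feature vectors
#'
#' Within each partition, duplicate feature vectors reduce to their first
#' occurrence; test vectors exactly equal to any training vector are
#' dropped from test. After this, train and test share no feature vector
#' and neither partition holds duplicates.
#'
#' @param train,test `ppi_dataset` objects with equal feature length.
#' @return List with the deduplicated `train` and `test`.
#' @export
remove_redundancy <- function(train, test) {
  stopifnot(inherits(train, "ppi_dataset"), inherits(test, "ppi_dataset"),
            ncol(train$features) == ncol(test$features))
  key <- function(m) apply(m, 1L, paste, collapse = "\r")
  tr_keep <- !duplicated(key(train$features))
  train2 <- ppi_dataset(train$features[tr_keep, , drop = FALSE],
                        train$labels[tr_keep], train$provenance)
  te_key <- key(test$features)
  te_keep <- !duplicated(te_key) & !(te_key %in% key(train2$features))
  if (!any(te_keep)) warning("test partition is empty after redundancy removal")
  test2 <- ppi_dataset(test$features[te_keep, , drop = FALSE],
                       test$labels[te_keep], test$provenance)
  list(train = train2, test = test2)
}

#' Sampling grid specification
#'
#' Defaults reproduce the study design: cutoffs 7 and 8 Angstrom, both
#' atom modes, both combine modes, undersample ratios 1:1/2:1/3:1,
#' oversample factors 1:2/1:3 (each built from the replicate's 1:1
#' undersample), 3 replicates and 3 scalings — 216 undersample-branch plus
#' 144 oversample-branch training configurations (360 total) and 24 test
#' configurations.
#'
#' @param cutoffs Numeric cutoffs in Angstrom.
#' @param atom_modes Subset of `c("SC", "noSC")`.
#' @param combine_modes Subset of `c("sum", "concat")`.
#' @param under_ratios Undersample ratios (positives per negative).
#' @param over_factors SMOTE factors for the minority class.
#' @param replicates Random replicates per sampling.
#' @param scalings Subset of `c("raw", "normalized", "standardized")`.
#' @param base_seed Base seed from which per-configuration seeds derive.
#' @return A `sampling_grid_spec`.
#' @export
sampling_grid_spec <- function(cutoffs = c(7, 8),
                               atom_modes = c("SC", "noSC"),
                               combine_modes = c("sum", "concat"),
                               under_ratios = c(1L, 2L, 3L),
                               over_factors = c(2L, 3L),
                               replicates = 3L,
                               scalings = c("raw", "normalized",
                                            "standardized"),
                               base_seed = 1L) {
  stopifnot(replicates >= 1L, all(under_ratios > 0), all(over_factors > 1))
  structure(list(cutoffs = cutoffs, atom_modes = atom_modes,
                 combine_modes = combine_modes, under_ratios = under_ratios,
                 over_factors = over_factors, replicates = replicates,
                 scalings = scalings, base_seed = base_seed),
            class = "sampling_grid_spec")
}

#' Enumerate the training-set configuration grid
#'
#' The undersample branch crosses (cutoff, atom mode, combine mode) with
#' the undersample ratios, replicates and scalings; the oversample branch
#' crosses the same base with the SMOTE factors (applied to each
#' replicate's 1:1 undersample), replicates and scalings. Under the
#' default spec this yields 216 + 144 = 360 rows. A pure function of the
#' spec: identical specs give identical grids.
#'
#' @param spec A [sampling_grid_spec()].
#' @return Data frame with one row per training configuration: `branch`,
#'   `cutoff`, `atom_mode`, `combine_mode`, `sampling`, `replicate`,
#'   `scaling`, `seed`.
#' @export
enumerate_training_grid <- function(spec) {
  stopifnot(inherits(spec, "sampling_grid_spec"))
  under <- expand.grid(
    cutoff = spec$cutoffs, atom_mode = spec$atom_modes,
    combine_mode = spec$combine_modes,
    sampling = paste0("under_", spec$under_ratios, ":1"),
    replicate = seq_len(spec$replicates), scaling = spec$scalings,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  under$branch <- "undersample"
  over <- expand.grid(
    cutoff = spec$cutoffs, atom_mode = spec$atom_modes,
    combine_mode = spec$combine_modes,
    sampling = paste0("over_1:", spec$over_factors),
    replicate = seq_len(spec$replicates), scaling = spec$scalings,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  over$branch <- "oversample"
  grid <- rbind(under, over)
  grid <- grid[, c("branch", "cutoff", "atom_mode", "combine_mode",
                   "sampling", "replicate", "scaling")]
  grid$seed <- mapply(derive_seed, spec$base_seed, grid$branch,
                      grid$cutoff, grid$atom_mode, grid$combine_mode,
                      grid$sampling, grid$replicate)
  rownames(grid) <- NULL
  grid
}

#' Enumerate the test-set configuration grid
#'
#' Cross product of cutoffs, atom modes, combine modes and scalings with
#' no sampling: 2 x 2 x 2 x 3 = 24 under the default spec.
#'
#' @param spec A [sampling_grid_spec()].
#' @return Data frame with one row per test configuration.
#' @export
enumerate_test_grid <- function(spec) {
  stopifnot(inherits(spec, "sampling_grid_spec"))
  grid <- expand.grid(
    cutoff = spec$cutoffs, atom_mode = spec$atom_modes,
    combine_mode = spec$combine_modes, scaling = spec$scalings,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rownames(grid) <- NULL
  grid
}

#' Seeded 80/20 negative split for the non-redundant protocol
#'
#' The non-redundant design places 80 percent of the unique negative
#' instances in training and the remaining 20 percent in test, before any
#' positive sampling.
#'
#' @param dataset A `ppi_dataset` of negatives (or mixed; only negatives
#'   are split, positives all go to train).
#' @param seed Integer RNG seed.
#' @param train_fraction Fraction of unique negatives assigned to train.
#' @return List with `ppi_dataset`s `train` and `test`.
#' @export
split_negatives <- function(dataset, seed, train_fraction = 0.8) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  key <- apply(dataset$features, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  neg_idx <- which(first & dataset$labels == "negative")
  pos_idx <- which(first & dataset$labels == "positive")
  n_train <- round(train_fraction * length(neg_idx))
  tr_neg <- local({ set.seed(seed); sort(sample(neg_idx, n_train)) })
  te_neg <- setdiff(neg_idx, tr_neg)
  mk <- function(idx) {
    ppi_dataset(dataset$features[idx, , drop = FALSE], dataset$labels[idx],
                dataset$provenance)
  }
  list(train = mk(sort(c(pos_idx, tr_neg))), test = mk(te_neg))
}
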