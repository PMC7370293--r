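mk_dataset <- function(n_pos, n_neg, dim = 5L, seed = 1L) {
  set.seed(seed)
  ppi_dataset(matrix(rpois((n_pos + n_neg) * dim, 4), ncol = dim),
              c(rep("positive", n_pos), rep("negative", n_neg)))
}

test_that("undersampling keeps all negatives and hits the design positive counts", {
  ds <- mk_dataset(4819, 692)
  for (ratio in 1:3) {
    out <- undersample(ds, ratio, seed = 11)
    expect_equal(sum(out$labels == "negative"), 692L)
    expect_equal(sum(out$labels == "positive"), ratio * 692L)
  }
  # deterministic under a fixed seed, different under another
  a <- undersample(ds, 1, seed = 5)
  b <- undersample(ds, 1, seed = 5)
  expect_identical(a$features, b$features)
  c <- undersample(ds, 1, seed = 6)
  expect_false(identical(a$features, c$features))
  expect_error(undersample(mk_dataset(10, 20), 1, seed = 1),
               "cannot satisfy ratio")
})

test_that("undersampled positives are drawn without replacement from the originals", {
  ds <- mk_dataset(50, 10)
  out <- undersample(ds, 3, seed = 2)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  pos_out <- out$features[out$labels == "positive", ]
  expect_equal(anyDuplicated(rownames(pos_out)), 0)
  expect_true(all(key(pos_out) %in% key(ds$features[ds$labels == "positive", ])))
})

test_that("SMOTE multiplies the minority class and interpolates on neighbour segments", {
  ds <- mk_dataset(100, 30)
  for (f in 2:3) {
    out <- smote_oversample(ds, f, k_neighbors = 5, seed = 3)
    expect_equal(sum(out$labels == "negative"), f * 30L)
    expect_equal(sum(out$labels == "positive"), 100L)
    # originals retained unmodified
    expect_equal(out$features[seq_len(130), ], ds$features)
  }
  # every synthetic point lies on a segment between its parent and one of
  # the parent's k nearest minority neighbours
  out <- smote_oversample(ds, 2, k_neighbors = 5, seed = 3)
  X <- ds$features[ds$labels == "negative", ]
  d <- as.matrix(dist(X)); diag(d) <- Inf
  synth <- out$features[-seq_len(130), , drop = FALSE]
  for (r in seq_len(nrow(synth))) {
    parent <- X[r, ]  # synthetics generated in minority order, 1 per parent
    nbrs <- X[order(d[r, ])[1:5], , drop = FALSE]
    on_segment <- vapply(seq_len(5), function(j) {
      seg <- nbrs[j, ] - parent
      rel <- synth[r, ] - parent
      if (all(seg == 0)) return(all(rel == 0))
      u <- sum(rel * seg) / sum(seg^2)
      u >= 0 && u < 1 + 1e-9 && sqrt(sum((rel - u * seg)^2)) < 1e-8
    }, logical(1))
    expect_true(any(on_segment), info = paste("synthetic", r))
  }
})

test_that("SMOTE on duplicated identical minority points reproduces the originals", {
  feats <- rbind(matrix(5, 8, 3), matrix(rpois(60, 4) + 10, 20, 3))
  ds <- ppi_dataset(feats, c(rep("negative", 8), rep("positive", 20)))
  out <- smote_oversample(ds, 2, k_neighbors = 5, seed = 1)
  synth <- out$features[-seq_len(28), , drop = FALSE]
  expect_true(all(synth == 5))
  expect_error(smote_oversample(mk_dataset(10, 4), 2, k_neighbors = 5, seed = 1),
               "too few minority")
})

test_that("redundancy removal dedups partitions and empties train/test overlap", {
  f <- matrix(c(1, 1, 1,
                1, 1, 1,
                2, 2, 2,
                3, 3, 3), ncol = 3, byrow = TRUE)
  train <- ppi_dataset(f, rep("positive", 4))
  test <- ppi_dataset(rbind(c(2, 2, 2), c(4, 4, 4), c(4, 4, 4)),
                      rep("negative", 3))
  res <- remove_redundancy(train, test)
  expect_equal(nrow(res$train$features), 3L)  # duplicate (1,1,1) collapsed
  expect_equal(nrow(res$test$features), 1L)   # (2,2,2) leaked, (4,4,4) deduped
  expect_equal(unname(res$test$features[1, ]), c(4, 4, 4))
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(key(res$train$features), key(res$test$features)), 0L)
})

test_that("the default sampling grid enumerates 216 + 144 training and 24 test sets", {
  spec <- sampling_grid_spec()
  grid <- enumerate_training_grid(spec)
  expect_equal(sum(grid$branch == "undersample"), 216L)
  expect_equal(sum(grid$branch == "oversample"), 144L)
  expect_equal(nrow(grid), 360L)
  expect_equal(nrow(enumerate_test_grid(spec)), 24L)
  # pure function of the spec
  expect_identical(grid, enumerate_training_grid(sampling_grid_spec()))
  # reduced spec: 8 x 3 + 8 x 2 = 40
  small <- sampling_grid_spec(replicates = 1, scalings = "raw")
  expect_equal(nrow(enumerate_training_grid(small)), 40L)
  expect_equal(nrow(enumerate_test_grid(small)), 8L)
  one <- sampling_grid_spec(cutoffs = 7, atom_modes = "SC",
                            combine_modes = "sum", scalings = "raw")
  expect_equal(nrow(enumerate_test_grid(one)), 1L)
})

test_that("domain-aware splitting keeps the majority in train and never leaks a pair", {
  pairs <- data.frame(
    id_a = paste0("a", 1:10), id_b = paste0("b", 1:10),
    label = rep("positive", 10))
  ann <- data.frame(protein_id = c(paste0("a", 1:10), paste0("b", 1:10)),
                    domain_id = c(rep("PF1", 10), rep("PF2", 10)))
  neg <- data.frame(id_a = "n1", id_b = "n2", label = "negative")
  ann <- rbind(ann, data.frame(protein_id = c("n1", "n2"),
                               domain_id = c("PF9", "PF9")))
  res <- split_by_domain(rbind(pairs, neg), ann)
  n_test_pos <- sum(res$test$label == "positive")
  expect_lte(n_test_pos, 5L)
  expect_gte(sum(res$train$label == "positive"), 5L)
  # no positive pair in both partitions
  pk <- function(df) paste(df$id_a, df$id_b)
  pos_tr <- pk(res$train[res$train$label == "positive", ])
  pos_te <- pk(res$test[res$test$label == "positive", ])
  expect_length(intersect(pos_tr, pos_te), 0L)
  # negatives copied into both
  expect_true("n1 n2" %in% pk(res$train))
  expect_true("n1 n2" %in% pk(res$test))

  # a domain combination seen once goes to train, never test
  solo <- data.frame(id_a = "s1", id_b = "s2", label = "positive")
  ann2 <- rbind(ann, data.frame(protein_id = c("s1", "s2"),
                                domain_id = c("PF7", "PF8")))
  res2 <- split_by_domain(rbind(pairs, solo, neg), ann2)
  expect_true("s1 s2" %in% pk(res2$train))
  expect_false("s1 s2" %in% pk(res2$test))
  expect_error(split_by_domain(data.frame(id_a = "q1", id_b = "q2",
                                          label = "positive"), ann),
               "missing domain annotation")
})

test_that("the non-redundant protocol splits unique negatives 80/20", {
  feats <- matrix(seq_len(200), ncol = 2)  # 100 unique rows
  ds <- ppi_dataset(feats, rep("negative", 100))
  res <- split_negatives(ds, seed = 4)
  expect_equal(nrow(res$train$features), 80L)
  expect_equal(nrow(res$test$features), 20L)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(key(res$train$features), key(res$test$features)), 0L)
  # deterministic under seed
  res2 <- split_negatives(ds, seed = 4)
  expect_identical(res$train$features, res2$train$features)
})
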