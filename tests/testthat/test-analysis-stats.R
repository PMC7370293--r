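test_that("set diameter and inter-set distance match brute-force double loops", {
  expect_equal(set_diameter(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(set_diameter(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(inter_set_min_distance(matrix(c(0, 0), 1), matrix(c(6, 8), 1)), 10)
  shared <- rbind(c(1, 1), c(9, 9))
  expect_equal(inter_set_min_distance(shared, rbind(c(1, 1), c(50, 50))), 0)

  set.seed(8)
  A <- matrix(rnorm(40 * 6), 40)
  B <- matrix(rnorm(25 * 6, 2), 25)
  brute_max <- 0
  for (i in 1:39) for (j in (i + 1):40) {
    brute_max <- max(brute_max, sqrt(sum((A[i, ] - A[j, ])^2)))
  }
  brute_min <- Inf
  for (i in 1:40) for (j in 1:25) {
    brute_min <- min(brute_min, sqrt(sum((A[i, ] - B[j, ])^2)))
  }
  expect_equal(set_diameter(A), brute_max)
  expect_equal(inter_set_min_distance(A, B), brute_min)
  expect_error(set_diameter(matrix(numeric(0), 0, 2)), "empty")
})

test_that("distance separability flags d > D on the negative set", {
  neg <- rbind(c(0, 0), c(1, 0))          # diameter 1
  pos_far <- rbind(c(10, 0), c(11, 0))    # gap 9 > 1
  rep1 <- distance_separability(pos_far, neg)
  expect_true(rep1$distance_separable)
  expect_equal(rep1$D, 1)
  expect_equal(rep1$d, 9)

  rep2 <- distance_separability(neg, neg)  # identical sets: d = 0 <= D
  expect_false(rep2$distance_separable)
  expect_equal(rep2$d, 0)

  # gap equal to the spread: flag matches the direct comparison
  pos_eq <- rbind(c(2, 0), c(3, 0))        # d = 1 = D
  rep3 <- distance_separability(pos_eq, neg)
  expect_equal(rep3$distance_separable, rep3$d > rep3$D)
  expect_false(rep3$distance_separable)
})

test_that("linear separability is exact on classical cases and verifies its witness", {
  expect_true(linear_separability(matrix(2), matrix(0))$separable)
  # XOR is not linearly separable
  expect_false(linear_separability(rbind(c(0, 0), c(1, 1)),
                                   rbind(c(0, 1), c(1, 0)))$separable)
  # a shared point defeats separation
  expect_false(linear_separability(rbind(c(0, 0), c(5, 5)),
                                   matrix(c(0, 0), 1))$separable)

  set.seed(3)
  P <- matrix(rnorm(120 * 4, mean = 10), ncol = 4)
  N <- matrix(rnorm(120 * 4, mean = 0), ncol = 4)
  res <- linear_separability(P, N)
  expect_true(res$separable)
  expect_true(all(P %*% res$w + res$b > 0))
  expect_true(all(N %*% res$w + res$b < 0))
})

test_that("linear separability agrees with exhaustive hyperplane search on small cases", {
  # oracle: strict separability in 2-D holds iff some direction from the
  # candidate set (point-pair differences and their perpendiculars; the
  # max-margin normal is always one of these) splits the projections
  oracle_sep <- function(P, N) {
    X <- rbind(P, N)
    n_p <- nrow(P)
    dirs <- list()
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X))) {
      if (i == j) next
      v <- X[j, ] - X[i, ]
      if (all(v == 0)) next
      dirs[[length(dirs) + 1L]] <- v
      dirs[[length(dirs) + 1L]] <- c(-v[2], v[1])
    }
    for (w in dirs) {
      proj <- drop(X %*% w)
      pp <- proj[seq_len(n_p)]
      pn <- proj[-seq_len(n_p)]
      if (max(pp) < min(pn) || max(pn) < min(pp)) return(TRUE)
    }
    FALSE
  }
  set.seed(12)
  for (case in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    P <- matrix(sample(0:4, n1 * 2, TRUE), ncol = 2)
    N <- matrix(sample(0:4, n2 * 2, TRUE), ncol = 2)
    expect_equal(linear_separability(P, N)$separable, oracle_sep(P, N),
                 info = paste("case", case))
  }
})

test_that("exact rank-sum p-values match enumeration and the classical exact test", {
  # 3 vs 3 fully separated: the minimum attainable two-sided p is 0.1
  expect_equal(rank_sum_exact(1:3, 101:103), 0.1)
  # tie-free cases agree with the classical exact Wilcoxon p-value
  set.seed(5)
  for (case in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(seq(2, 2000, 2), n1)  # evens vs odds: tie-free by design
    y <- sample(seq(1, 1999, 2), n2)
    expect_equal(rank_sum_exact(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 info = paste("case", case))
  }
  # with ties the enumeration is still a valid permutation p-value
  p <- rank_sum_exact(c(1, 1, 2), c(1, 2, 2))
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("feature screening flags shifted features and not identical ones", {
  set.seed(9)
  pos <- cbind(shift = rpois(30, 12), same = rpois(30, 3),
               const = rep(2, 30))
  neg <- cbind(shift = rpois(30, 2), same = rpois(30, 3),
               const = rep(2, 30))
  rep <- feature_screen(pos, neg, correction = "bonferroni")
  expect_true(rep$significant[1])
  expect_false(rep$significant[2])
  expect_true(rep$degenerate[3])
  expect_equal(rep$p_raw[3], 1)
  # invariant to instance order
  perm <- sample(30)
  rep2 <- feature_screen(pos[perm, ], neg[rev(perm), ], correction = "bonferroni")
  expect_equal(rep2$p_raw, rep$p_raw)
  expect_error(feature_screen(pos[1, , drop = FALSE], neg), "at least 2")
})

test_that("p-value adjustment follows Bonferroni and BH step-up exactly", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bh"), 0.01)
  expect_equal(adjust_pvalues(rep(0.001, 1), "bonferroni"), 0.001)
  # Bonferroni multiplies by m and clips
  expect_equal(adjust_pvalues(c(0.001, 0.5, 0.9), "bonferroni"),
               c(0.003, 1, 1))
  # BH step-up on an arithmetic ladder collapses to the largest
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("BH rejections are a superset of Bonferroni rejections", {
  set.seed(17)
  for (case in 1:200) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    alpha <- 0.05
    bonf <- adjust_pvalues(p, "bonferroni") < alpha
    bh <- adjust_pvalues(p, "bh") < alpha
    expect_true(all(bh[bonf]), info = paste("case", case))
  }
})

test_that("nonzero-fraction profiling counts strictly nonzero entries", {
  m <- cbind(allzero = c(0, 0, 0, 0), full = c(1, 2, 3, 4),
             half = c(0, 1, 0, 2))
  fr <- nonzero_fraction_profile(m)
  expect_equal(unname(fr), c(0, 1, 0.5))
  set.seed(2)
  sp <- matrix(rbinom(300, 1, 0.3) * rpois(300, 2), ncol = 10)
  expect_equal(unname(nonzero_fraction_profile(sp)),
               apply(sp, 2, function(col) sum(col != 0) / length(col)))
  ds <- ppi_dataset(m, c("positive", "positive", "negative", "negative"))
  expect_equal(nonzero_fraction_profile(ds), fr)
})
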