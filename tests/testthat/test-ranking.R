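test_that("wilcoxon_score matches the hand-computed rank-sum z", {
  expect_equal(wilcoxon_score(c(1, 2, 3), c(4, 5, 6)), 4.5 / sqrt(5.25),
               tolerance = 1e-12)
  expect_equal(wilcoxon_score(c(5, 5, 5), c(5, 5, 5)), 0)
  # invariance under strictly monotone transforms of the pooled values
  a <- tvpac:::with_seed(1, rnorm(9))
  b <- tvpac:::with_seed(2, rnorm(6) + 0.4)
  f <- function(x) exp(2 * x) - 1
  expect_equal(wilcoxon_score(a, b), wilcoxon_score(f(a), f(b)),
               tolerance = 1e-12)
  expect_error(wilcoxon_score(1, c(2, 3)), ">= 2")
})

test_that("vectorised engine agrees with wilcoxon_score, ties included", {
  X <- tvpac:::with_seed(3, matrix(rnorm(18 * 40), 18))
  X[, 1:5] <- round(X[, 1:5])            # heavy cross-subject value ties
  X[3, ] <- X[7, ]                       # duplicated subject rows
  lab <- rep(c("patient", "control"), c(10, 8))
  tab <- bootstrap_wscore_star(feature_matrix(X, lab), n_boot = 20, seed = 1)
  direct <- apply(X, 2, function(col) wilcoxon_score(col[1:10], col[11:18]))
  expect_equal(tab$wscore_full, direct, tolerance = 1e-12)
})

test_that("bootstrap ranking is deterministic and finds a planted feature", {
  fm <- gauss_fm(n_a = 12, n_b = 8, p = 40, n_signal = 1, delta = 3, seed = 2)
  t1 <- bootstrap_wscore_star(fm, n_boot = 100, seed = 7)
  t2 <- bootstrap_wscore_star(fm, n_boot = 100, seed = 7)
  expect_identical(t1, t2)
  expect_equal(t1$rank[1], 1L)

  # spec-scale design: one feature at 5 pooled-sd vs 200 noise features,
  # 25 + 15 subjects, n_boot = 200 -> rank 1 in at least 95 of 100 seeds
  hits <- vapply(1:100, function(s) {
    fm_s <- gauss_fm(n_a = 25, n_b = 15, p = 201, n_signal = 1, delta = 5,
                     seed = 1000 + s)
    tab <- bootstrap_wscore_star(fm_s, n_boot = 200, seed = s)
    tab$rank[1] == 1L
  }, logical(1))
  expect_gte(sum(hits), 95L)
})

test_that("zero-variance features are flagged and ranked last", {
  fm <- gauss_fm(n_a = 6, n_b = 6, p = 10, n_signal = 0, seed = 4)
  fm$features[, 10] <- 1.0               # constant: score 0 in every replicate
  tab <- bootstrap_wscore_star(fm, n_boot = 50, seed = 3)
  expect_true(is.na(tab$wscore_star[10]))
  expect_equal(tab$rank[10], 10L)
})

test_that("max Wscore* under permuted labels matches an independent oracle", {
  X <- tvpac:::with_seed(11, matrix(rnorm(15 * 25), 15))
  n_a <- 8L
  # slow, direct re-implementation: per replicate, rank() per feature and the
  # tie-corrected z by the textbook formula
  oracle_star <- function(Xp, labs, n_boot, seed) {
    ia <- which(labs == "a")
    ib <- which(labs == "b")
    sc <- matrix(0, n_boot, ncol(Xp))
    tvpac:::with_seed(seed, {
      for (r in seq_len(n_boot)) {
        idx <- c(sample(ia, length(ia), TRUE), sample(ib, length(ib), TRUE))
        for (f in seq_len(ncol(Xp))) {
          sc[r, f] <- wilcoxon_score(Xp[idx[seq_along(ia)], f],
                                     Xp[idx[-seq_along(ia)], f])
        }
      }
    })
    max(colMeans(sc) / apply(sc, 2, sd))
  }
  draws <- 60L
  ours <- numeric(draws)
  theirs <- numeric(draws)
  for (d in seq_len(draws)) {
    labs <- tvpac:::with_seed(500 + d, sample(rep(c("a", "b"), c(n_a, 7))))
    fm <- feature_matrix(X, labs)
    tab <- bootstrap_wscore_star(fm, n_boot = 60, seed = 900 + d)
    ours[d] <- max(tab$wscore_star, na.rm = TRUE)
    theirs[d] <- oracle_star(X, labs, n_boot = 60, seed = 4000 + d)
  }
  expect_gt(stats::ks.test(ours, theirs)$p.value, 0.01)
})

test_that("select_top returns ranked ids with documented tie handling", {
  fm <- gauss_fm(n_a = 8, n_b = 8, p = 12, n_signal = 2, delta = 4, seed = 6)
  tab <- bootstrap_wscore_star(fm, n_boot = 80, seed = 2)
  top2 <- select_top(tab, 2)
  expect_length(top2, 2L)
  expect_setequal(unname(top2), c(1L, 2L))
  all_p <- select_top(tab, nrow(tab))
  expect_equal(unname(all_p), order(tab$rank))
  expect_error(select_top(tab, 13), "top 13")
})

test_that("ranking is invariant to feature rescaling", {
  fm <- gauss_fm(n_a = 9, n_b = 7, p = 30, n_signal = 2, delta = 2, seed = 8)
  fm2 <- fm
  fm2$features <- sweep(fm$features, 2, seq(0.1, 3, length.out = 30), "*")
  t1 <- bootstrap_wscore_star(fm, n_boot = 60, seed = 5)
  t2 <- bootstrap_wscore_star(fm2, n_boot = 60, seed = 5)
  expect_equal(t1$rank, t2$rank)
  expect_equal(t1$wscore_star, t2$wscore_star, tolerance = 1e-12)
})

test_that("sweep_p traces accuracy against feature count", {
  fm <- gauss_fm(n_a = 10, n_b = 10, p = 30, n_signal = 5, delta = 2.5,
                 seed = 9)
  ps <- c(1, 3, 5, 10, 20)
  curve <- sweep_p(fm, ps, scheme = "loocv", mode = "paper_faithful",
                   n_boot = 50, seed = 3)
  expect_equal(curve$p, ps)
  expect_length(curve$accuracy, 5L)
  # consistency: the p = 1 point equals a directly run single-feature loocv
  direct <- loocv(fm, p = 1, mode = "paper_faithful", n_boot = 50, seed = 3)
  expect_equal(curve$accuracy[1], direct$accuracy)
  # separable design: accuracy rises to the true feature count, then stays
  # within noise of its plateau
  expect_gte(curve$accuracy[3], curve$accuracy[1])
  expect_gte(min(curve$accuracy[4:5]), curve$accuracy[3] - 0.15)
})
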