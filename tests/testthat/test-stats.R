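# Univariate tests, permutation pseudo-F, LDA.

test_that("unpaired t handles degenerate and separated samples and matches
           the definition-level oracle", {
  r <- unpaired_t(c(1, 1, 1, 1), rep(c("a", "b"), each = 2L))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(61)
  x <- rnorm(30); y <- rnorm(30, 5)
  r2 <- unpaired_t(c(x, y), rep(c("a", "b"), each = 30L))
  expect_lt(r2$p_value, 1e-6)
  o <- welch_t_oracle(x, y)
  expect_equal(r2$statistic, o$t, tolerance = 1e-12)
  expect_equal(r2$p_value, o$p, tolerance = 1e-12)
  expect_error(unpaired_t(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA + Tukey separates distinct groups and matches the
           studentized-range oracle", {
  set.seed(62)
  g <- rep(c("a", "b", "c"), each = 8L)
  v <- rep(c(0, 1, 2), each = 8L) + rnorm(24, 0, 1e-3)
  r <- anova_tukey(v, g)
  expect_true(r$significant)
  expect_true(all(r$details$p_adj < 0.001))
  # oracle comparison on noisy balanced data
  v2 <- rnorm(24) + rep(c(0, 0.5, 0.2), each = 8L)
  r2 <- anova_tukey(v2, g)
  oracle <- tukey_oracle(v2, g)
  got <- setNames(r2$details$p_adj, r2$details$pair)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-8)
  expect_error(anova_tukey(c(1, 2, 3), c("a", "b", "c")), "n >= 2")
})

test_that("null ANOVA rarely flags equal-mean groups", {
  set.seed(63)
  hits <- vapply(1:60, function(i) {
    v <- rnorm(30)
    anova_tukey(v, rep(c("a", "b", "c"), each = 10L))$significant
  }, logical(1L))
  expect_lt(mean(hits), 0.15)
})

test_that("Pearson correlation matches its definition and flags exact
           linear relations", {
  x <- 1:20
  r <- pearson_ci(x, 2 * x)
  expect_equal(r$statistic, 1)
  expect_equal(r$conf_int[2L], 1)
  set.seed(64)
  a <- rnorm(50); b <- -a + rnorm(50, 0, 0.01)
  r2 <- pearson_ci(a, b)
  expect_lt(r2$statistic, -0.99)
  expect_equal(r2$statistic, pearson_oracle(a, b), tolerance = 1e-12)
  expect_error(pearson_ci(1:3, 2:4), "n >= 4")
  expect_error(pearson_ci(rep(1, 10), 1:10), "variance")
})

test_that("permutation pseudo-F matches the PERMANOVA implementation in
           vegan and saturates at the attainable minimum", {
  skip_if_not_installed("vegan")
  set.seed(65)
  M <- matrix(rnorm(40 * 6), 40)
  M[1:20, 1L] <- M[1:20, 1L] + 5
  g <- rep(c("a", "b"), each = 20L)
  ours <- permutation_anova(M, g, n_perm = 999L, seed = 2L,
                            standardize = FALSE)
  veg <- vegan::adonis2(dist(M) ~ g, permutations = 999L)
  expect_equal(ours$statistic, veg$F[1L], tolerance = 1e-10)
  expect_lt(abs(ours$p_value - veg$`Pr(>F)`[1L]), 0.03)
  expect_equal(ours$p_value, 0.001)   # saturated: observed beats all perms
})

test_that("permutation test is deterministic, guards degenerate input and
           validates group sizes", {
  set.seed(66)
  M <- matrix(rnorm(30 * 4), 30)
  g <- rep(c("a", "b", "c"), each = 10L)
  r1 <- permutation_anova(M, g, n_perm = 199L, seed = 5L)
  r2 <- permutation_anova(M, g, n_perm = 199L, seed = 5L)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$perm_F, r2$perm_F)
  rd <- permutation_anova(matrix(1, 12, 3), rep(c("a", "b"), each = 6L),
                          n_perm = 99L)
  expect_equal(rd$p_value, 1)
  expect_true(rd$degenerate)
  expect_error(permutation_anova(M, c(rep("a", 28L), "b", "b"), n_perm = 99L),
               "n >= 3")
})

test_that("block-aware permutation keeps paired rows together", {
  set.seed(67)
  n_fish <- 20L
  fish <- rep(seq_len(n_fish), each = 2L)
  cls <- rep(rep(c("a", "b"), each = n_fish / 2L), each = 2L)
  # fish-level random effect only: class is null but rows are paired
  fx <- rnorm(n_fish, 0, 1)
  M <- matrix(fx[fish] + rnorm(2L * n_fish, 0, 0.2), ncol = 1L)
  ps <- vapply(1:40, function(i) {
    fx <- rnorm(n_fish, 0, 1)
    M <- matrix(fx[fish] + rnorm(2L * n_fish, 0, 0.2), ncol = 1L)
    permutation_anova(M, cls, n_perm = 99L, seed = i,
                      blocks = fish)$p_value
  }, numeric(1L))
  # calibrated: roughly uniform p under the blocked null
  expect_lt(mean(ps <= 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})

test_that("LDA separates well-separated classes and sits at chance on
           shuffled labels", {
  set.seed(68)
  x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1L)
  g <- rep(c("lo", "hi"), each = 20L)
  fit <- oto_lda(x, g)
  expect_equal(fit$accuracy, 1.0)
  expect_equal(as.integer(rowSums(fit$confusion)),
               as.integer(table(factor(g))))
  gs <- sample(g)
  fit2 <- oto_lda(x, gs)
  # chance-level: within the binomial 95% band around 0.5
  band <- qbinom(c(0.025, 0.975), 40L, 0.5) / 40
  expect_gte(fit2$accuracy, band[1L] - 0.075)
  expect_lte(fit2$accuracy, band[2L] + 0.075)
})

test_that("LDA scores are invariant to affine column rescaling up to sign", {
  set.seed(69)
  X <- matrix(rnorm(60 * 4), 60)
  X[1:30, 2L] <- X[1:30, 2L] + 1.5
  g <- rep(c("a", "b"), each = 30L)
  f1 <- oto_lda(X, g)
  f2 <- oto_lda(sweep(X, 2L, c(10, 0.1, 3, 0.5), "*"), g)
  s1 <- f1$scores[, 1L]; s2 <- f2$scores[, 1L]
  if (cor(s1, s2) < 0) s2 <- -s2
  expect_equal(s1, s2, tolerance = 1e-6)
  expect_equal(f1$accuracy, f2$accuracy)
})

test_that("LDA applies a PCA reduction when coefficients outnumber
           specimens", {
  set.seed(70)
  X <- matrix(rnorm(30 * 50), 30)
  X[1:15, 1:5] <- X[1:15, 1:5] + 3
  g <- rep(c("a", "b"), each = 15L)
  fit <- oto_lda(X, g)
  expect_false(is.null(fit$pca))
  expect_gt(fit$accuracy, 0.8)
})
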