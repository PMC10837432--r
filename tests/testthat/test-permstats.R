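test_that("euclidean distance matches a brute-force double loop", {
  d <- as.matrix(euclidean_dist(c(0, 3, 4)))
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 4)
  expect_equal(d[2, 3], 1)
  expect_true(all(diag(d) == 0))

  x <- matrix(c(1, 1, 1, 2, 2, 2), 2, 3, byrow = TRUE)
  expect_true(all(as.matrix(euclidean_dist(rbind(x[1, ], x[1, ]))) == 0))

  set.seed(3)
  y <- matrix(stats::rnorm(15), 5, 3)
  got <- as.matrix(euclidean_dist(y))
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) brute[i, j] <- sqrt(sum((y[i, ] - y[j, ])^2))
  expect_equal(got, brute, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(euclidean_dist(c(1, NA, 2)), "non-finite")
})

test_that("pseudo-F on {1,2,3} vs {4,5,6} equals 13.5 with exhaustive p = 0.1", {
  fit <- permanova(euclidean_dist(1:6), factor(rep(c("a", "b"), each = 3)))
  expect_equal(fit$pseudo_F, 13.5, tolerance = 1e-9)
  expect_identical(fit$method, "exhaustive")
  expect_equal(fit$n_perm, 20L)   # C(6,3) distinct arrangements
  expect_equal(fit$p_perm, 0.1)   # 2 of 20 arrangements reach 13.5
  expect_equal(fit$tab$SS[3], 17.5) # sum d^2 / n
})

test_that("univariate pseudo-F equals the classical one-way ANOVA F", {
  set.seed(42)
  for (i in 1:20) {
    a <- sample(2:4, 1)
    n_per <- sample(3:6, a, replace = TRUE)
    g <- factor(rep(seq_len(a), n_per))
    x <- stats::rnorm(length(g), mean = as.integer(g))
    f_classic <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
    fit <- permanova(euclidean_dist(x), g, permutations = 19)
    expect_equal(fit$pseudo_F, f_classic, tolerance = 1e-9)
  }
})

test_that("degenerate all-identical input reports F = 0 and p = 1", {
  fit <- permanova(euclidean_dist(rep(2, 6)), factor(rep(1:2, each = 3)))
  expect_true(fit$degenerate)
  expect_equal(fit$pseudo_F, 0)
  expect_equal(fit$p_perm, 1)
})

test_that("permutation p is confined to [1/(B+1), 1] and honors the +1 rule", {
  set.seed(9)
  x <- stats::rnorm(24)
  g <- factor(rep(1:2, each = 12)) # 2704156 arrangements -> sampled
  fit <- permanova(euclidean_dist(x), g, permutations = 99)
  expect_identical(fit$method, "unique-sampled")
  expect_gte(fit$p_perm, 1 / 100)
  expect_lte(fit$p_perm, 1)
  # strong separation: observed F exceeds all permutations -> p = 1/(B+1)
  y <- c(stats::rnorm(12), stats::rnorm(12) + 100)
  fit2 <- permanova(euclidean_dist(y), g, permutations = 99)
  expect_equal(fit2$p_perm, 1 / 100)
})

test_that("Monte-Carlo and exhaustive permutation p agree within binomial error", {
  set.seed(5)
  x <- c(stats::rnorm(8), stats::rnorm(8) + 1.2)
  g <- factor(rep(1:2, each = 8)) # 12870 arrangements -> sampled at B = 999
  fit <- permanova(euclidean_dist(x), g, permutations = 999, seed = 17)
  expect_identical(fit$method, "unique-sampled")
  # exact null by full enumeration (independent of the sampling path)
  arr <- isopulse:::multiset_arrangements(c(8L, 8L))
  f_all <- isopulse:::pseudo_f_cols(as.matrix(euclidean_dist(x))^2, arr,
                                    c(8L, 8L))$F
  p_exact <- mean(f_all >= fit$pseudo_F - 1e-12)
  expect_lt(abs(fit$p_perm - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 999) + 1 / 1000)
})

test_that("sequential multi-factor pseudo-F matches vegan::adonis2 by terms", {
  skip_if_not_installed("vegan")
  set.seed(21)
  n <- 24
  fac <- data.frame(
    species = factor(sample(letters[1:3], n, replace = TRUE)),
    timepoint = factor(sample(c("T3", "T6"), n, replace = TRUE))
  )
  for (p in c(1, 3)) {
    x <- matrix(stats::rnorm(n * p), n, p) +
      as.integer(fac$species) %o% rep(0.8, p)
    d <- euclidean_dist(x)
    fit <- permanova(d, fac, permutations = 99, seed = 2)
    ref <- vegan::adonis2(stats::dist(x) ~ species + timepoint, data = fac,
                          permutations = 99, by = "terms")
    expect_equal(fit$tab$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
    expect_equal(fit$tab$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
    expect_equal(fit$tab$df[1:2], ref$Df[1:2])
  }
})

test_that("single-factor pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(33)
  x <- stats::rnorm(18, mean = rep(c(0, 1, 3), each = 6))
  g <- factor(rep(1:3, each = 6))
  fit <- permanova(euclidean_dist(x), g, permutations = 99)
  ref <- vegan::adonis2(stats::dist(x) ~ g, permutations = 99)
  expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-9)
})

test_that("pairwise tests cover all pairs with Bonferroni capping", {
  set.seed(13)
  x <- c(stats::rnorm(5), stats::rnorm(5), stats::rnorm(5) + 30)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  pw <- pairwise_permanova(euclidean_dist(x), g, permutations = 999)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, pw$p_perm * 3))
  # only the two pairs involving the divergent group are significant
  divergent <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adj[divergent] < 0.05))
  expect_true(all(pw$p_adj[!divergent] > 0.05))
})

test_that("Kruskal-Wallis complete separation at n = (3,3) gives H = 27/7", {
  k <- kruskal_wallis(list(c(1.2, 2.3, 3.1), c(10, 11, 12)))
  expect_equal(k$H, 27 / 7, tolerance = 1e-12)
  expect_equal(round(k$H, 3), 3.857)
  expect_equal(k$df, 1L)
  # chi-squared approximation and exact enumeration disagree at this n;
  # both are reported
  expect_equal(k$p_chi2, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
  expect_equal(k$p_exact, 2 / 20)
})

test_that("tie-corrected H matches stats::kruskal.test on random data", {
  set.seed(19)
  for (i in 1:15) {
    g <- factor(rep(1:3, times = sample(3:7, 3, replace = TRUE)))
    x <- sample(1:6, length(g), replace = TRUE) # heavy ties
    k <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, g)
    expect_equal(k$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(k$p_chi2, ref$p.value, tolerance = 1e-12)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- stats::rnorm(12)
  g <- factor(rep(1:2, each = 6))
  h0 <- kruskal_wallis(x, g)$H
  expect_equal(kruskal_wallis(exp(x), g)$H, h0)
  expect_equal(kruskal_wallis(x^3, g)$H, h0)
})

test_that("Kruskal-Wallis degenerate and error cases", {
  k <- kruskal_wallis(list(c(1, 1, 1), c(1, 1)))
  expect_true(k$degenerate)
  expect_equal(k$H, 0)
  expect_error(kruskal_wallis(c(1, 2), factor(c("a", "a"))), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))))
})

test_that("Welch t matches stats::t.test and behaves monotonically in shift", {
  set.seed(29)
  for (i in 1:10) {
    a <- stats::rnorm(sample(3:8, 1))
    b <- stats::rnorm(sample(3:8, 1), sd = 2)
    w <- welch_t(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
  a <- c(1, 2, 3)
  expect_equal(welch_t(a, a)$t, 0)
  expect_equal(welch_t(a, a)$p, 1)
  tt <- vapply(c(1, 5, 25), function(s) abs(welch_t(a, a + s)$t), numeric(1))
  expect_true(all(diff(tt) > 0))
  expect_true(welch_t(c(1, 1), c(1, 1))$degenerate)
})
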