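# Evaluation metric and multivariate population statistics.

test_that("MAPE matches its elementwise definition", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(100, 110), 10)
  set.seed(51)
  tr <- runif(20, 1, 10); es <- tr + rnorm(20)
  expect_equal(mape(tr, es), mean(abs(es - tr) / abs(tr)) * 100)
  expect_error(mape(c(1, 0), c(1, 1)), "nonzero")
})

test_that("coefficient of variation is scale invariant", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(52)
  x <- runif(30, 1, 5)
  expect_equal(coefficient_of_variation(7 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("polymerized tubulin is the count-length product", {
  expect_equal(polymerized_tubulin(250, 30), 7500)
  expect_equal(polymerized_tubulin(0, 12), 0)
  # consistency with the sampled length total at those parameters
  set.seed(53)
  tot <- mean(replicate(200, sum(sample_lengths(50, 10, 2))))
  expect_lt(abs(tot - polymerized_tubulin(50, 10)) / 500, 0.1)
})

test_that("Hotelling's T2 agrees with the direct matrix formula", {
  set.seed(54)
  a <- matrix(rnorm(40), 20, 2)
  b <- matrix(rnorm(50, mean = 0.6), 25, 2)
  h <- hotelling_t2(a, b)
  # independent evaluation
  dm <- colMeans(a) - colMeans(b)
  sp <- (19 * cov(a) + 24 * cov(b)) / 43
  t2 <- 20 * 25 / 45 * drop(t(dm) %*% solve(sp) %*% dm)
  expect_equal(h$T2, t2, tolerance = 1e-8)
  fstat <- (45 - 2 - 1) / (2 * 43) * t2
  expect_equal(h$p, pf(fstat, 2, 42, lower.tail = FALSE), tolerance = 1e-8)

  same <- hotelling_t2(a, a)
  expect_equal(same$T2, 0)
  expect_equal(same$p, 1)

  degen <- cbind(1:5, 2 * (1:5))  # collinear columns
  expect_error(hotelling_t2(degen, degen), "singular")
})

test_that("Hotelling's T2 type-I error is calibrated under the null", {
  set.seed(55)
  rej <- mean(replicate(500, {
    hotelling_t2(matrix(rnorm(70), 35, 2),
                 matrix(rnorm(70), 35, 2))$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Box's M matches the log-determinant formula and is calibrated", {
  set.seed(56)
  gs <- list(matrix(rnorm(60), 30, 2), matrix(rnorm(50), 25, 2),
             matrix(rnorm(40), 20, 2))
  bm <- box_m_test(gs)
  ns <- c(30, 25, 20); N <- sum(ns); k <- 3; p <- 2
  covs <- lapply(gs, cov)
  sp <- Reduce(`+`, Map(function(s, n) (n - 1) * s, covs, ns)) / (N - k)
  M <- (N - k) * log(det(sp)) -
    sum((ns - 1) * vapply(covs, function(s) log(det(s)), 0))
  expect_equal(bm$M, M, tolerance = 1e-10)
  cc <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  expect_equal(bm$chi_sq, M * (1 - cc), tolerance = 1e-10)
  expect_equal(bm$df, 6)

  ident <- box_m_test(list(gs[[1]], gs[[1]], gs[[1]]))
  expect_equal(ident$M, 0, tolerance = 1e-10)

  # null calibration: p-values roughly uniform
  set.seed(57)
  ps <- replicate(200, {
    box_m_test(list(matrix(rnorm(70), 35, 2),
                    matrix(rnorm(70), 35, 2)))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("pairwise comparisons subsample, correct, and stay in [0, 1]", {
  # same-distribution groups: adjusted p near 1 across seeded runs
  # (data redrawn per run)
  ok <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    tb <- data.frame(group = rep(c("A", "B"), each = 60),
                     x = rnorm(120), y = rnorm(120))
    pairwise_compare(tb, c("x", "y"), 35, 100, seed = s)$p_adjusted > 0.5
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  set.seed(58)
  tab <- data.frame(group = rep(c("A", "B"), each = 60),
                    x = rnorm(120), y = rnorm(120))
  # separated means are detected
  tab2 <- tab
  tab2$x[tab2$group == "B"] <- tab2$x[tab2$group == "B"] + 3
  res2 <- pairwise_compare(tab2, c("x", "y"), 35, 100, seed = 1)
  expect_lt(res2$p_adjusted, 0.05)

  # symmetric in group order under the same seed policy
  tab_rev <- tab2[rev(seq_len(nrow(tab2))), ]
  res_rev <- pairwise_compare(tab_rev, c("x", "y"), 35, 100, seed = 1)
  expect_equal(res2$p_adjusted, res_rev$p_adjusted)
  expect_equal(res2$T2, res_rev$T2)

  # group smaller than the subsample is named in the error
  small <- data.frame(group = rep(c("A", "B"), c(60, 10)),
                      x = rnorm(70), y = rnorm(70))
  expect_error(pairwise_compare(small, c("x", "y"), 35, 10, 1), "B")
})

test_that("cluster trees merge the closest groups first and emit Newick", {
  m <- matrix(c(0, 1, 8, 1, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ct <- cluster_tree(m)
  expect_identical(sort(ct$tree$merge[1, ]), c(-2L, -1L))  # A,B first
  ph <- ape::read.tree(text = ct$newick)
  expect_identical(sort(ph$tip.label), c("A", "B", "C"))

  # agrees with a hand-rolled UPGMA on random matrices (cophenetic check)
  set.seed(59)
  for (i in 1:5) {
    n <- 5
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 10)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    got <- cophenetic(cluster_tree(d)$tree)
    want <- cophenetic(hclust(as.dist(d), method = "average"))
    expect_equal(got, want)
  }

  asym <- m; asym[1, 2] <- 5
  expect_error(cluster_tree(asym), "symmetric")
})

test_that("rank-2 data is represented exactly by the first two PCs", {
  set.seed(60)
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  scores <- cbind(rnorm(40, sd = 3), rnorm(40))
  x <- scores %*% t(basis)
  p <- pca_first_two(x)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(x)),
               tolerance = 1e-6)
  # sign convention: largest-magnitude loading positive
  pc <- prcomp(x, center = TRUE)
  for (j in 1:2) {
    l <- pc$rotation[, j] * sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    got <- cov(p$scores[, j], x %*% l)
    expect_gt(got, 0)
  }
  expect_error(pca_first_two(matrix(rep(1:10, 3), 10, 3)), "rank")
})

test_that("correlate is Pearson's r with guarded variance", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  set.seed(61)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(correlate(a, b),
               mean((a - mean(a)) * (b - mean(b))) /
                 (sd(a) * sd(b)) * 25 / 24)
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
})
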