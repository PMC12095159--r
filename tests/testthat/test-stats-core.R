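test_that("Mann-Whitney exact p matches enumeration on fixed examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)          # 2 * (1 / choose(6, 3))
  expect_equal(r$method, "exact")

  # identical multisets carry no evidence
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r2$p_value, 0.99)
})

test_that("Mann-Whitney exact p equals brute-force enumeration on random tie-free inputs", {
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    v <- sample(seq_len(50), n1 + n2)   # distinct values: tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    for (alt in c("two.sided", "greater", "less")) {
      r <- mann_whitney_u(x, y, alternative = alt)
      expect_equal(r$method, "exact")
      expect_equal(r$p_value, mwu_enum_oracle(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney two-sided p is invariant under swapping the samples", {
  set.seed(5)
  x <- rnorm(6); y <- rnorm(5)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  # also in the approximate regime
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
})

test_that("Mann-Whitney approximation agrees with the reference implementation", {
  set.seed(7)
  x <- round(rnorm(15), 1); y <- round(rnorm(20, 0.5), 1)  # ties likely
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "approximate")
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman matches the rank formula and handles degenerate input", {
  expect_equal(spearman(1:4, 1:4)$rho, 1)
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  # d = (-1, 1, -1, 1): rho = 1 - 6*4 / (4*15)
  r <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  ref <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman")
  expect_equal(r$rho, unname(ref$estimate))

  const <- spearman(c(1, 1, 1), c(1, 2, 3))
  expect_true(const$flagged)
  expect_true(is.na(const$rho))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman(rank(x), y)$rho, base$rho)
})

test_that("Fisher exact 2x2 equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 2, 2), 2)), "non-negative")

  # transpose invariance + agreement with the reference implementation
  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 5), 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_exact_2x2(t(tab))$p_value)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("ROC-AUC equals pair counting and the U statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    s <- rnorm(n1 + n0); y <- c(rep(1, n1), rep(0, n0))
    u <- mann_whitney_u(s[y == 1], s[y == 0])$statistic
    expect_equal(roc_auc(s, y), u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC-AUC of negated tie-free scores is the complement", {
  set.seed(22)
  s <- rnorm(30); y <- rbinom(30, 1, 0.4)
  y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
})

test_that("PR-AUC is average precision", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked last among 4
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  # random scores: expectation near the positive prevalence
  set.seed(31)
  vals <- replicate(200, {
    y <- c(rep(1, 50), rep(0, 150))
    pr_auc(rnorm(200), y)
  })
  expect_lt(abs(mean(vals) - 0.25), 0.05)
})

test_that("threshold metrics follow confusion-matrix arithmetic", {
  perfect <- threshold_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  none <- threshold_metrics(c(0.1, 0.2, 0.3, 0.4), c(1, 0, 1, 0))
  expect_equal(none$recall, 0)
  expect_equal(none$accuracy, 0.5)     # negative prevalence
  expect_false(none$precision_defined)

  mid <- threshold_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(unlist(mid[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))
})

test_that("OLS matches a pseudo-inverse oracle and flags collinearity", {
  x <- 1:10
  fit <- ols_fit(2 * x, cbind(intercept = 1, x = x))
  expect_equal(fit$estimate, c(0, 2), tolerance = 1e-10)

  set.seed(41)
  X <- cbind(1, matrix(rnorm(60), 20, 3))
  colnames(X) <- c("i", "a", "b", "c")
  y <- rnorm(20)
  fit <- ols_fit(y, X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$estimate, as.numeric(beta_oracle), tolerance = 1e-10)
  ref <- summary(lm(y ~ 0 + X))$coefficients
  expect_equal(fit$std_error, unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(fit$p_value, unname(ref[, 4]), tolerance = 1e-10)

  Xd <- cbind(X, dup = X[, "a"])
  expect_error(ols_fit(y, Xd), "rank deficient")
})
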