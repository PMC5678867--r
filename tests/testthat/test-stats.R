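test_that("contingency tests reproduce printed and degenerate cases", {
  pass_tab <- matrix(c(35, 3, 22, 12), 2, byrow = TRUE)
  res <- contingency_test(pass_tab, "yates")
  expect_equal(round(res$p_value, 2), 0.01)
  flat <- contingency_test(matrix(c(10, 10, 10, 10), 2), "yates")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})

test_that("Fisher's exact P matches full hypergeometric enumeration", {
  tabs <- list(matrix(c(51, 6, 10, 5), 2, byrow = TRUE),
               matrix(c(3, 7, 8, 2), 2, byrow = TRUE),
               matrix(c(1, 9, 5, 5), 2, byrow = TRUE))
  for (tab in tabs) {
    expect_equal(contingency_test(tab, "fisher")$p_value,
                 fisher_oracle_2x2(tab), tolerance = 1e-8)
  }
})

test_that("auto method applies the small-expected-count switch", {
  small <- matrix(c(51, 6, 10, 5), 2, byrow = TRUE)  # expected min < 5
  expect_equal(contingency_test(small, "auto")$method, "fisher")
  big <- matrix(c(35, 3, 22, 12), 2, byrow = TRUE)
  expect_equal(contingency_test(big, "auto")$method, "yates")
  rxc <- matrix(c(20, 10, 5, 10, 20, 7), 2, byrow = TRUE)
  expect_equal(contingency_test(rxc, "auto")$method, "pearson")
})

test_that("Yates statistic never exceeds the Pearson statistic on 2x2", {
  withr::with_seed(7, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 12) + 1, 2)
      y <- contingency_test(tab, "yates")
      p <- contingency_test(tab, "pearson")
      expect_lte(y$statistic, p$statistic + 1e-12)
      expect_true(y$p_value >= 0 && y$p_value <= 1)
      expect_true(p$p_value >= 0 && p$p_value <= 1)
    }
  })
})

test_that("Mann-Whitney comparison matches the permutation oracle", {
  # identical groups: U at its null mean, P = 1
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 4.5)
  expect_equal(res$p_value, 1)
  # exact small-sample route vs brute-force enumeration
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  withr::with_seed(11, {
    for (i in 1:5) {
      a <- sample(100, 5)
      b <- sample(100, 6) + 30
      expect_equal(compare_groups(a, b)$p_value, mw_exact_oracle(a, b),
                   tolerance = 1e-10)
    }
  })
})

test_that("degenerate and t-test comparisons behave as documented", {
  expect_warning(res <- compare_groups(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  tt <- compare_groups(c(1, 2, 3, 4), c(3, 4, 5, 6), "t_test")
  expect_lt(tt$p_value, 1)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
  expect_error(compare_groups(1, c(2, 3), "t_test"), "at least 2")
})

test_that("Cox fit matches the closed-form and symmetric cases", {
  d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 0), x = c(1, 0, 1))
  fit <- fit_cox(d, "t", "e", "x")
  expect_equal(fit$hr, 2^(-1 / 2), tolerance = 1e-5)
  expect_equal(fit$conf_low, exp(fit$estimate - 1.96 * fit$std_error))
  expect_equal(fit$conf_high, exp(fit$estimate + 1.96 * fit$std_error))
  sym <- data.frame(t = c(1, 1, 2, 2), e = 1, x = c(1, 0, 0, 1))
  expect_equal(fit_cox(sym, "t", "e", "x")$estimate, 0, tolerance = 1e-8)
})

test_that("Cox fit agrees with the grid-search partial-likelihood oracle", {
  for (fx in cox_small_fixtures()) {
    d <- data.frame(t = fx$time, e = fx$event, x = fx$x)
    beta_hat <- fit_cox(d, "t", "e", "x")$estimate
    beta_grid <- cox_grid_oracle(fx$time, fx$event, fx$x)
    expect_lt(abs(beta_hat - beta_grid), 1e-4)
  }
})

test_that("Cox fit refuses separation and degenerate covariates", {
  # every event in the x = 1 group: monotone likelihood
  sep <- data.frame(t = c(1, 2, 3, 4, 5, 6),
                    e = c(1, 1, 1, 0, 0, 0),
                    x = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(sep, "t", "e", "x"), "separation")
  zv <- data.frame(t = 1:4, e = c(1, 0, 1, 0), x = 1)
  expect_error(fit_cox(zv, "t", "e", "x"), "zero-variance")
  noev <- data.frame(t = 1:4, e = 0, x = c(0, 1, 0, 1))
  expect_error(fit_cox(noev, "t", "e", "x"), "event")
})

test_that("multivariate Cox fits all covariates jointly", {
  withr::with_seed(5, {
    d <- data.frame(t = rexp(60, 0.1),
                    e = rbinom(60, 1, 0.7),
                    x1 = rbinom(60, 1, 0.5),
                    x2 = rnorm(60))
    fit <- fit_cox(d, "t", "e", c("x1", "x2"))
    expect_equal(nrow(fit), 2)
    expect_equal(fit$term, c("x1", "x2"))
    expect_true(all(fit$conf_low <= fit$hr & fit$hr <= fit$conf_high))
  })
})

test_that("AUC equals exhaustive pair counting and the U statistic", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 0, 1, 1))$auc, 0.5)
  s <- c(3, 1, 2, 4, 2)
  l <- c(0, 0, 1, 1, 0)
  expect_equal(roc_auc(s, l)$auc, auc_pair_oracle(s, l))
  withr::with_seed(21, {
    for (i in 1:10) {
      scores <- sample(0:6, 30, replace = TRUE)
      labels <- rbinom(30, 1, 0.4)
      if (length(unique(labels)) < 2) next
      r <- roc_auc(scores, labels)
      expect_equal(r$auc, auc_pair_oracle(scores, labels))
      # algebraic identity with the Mann-Whitney U of positives vs negatives
      u <- compare_groups(scores[labels == 1],
                          scores[labels == 0])$statistic
      expect_equal(r$auc, u / (sum(labels) * sum(!labels)))
    }
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC operating points are monotone in the cutoff", {
  withr::with_seed(3, {
    r <- roc_auc(rnorm(40), rbinom(40, 1, 0.5))
    expect_true(all(diff(r$points$sensitivity) <= 0))
    expect_true(all(diff(r$points$specificity) >= 0))
    expect_true(all(r$points$sensitivity >= 0 & r$points$sensitivity <= 1))
  })
})

test_that("DeLong comparison is antisymmetric and handles identity", {
  same <- delong_compare(c(1, 2, 3, 4), c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  withr::with_seed(9, {
    lab <- rep(c(0, 1), each = 20)
    s1 <- lab + rnorm(40)
    s2 <- 0.5 * lab + rnorm(40)
    ab <- delong_compare(s1, s2, lab)
    ba <- delong_compare(s2, s1, lab)
    expect_equal(ab$difference, -ba$difference)
    expect_equal(ab$p_value, ba$p_value)
  })
})

test_that("DeLong results agree with the reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (i in 1:5) {
      lab <- rep(c(0, 1), times = c(25, 15))
      latent <- lab * runif(1, 0.5, 1.5)
      s1 <- latent + rnorm(40)
      s2 <- latent + rnorm(40)
      ours <- delong_compare(s1, s2, lab)
      r1 <- pROC::roc(lab, s1, quiet = TRUE, direction = "<")
      r2 <- pROC::roc(lab, s2, quiet = TRUE, direction = "<")
      ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
      expect_equal(ours$auc_1, as.numeric(pROC::auc(r1)))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Youden cutoff matches brute force with smallest-cutoff ties", {
  expect_equal(youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))$cutoff, 3)
  expect_equal(youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))$j, 1)
  flat <- youden_cutoff(c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(flat$cutoff, 1)
  expect_equal(flat$j, 0)
  brute <- function(scores, labels) {
    cands <- sort(unique(scores))
    js <- vapply(cands, function(c) {
      mean(scores[labels == 1] >= c) + mean(scores[labels == 0] < c) - 1
    }, numeric(1))
    c(cutoff = cands[which.max(js)], j = max(js))
  }
  cases <- list(
    list(s = c(0, 1, 2, 2, 3, 4), l = c(0, 0, 0, 1, 1, 1)),
    list(s = c(5, 1, 3, 2, 4, 2, 0), l = c(1, 0, 1, 0, 1, 1, 0)))
  withr::with_seed(31, {
    for (i in 1:5) {
      cases[[length(cases) + 1]] <- list(s = sample(0:8, 25, TRUE),
                                         l = rbinom(25, 1, 0.4))
    }
  })
  for (cs in cases) {
    if (length(unique(cs$l)) < 2) next
    got <- youden_cutoff(cs$s, cs$l)
    want <- brute(cs$s, cs$l)
    expect_equal(got$cutoff, unname(want["cutoff"]))
    expect_equal(got$j, unname(want["j"]))
    expect_equal(got$j, got$sensitivity + got$specificity - 1)
  }
})

test_that("Kaplan-Meier estimator reproduces the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  # no events: flat at 1
  flat <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(flat$survival == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM curves are order-invariant and scale-equivariant", {
  withr::with_seed(17, {
    t <- rexp(30, 0.1)
    e <- rbinom(30, 1, 0.6)
    base <- km_estimate(t, e)
    perm <- sample(30)
    expect_equal(km_estimate(t[perm], e[perm]), base)
    scaled <- km_estimate(t * 12, e)
    expect_equal(scaled$time, base$time * 12)
    expect_equal(scaled$survival, base$survival)
    expect_true(all(diff(base$survival) <= 1e-12))
  })
})

test_that("log-rank test handles symmetry and the single-event form", {
  t <- c(1, 2, 3, 4)
  e <- c(1, 0, 1, 1)
  res <- log_rank(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  # one event total: 2x1 hypergeometric closed form
  t2 <- c(1, 2, 3, 4, 5)
  e2 <- c(1, 0, 0, 0, 0)
  g2 <- c("a", "a", "b", "b", "b")
  res2 <- log_rank(t2, e2, g2)
  n1 <- 2; n <- 5
  expected <- n1 / n
  v <- n1 * (n - n1) / n^2
  expect_equal(res2$statistic, (1 - expected)^2 / v, tolerance = 1e-8)
  expect_error(log_rank(t2, e2, rep("a", 5)), "2 non-empty groups")
})

test_that("Pearson correlation recovers exact linear relations", {
  expect_equal(pearson_mfs_corr(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_mfs_corr(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)
  expect_error(pearson_mfs_corr(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_mfs_corr(c(1, 2), c(1, 2)), "at least 3")
})
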