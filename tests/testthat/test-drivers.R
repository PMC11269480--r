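test_that("pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$n, 5)
  # pairwise deletion
  expect_equal(pearson_cor(c(x, NA), c(y, 1))$n, 5)
  expect_error(pearson_cor(rep(1, 5), 1:5), class = "enzlim_domain_error",
               regexp = "'x' is constant")
})

test_that("driver screen returns one row per predictor, NA for constants", {
  d <- tibble::tibble(resp = c(1, 3, 2, 5, 4), a = 1:5, b = rep(2, 5),
                      lab = letters[1:5])
  out <- correlate_drivers(d, resp)
  expect_setequal(out$predictor, c("a", "b"))
  expect_true(is.na(out$r[out$predictor == "b"]))
  expect_equal(out$r[out$predictor == "a"], cor(d$a, d$resp))
})

test_that("OLS reproduces closed-form identities", {
  d <- data.frame(x = 1:10, y = 3 * (1:10) - 2)
  fit <- suppressWarnings(fit_ols(y ~ x, d))
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)
  expect_equal(unname(coef(fit$fit)), c(-2, 3), tolerance = 1e-10)

  withr::with_seed(41, {
    d2 <- data.frame(x = rnorm(50))
    d2$y <- 1 + 0.5 * d2$x + rnorm(50)
    f2 <- fit_ols(y ~ x, d2)
    # single predictor: slope = r * sd(y)/sd(x)
    expect_equal(unname(coef(f2$fit)["x"]),
                 cor(d2$x, d2$y) * sd(d2$y) / sd(d2$x), tolerance = 1e-12)
    # standardized single predictor: slope = r
    d2s <- data.frame(x = scale(d2$x)[, 1], y = scale(d2$y)[, 1])
    expect_equal(unname(coef(fit_ols(y ~ x, d2s)$fit)["x"]),
                 cor(d2$x, d2$y), tolerance = 1e-12)
    # adjusted R2 matches its formula and the lm cross-check
    sm <- summary(f2$fit)
    expect_equal(f2$adj_r2, 1 - (1 - f2$r2) * (50 - 1) / (50 - 1 - 1))
    expect_equal(f2$r2, sm$r.squared)

    # independent noise at large n: adjusted R2 near zero
    d3 <- data.frame(x = rnorm(10000), y = rnorm(10000))
    expect_lt(abs(fit_ols(y ~ x, d3)$adj_r2), 0.01)
  })

  # rank-deficient design names the collinear column
  d4 <- data.frame(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_ols(y ~ x1 + x2, d4), class = "enzlim_domain_error",
               regexp = "x2")
  expect_error(suppressWarnings(fit_ols(y ~ x, data.frame(x = 1:2, y = 1:2))),
               regexp = "n >")
})

test_that("tidy and glance expose the fitted quantities", {
  d <- data.frame(x = 1:20, y = (1:20) + rnorm(20, sd = 0.1))
  fit <- fit_ols(y ~ x, d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_true(all(c("estimate", "std_error", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 20)
  expect_lte(gl$adj_r2, gl$r2)
  expect_equal(gl$aic, stats::AIC(fit$fit))
})

test_that("one-way ANOVA matches the SSB/SSW oracle and t-squared identity", {
  g1 <- c(1, 2, 3)
  g2 <- c(4, 5, 6)
  res <- anova_oneway(list(g1, g2))
  # hand-computed sums of squares
  gm <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - gm)^2 + 3 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(res$f_stat, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  # F = t^2 for two groups
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  # identical group means give F ~ 0
  expect_lt(anova_oneway(list(c(1, 2, 3), c(3, 2, 1)))$f_stat, 1e-12)
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))),
               class = "enzlim_domain_error")
  expect_error(anova_oneway(list(1:3)), class = "enzlim_domain_error")

  # data-frame interface agrees with the list interface
  d <- tibble::tibble(v = c(g1, g2), grp = rep(c("A", "B"), each = 3))
  expect_equal(anova_oneway(d, v, grp), res)
})

perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[[length(out) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  out
}

test_that("mantel p on 4x4 matrices agrees with exhaustive enumeration", {
  withr::with_seed(42, {
    pts1 <- matrix(rnorm(8), ncol = 2)
    pts2 <- pts1 + matrix(rnorm(8, sd = 0.4), ncol = 2)
    m1 <- as.matrix(dist(pts1))
    m2 <- as.matrix(dist(pts2))
  })
  v1 <- m1[lower.tri(m1)]
  r_obs <- cor(v1, m2[lower.tri(m2)])
  r_all <- vapply(perms4(), function(p) {
    mp <- m2[p, p]
    cor(v1, mp[lower.tri(mp)])
  }, numeric(1))
  q <- mean(r_all >= r_obs) # exhaustive tail probability over all 24
  mt <- mantel_test(m1, m2, n_perm = 999, seed = 9)
  expect_equal(mt$r, r_obs, tolerance = 1e-12)
  # sampled p concentrates on (1 + 999 q) / 1000
  expect_equal(mt$p_value, (1 + 999 * q) / 1000, tolerance = 0.06)
})

test_that("mantel test agrees with the vegan implementation", {
  withr::with_seed(43, {
    m <- matrix(rpois(60, 8), nrow = 6,
                dimnames = list(paste0("s", 1:6), NULL))
    e <- matrix(rnorm(12), nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  })
  d1 <- vegan::vegdist(m, "bray")
  d2 <- dist(e)
  mt <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  vg <- withr::with_seed(5, vegan::mantel(d1, d2, permutations = 999))
  expect_equal(mt$r, vg$statistic, tolerance = 1e-12)
  expect_lt(abs(mt$p_value - vg$signif), 0.1)
  # identical matrices: r = 1, minimum attainable p
  self <- mantel_test(d1, d1, n_perm = 99, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 100)
  expect_error(mantel_test(d1, dist(e[6:1, ])), class = "enzlim_schema_error")
})

test_that("mantel p is invariant to relabeling both matrices together", {
  withr::with_seed(44, {
    a <- as.matrix(dist(matrix(rnorm(10), ncol = 2)))
    b <- as.matrix(dist(matrix(rnorm(10), ncol = 2)))
    p <- sample(5)
  })
  m0 <- mantel_test(a, b, n_perm = 999, seed = 7)
  m1 <- mantel_test(a[p, p], b[p, p], n_perm = 999, seed = 7)
  expect_equal(m0$r, m1$r, tolerance = 1e-12)
  expect_lt(abs(m0$p_value - m1$p_value), 0.08)
})

test_that("forward stepwise recovers planted predictors and honours AIC", {
  withr::with_seed(45, {
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 8), ncol = 8))
    names(X) <- paste0("x", 1:8)
    X$y <- 2 * X$x3 + 1.5 * X$x6 + rnorm(n)
  })
  sel <- forward_stepwise(X, y, paste0("x", 1:8))
  expect_true(all(c("x3", "x6") %in% sel$predictors))
  # the planted pair carries the signal: they are the two strongest terms
  td <- tidy(sel)
  ord <- td$term[order(td$p_value)]
  expect_setequal(setdiff(ord, "(Intercept)")[1:2], c("x3", "x6"))
  # selected model cannot be worse than intercept-only
  null_aic <- stats::AIC(lm(y ~ 1, data = X))
  expect_lte(sel$aic, null_aic)

  # single perfect predictor
  d <- data.frame(x = 1:30, y = 2 * (1:30))
  s2 <- suppressWarnings(forward_stepwise(d, y, "x"))
  expect_equal(s2$predictors, "x")
  expect_equal(s2$adj_r2, 1)
})

test_that("stepwise on pure noise rarely keeps a large model", {
  sizes <- withr::with_seed(46, {
    vapply(1:40, function(i) {
      d <- as.data.frame(matrix(rnorm(60 * 4), ncol = 4))
      names(d) <- c("y", paste0("x", 1:3))
      length(forward_stepwise(d, y, paste0("x", 1:3))$predictors)
    }, numeric(1))
  })
  # AIC-forward admits a spurious term with non-trivial probability, but
  # should almost never build models using most of the noise candidates
  expect_gte(mean(sizes <= 1), 0.6)
  expect_lt(mean(sizes == 3), 0.15)
})

test_that("permutation importance ranks strong effects first and normalises", {
  withr::with_seed(47, {
    n <- 300
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 3 * d$x1 + 1 * d$x2 + 0 * d$x3 + rnorm(n, sd = 0.5)
  })
  fit <- fit_ols(y ~ x1 + x2 + x3, d)
  imp <- permutation_importance(fit, n_rep = 50, seed = 8)
  expect_equal(sum(imp$importance_pct), 100)
  expect_equal(imp$term[1], "x1")
  expect_gt(imp$mse_increase[imp$term == "x1"],
            imp$mse_increase[imp$term == "x2"])
  # near-zero coefficient: near-zero importance
  expect_lt(imp$importance_pct[imp$term == "x3"], 5)
  expect_error(permutation_importance(fit, predictors = "zz"),
               class = "enzlim_domain_error")
  # reproducible under a fixed seed
  expect_equal(imp, permutation_importance(fit, n_rep = 50, seed = 8))
})

test_that("importance of x1 exceeds x2 across replicate simulations", {
  wins <- withr::with_seed(48, {
    vapply(1:20, function(i) {
      d <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
      d$y <- 3 * d$x1 + d$x2 + rnorm(120)
      imp <- permutation_importance(fit_ols(y ~ x1 + x2, d), n_rep = 20)
      imp$mse_increase[imp$term == "x1"] > imp$mse_increase[imp$term == "x2"]
    }, logical(1))
  })
  expect_gte(mean(wins), 0.95)
})
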