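.fits_on <- function(d) {
  list(full = fit_zip_glm(y ~ x, ~1, d),
       null = fit_zip_glm(y ~ 1, ~1, d))
}

test_that("AIC ranking orders models and checks data identity", {
  set.seed(101)
  d <- data.frame(y = rzip(400, 4, 0.35),
                  x = factor(sample(c("a", "b"), 400, TRUE)))
  fits <- .fits_on(d)
  tab <- aic_rank(fits)
  expect_equal(tab$dAIC[1], 0)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$loglik)

  single <- aic_rank(fits["full"])
  expect_equal(single$dAIC, 0)

  d2 <- d
  d2$y[1] <- d2$y[1] + 5L
  expect_error(aic_rank(list(a = fits$full, b = fit_zip_glm(y ~ x, ~1, d2))),
               "identical data")
})

test_that("Wald z handles degenerate and standard contrasts", {
  set.seed(111)
  d <- data.frame(y = rzip(500, 3, 0.3),
                  x = factor(sample(c("a", "b"), 500, TRUE)))
  fit <- fit_zip_glm(y ~ x, ~x, d)
  zero <- wald_z(fit, rep(0, 4))
  expect_equal(zero$z, 0)
  expect_equal(zero$p, 1)
  # the normal quantile identity
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  w <- wald_z(fit, setNames(1, "cond_xb"))
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_error(wald_z(fit, setNames(1, "cond_missing")), "unknown")
})

test_that("Wald z-squared approaches the LRT chi-square at large n", {
  set.seed(121)
  n <- 10000
  x <- factor(sample(c("a", "b"), n, TRUE))
  X <- model.matrix(~x)
  y <- rzip(n, exp(drop(X %*% c(1, 0.12))), 0.3)
  d <- data.frame(y = y, x = x)
  full <- fit_zip_glm(y ~ x, ~1, d)
  red <- fit_zip_glm(y ~ 1, ~1, d)
  lr <- lrt(full, red)
  z <- wald_z(full, setNames(1, "cond_xb"))$z
  expect_lt(abs(z^2 - lr$chisq) / lr$chisq, 0.05)
})

test_that("LRT handles identities, published mapping, and misuse", {
  set.seed(131)
  d <- data.frame(y = rzip(300, 3, 0.3),
                  x = factor(sample(c("a", "b"), 300, TRUE)))
  fit <- fit_zip_glm(y ~ x, ~1, d)
  same <- lrt(fit, fit)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # the reported tree-type effect size maps to p < .001
  expect_lt(pchisq(66.98, 1, lower.tail = FALSE), 0.001)
  expect_lt(pchisq(102.84, 10, lower.tail = FALSE), 0.001)
  fit2 <- fit_zip_glm(y ~ x, ~1, d[1:200, ])
  expect_error(lrt(fit, fit2), "identical data")
})

test_that("two-level factors need no multiplicity adjustment", {
  set.seed(141)
  d <- data.frame(y = rzip(600, 3, 0.3),
                  x = factor(sample(c("a", "b"), 600, TRUE)))
  fit <- fit_zip_glm(y ~ x, ~1, d)
  tk <- tukey_pairwise(fit, "x", "cond")
  w <- wald_z(fit, setNames(1, "cond_xb"))
  expect_equal(tk$estimate, w$estimate, tolerance = 1e-9)
  expect_equal(tk$lower, w$estimate - qnorm(0.975) * w$se, tolerance = 1e-6)
  expect_equal(tk$upper, w$estimate + qnorm(0.975) * w$se, tolerance = 1e-6)
})

test_that("three-group critical value matches the studentized-range constant", {
  # independent equal-variance level estimates: single-step equicoordinate
  # quantile equals qtukey(0.95, 3, Inf)/sqrt(2)
  est <- c(0.2, -0.1, 0.4)
  V <- diag(0.09, 3)
  C <- rbind(c(-1, 1, 0), c(-1, 0, 1), c(0, -1, 1))
  sc <- simultaneous_contrasts(setNames(drop(C %*% est), c("ba", "ca", "cb")),
                               C %*% V %*% t(C))
  expect_equal(attr(sc, "crit"), qtukey(0.95, 3, Inf) / sqrt(2),
               tolerance = 1e-3)
  # adjusted intervals contain (are at least as wide as) unadjusted ones
  se <- sqrt(diag(C %*% V %*% t(C)))
  expect_true(all(sc$lower <= sc$estimate - qnorm(0.975) * se + 1e-12))
  expect_true(all(sc$upper >= sc$estimate + qnorm(0.975) * se - 1e-12))
})

test_that("simultaneous coverage holds under the null with four groups", {
  # 400 null draws of 4 independent group means; all 6 pairwise contrasts
  set.seed(151)
  m <- 4
  C <- t(combn(m, 2, function(ij) {
    v <- numeric(m); v[ij[1]] <- -1; v[ij[2]] <- 1; v
  }))
  V <- C %*% diag(1, m) %*% t(C)
  sc0 <- simultaneous_contrasts(setNames(rep(0, 6), paste0("c", 1:6)), V)
  crit <- attr(sc0, "crit")
  se <- sqrt(diag(V))
  n_rep <- 400
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mu <- rnorm(m)
    est <- drop(C %*% mu)
    cover[r] <- all(abs(est) <= crit * se)
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.985)
})
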