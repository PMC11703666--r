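test_that("layer summaries match hand values and the sorted-quartile oracle", {
  one <- data.frame(participant_id = "P1", layer_name = "solo",
                    arousal = 70, valence = 30)
  s1 <- layer_summaries(one)
  expect_equal(s1$arousal_mean, 70)
  expect_equal(s1$arousal_median, 70)
  expect_equal(s1$valence_median, 30)
  two <- data.frame(layer_name = "l", arousal = c(40, 60), valence = c(40, 60))
  s2 <- layer_summaries(two)
  expect_equal(s2$arousal_mean, 50)
  expect_equal(s2$arousal_median, 50)
  rt <- make_rating_table(c("a", "b", "c"), 11,
                          function(i, n) runif(n, 0, 100),
                          function(i, n) runif(n, 0, 100), seed = 13)
  sm <- layer_summaries(rt, inventory = c("c", "a", "b"))
  expect_identical(sm$layer, c("c", "a", "b"))
  for (lay in c("a", "b", "c")) {
    x <- rt$arousal[rt$layer_name == lay]
    row <- sm[sm$layer == lay, ]
    expect_equal(row$arousal_q1, quartile_oracle(x, 0.25))
    expect_equal(row$arousal_median, quartile_oracle(x, 0.5))
    expect_equal(row$arousal_q3, quartile_oracle(x, 0.75))
    expect_true(row$arousal_q1 <= row$arousal_median &&
                  row$arousal_median <= row$arousal_q3)
  }
})

test_that("pearson matrix reproduces analytic and covariance-formula values", {
  x <- c(1, 2, 4, 7)
  pm <- pearson_matrix(data.frame(x = x, y = -2 * x + 3))
  expect_equal(pm$r["x", "y"], -1)
  expect_equal(diag(pm$r), c(x = 1, y = 1))
  # 4-point hand example against the covariance formula
  a <- c(2, 4, 5, 9); b <- c(1, 3, 2, 8)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  pm2 <- pearson_matrix(data.frame(a = a, b = b))
  expect_equal(pm2$r["a", "b"], oracle, tolerance = 1e-12)
  expect_true(pm2$p["a", "b"] > 0 && pm2$p["a", "b"] <= 1)
  expect_warning(pm3 <- pearson_matrix(data.frame(a = a, c = rep(1, 4))),
                 "constant")
  expect_true(is.na(pm3$r["a", "c"]))
})

test_that("OLS reproduces the normal-equations oracle and its identities", {
  # noiseless single predictor
  x <- 1:10
  f <- suppressWarnings(ols_fit(2 * x, data.frame(x = x)))
  expect_equal(f$coefficients$estimate[2], 2)
  expect_equal(f$r_squared, 1)
  # six-predictor fixture against an explicit normal-equations solve
  withr::with_seed(31, {
    X <- as.data.frame(matrix(rnorm(40 * 6), 40, 6,
                              dimnames = list(NULL, paste0("f", 1:6))))
    y <- drop(as.matrix(X) %*% c(1, -2, 0.5, 0, 3, -1)) + rnorm(40, 0, 2)
  })
  fit <- ols_fit(y, X)
  Xd <- cbind(1, as.matrix(X))
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(fit$coefficients$estimate, drop(beta_oracle),
               tolerance = 1e-10, ignore_attr = TRUE)
  resid <- y - drop(Xd %*% beta_oracle)
  r2_oracle <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2_oracle, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared,
               1 - (1 - r2_oracle) * (40 - 1) / (40 - 6 - 1),
               tolerance = 1e-10)
  # F / R2 identity holds exactly
  k <- fit$df1; df2 <- fit$df2
  expect_equal(fit$f, (fit$r_squared / k) / ((1 - fit$r_squared) / df2))
  expect_identical(c(fit$df1, fit$df2), c(6, 33))
  # rank deficiency names the collinear column
  X2 <- X; X2$dup <- X$f1
  expect_error(ols_fit(y, X2), "dup")
  expect_error(ols_fit(1:5, data.frame(a = 1:5, b = (1:5)^2, c = (1:5)^3,
                                       d = (1:5)^0.5)), "n > k")
})

test_that("one-way ANOVA matches brute-force sums of squares and F = t^2", {
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$f,
               0)
  expect_equal(one_way_anova(rep(5, 9), rep(letters[1:3], 3))$f, 0)
  # brute force on three groups
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- one_way_anova(vals, grp)
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_identical(c(res$df_between, res$df_within), c(2L, 6L))
  # two groups: F equals the squared pooled-variance t statistic
  withr::with_seed(17, { a <- rnorm(12, 50, 9); b <- rnorm(15, 55, 9) })
  tt <- stats::t.test(a, b, var.equal = TRUE)
  av <- one_way_anova(c(a, b), rep(c("a", "b"), c(12, 15)))
  expect_equal(av$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p.value, tolerance = 1e-10)
})

test_that("neutrality tests flag departures from the scale midpoint", {
  neutral <- data.frame(layer_name = "n", arousal = rep(50, 10),
                        valence = rep(50, 10))
  rn <- neutrality_test(neutral)
  expect_true(all(rn$p == 1))
  expect_true(all(rn$direction == 0))
  high <- data.frame(layer_name = "h", arousal = rep(90, 50),
                     valence = rep(90, 50))
  rh <- neutrality_test(high)
  expect_true(all(rh$p_adj < 0.001))
  expect_true(all(rh$direction == 1))
  # data symmetric about 50 stays non-significant
  sym <- data.frame(layer_name = "s", arousal = c(30, 70, 40, 60, 50, 45, 55),
                    valence = c(20, 80, 35, 65, 50, 42, 58))
  rs <- neutrality_test(sym)
  expect_true(all(rs$p > 0.9))
  expect_warning(neutrality_test(data.frame(layer_name = "tiny",
                                            arousal = c(1, 2),
                                            valence = c(1, 2))), "n < 6")
})

test_that("layer-family comparisons pool by pattern and detect shifts", {
  inv <- inception_layer_inventory()
  rt <- make_rating_table(inv[1:20], 8,
                          function(i, n) runif(n, 30, 70),
                          function(i, n) runif(n, 30, 70), seed = 23)
  cm <- group_compare(rt, c(conv = "^conv2d[0-2]$", other = "^maxpool0$"))
  expect_identical(sort(cm$members$conv), c("conv2d0", "conv2d1", "conv2d2"))
  expect_error(group_compare(rt, c(a = "^conv2d0$", b = "^zzz$")), "zzz")
  expect_error(group_compare(rt, c(a = "^conv2d0$", b = "conv2d0")),
               "not disjoint")
  # identical rating sets in both families -> p near 1
  same <- rbind(
    data.frame(layer_name = "famA", arousal = 1:60, valence = 1:60),
    data.frame(layer_name = "famB", arousal = 1:60, valence = 1:60))
  ps <- group_compare(same, c(A = "^famA$", B = "^famB$"))$tests$p
  expect_true(all(ps > 0.9))
  # +30 shift on one family with n = 100 per side
  withr::with_seed(29, {
    shift <- rbind(
      data.frame(layer_name = "lo", arousal = pmin(pmax(rnorm(100, 35, 10), 0), 100),
                 valence = runif(100, 0, 100)),
      data.frame(layer_name = "hi", arousal = pmin(pmax(rnorm(100, 65, 10), 0), 100),
                 valence = runif(100, 0, 100)))
  })
  tests <- group_compare(shift, c(lo = "^lo$", hi = "^hi$"))$tests
  expect_lt(tests$p[tests$scale == "arousal"], 0.001)
  expect_gt(tests$p[tests$scale == "valence"], 0.01)
})
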