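test_that("the Wald ratio and its delta-method SE are exact arithmetic", {
  est <- wald_ratio(beta_x = 0.1, se_x = 0.01, beta_y = 0.05, se_y = 0.01)
  expect_equal(est$estimates$beta, 0.5)
  expect_equal(est$estimates$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$estimates$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01),
               class = "tidymr_undefined_ratio")
  # the second-order SE adds a nonnegative variance term
  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(4, 0.01, 0.2))
    e1 <- wald_ratio(v[1], v[2], v[3], v[4], order = 1)
    e2 <- wald_ratio(v[1], v[2], v[3], v[4], order = 2)
    expect_gte(e2$estimates$se, e1$estimates$se)
  }
})

test_that("IVW pools equal-weight equal-strength ratios to their mean", {
  frame <- make_frame(bx = c(0.1, 0.1), sx = c(0.01, 0.01),
                      by = c(0.04, 0.06), sy = c(0.01, 0.01))
  expect_equal(mr_ivw(frame)$estimates$beta, 0.5)
})

test_that("IVW and Egger match the weighted-least-squares oracle", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(5:50, 1))
    frame <- random_frame(n, seed + 100)
    expect_equal(mr_ivw(frame)$estimates$beta, lm_ivw_oracle(frame),
                 tolerance = 1e-10)
    egger <- mr_egger(frame)
    oracle <- lm_egger_oracle(frame)
    expect_equal(egger$estimates$beta, oracle["slope"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(egger$extras$intercept, oracle["intercept"],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("fixed and random-effects IVW differ only via the residual scale", {
  frame <- random_frame(20, 1)
  fx <- mr_ivw(frame, effects_model = "fixed")
  re <- mr_ivw(frame, effects_model = "multiplicative_random")
  expect_equal(fx$estimates$beta, re$estimates$beta)
  sigma <- re$extras$residual_scale
  expect_equal(re$estimates$se, fx$estimates$se * max(1, sigma))
})

test_that("a single instrument falls back to the Wald ratio with a notice", {
  frame <- make_frame(0.1, 0.01, 0.05, 0.01)
  expect_message(est <- mr_ivw(frame), "Wald")
  expect_equal(est$estimates$beta, 0.5)
})

test_that("all estimators agree in the zero-heterogeneity limit", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  frame <- make_frame(bx = bx, sx = rep(0.001, 4),
                      by = 0.37 * bx, sy = rep(0.01, 4))
  expect_equal(mr_ivw(frame)$estimates$beta, 0.37, tolerance = 1e-12)
  expect_equal(mr_egger(frame)$estimates$beta, 0.37, tolerance = 1e-8)
  expect_equal(mr_weighted_median(frame, n_boot = 0)$estimates$beta, 0.37,
               tolerance = 1e-12)
})

test_that("Egger orientation is the identity when all beta_x are positive", {
  frame <- random_frame(15, 2)
  frame$beta_x <- abs(frame$beta_x)
  manual <- lm(beta_y ~ beta_x, data = frame, weights = 1 / frame$se_y^2)
  expect_equal(mr_egger(frame)$estimates$beta, unname(coef(manual)[2]),
               tolerance = 1e-10)
  expect_error(mr_egger(frame[1:2, ]),
               class = "tidymr_insufficient_instruments")
})

test_that("weighted median: equal weights pick the middle ratio", {
  frame <- make_frame(bx = c(1, 1, 1), sx = rep(0.01, 3),
                      by = c(0.2, 0.5, 0.9), sy = rep(0.1, 3))
  expect_equal(mr_weighted_median(frame, n_boot = 0)$estimates$beta, 0.5)
})

test_that("weighted median matches the brute-force interpolation oracle", {
  for (seed in 1:15) {
    n <- withr::with_seed(seed, sample(3:7, 1))
    frame <- random_frame(n, seed + 300)
    got <- mr_weighted_median(frame, n_boot = 0)$estimates$beta
    ratio <- frame$beta_y / frame$beta_x
    w <- (frame$beta_x / frame$se_y)^2
    expect_equal(got, brute_weighted_median(ratio, w), tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap SE is deterministic given the seed", {
  frame <- random_frame(12, 3)
  a <- mr_weighted_median(frame, n_boot = 200, seed = 99)
  b <- mr_weighted_median(frame, n_boot = 200, seed = 99)
  expect_identical(a$estimates$se, b$estimates$se)
  expect_gt(a$estimates$se, 0)
})

test_that("estimators are sign-equivariant", {
  frame <- random_frame(20, 4)
  neg_x <- frame
  neg_x$beta_x <- -neg_x$beta_x   # allele relabel on the exposure side
  neg_y <- frame
  neg_y$beta_y <- -neg_y$beta_y
  for (est in list(function(f) mr_ivw(f)$estimates$beta,
                   function(f) mr_egger(f)$estimates$beta,
                   function(f) mr_weighted_median(f, n_boot = 0)$estimates$beta)) {
    expect_equal(est(neg_x), -est(frame), tolerance = 1e-10)
    expect_equal(est(neg_y), -est(frame), tolerance = 1e-10)
  }
  # negating beta_x flips the estimate's sign because the frame then
  # codes the opposite allele; full relabeling (bx and by fixed jointly)
  # leaves everything unchanged: ratios by/bx are unaffected
  both <- frame
  both$beta_x <- -both$beta_x
  both$beta_y <- -both$beta_y
  expect_equal(mr_ivw(both)$estimates$beta, mr_ivw(frame)$estimates$beta,
               tolerance = 1e-12)
})

test_that("multivariable IVW reduces exactly to univariable IVW at K = 1", {
  frame <- random_frame(15, 5)
  uni <- mr_ivw(frame)
  multi <- mvmr_ivw(frame)
  expect_equal(multi$estimates$beta, uni$estimates$beta, tolerance = 1e-14)
  expect_equal(multi$estimates$se, uni$estimates$se, tolerance = 1e-14)
  eg_uni <- mr_egger(frame)
  eg_multi <- mvmr_egger(frame)
  expect_equal(eg_multi$estimates$beta, eg_uni$estimates$beta,
               tolerance = 1e-12)
  expect_equal(eg_multi$extras$intercept, eg_uni$extras$intercept,
               tolerance = 1e-12)
  expect_equal(eg_multi$extras$intercept_p, eg_uni$extras$intercept_p,
               tolerance = 1e-12)
})

mvmr_frame <- function(n, k, seed, theta = rep(0.1, k)) {
  withr::with_seed(seed, {
    x <- matrix(abs(rnorm(n * k, 0.08, 0.04)), n, k)
    sy <- runif(n, 0.01, 0.05)
    frame <- tibble::tibble(rsid = sprintf("rs%03d", 1:n))
    for (j in 1:k) {
      frame[[paste0("beta_x_e", j)]] <- x[, j]
      frame[[paste0("se_x_e", j)]] <- runif(n, 0.002, 0.01)
    }
    frame$beta_y <- drop(x %*% theta) + rnorm(n, 0, 0.02)
    frame$se_y <- sy
    frame
  })
}

test_that("multivariable IVW matches the weighted-least-squares oracle", {
  for (seed in 1:6) {
    frame <- mvmr_frame(20, 3, seed)
    got <- mvmr_ivw(frame)
    x <- as.matrix(frame[, paste0("beta_x_e", 1:3)])
    fit <- lm(frame$beta_y ~ 0 + x, weights = 1 / frame$se_y^2)
    expect_equal(got$estimates$beta, unname(coef(fit)), tolerance = 1e-10)
    eg <- mvmr_egger(frame)
    fit2 <- lm(frame$beta_y ~ x, weights = 1 / frame$se_y^2)
    expect_equal(eg$estimates$beta, unname(coef(fit2)[-1]),
                 tolerance = 1e-10)
  }
})

test_that("collinear exposures raise a named collinearity error", {
  frame <- mvmr_frame(15, 2, 7)
  frame$beta_x_e2 <- 2 * frame$beta_x_e1
  err <- expect_error(mvmr_ivw(frame), class = "tidymr_collinearity")
  expect_match(conditionMessage(err), "e2|e1")
})

test_that("multivariable median is deterministic and matches the univariable
           weighted median under equal weights", {
  frame <- mvmr_frame(20, 2, 8)
  a <- mvmr_median(frame, n_boot = 100, seed = 5)
  b <- mvmr_median(frame, n_boot = 100, seed = 5)
  expect_identical(a$estimates, b$estimates)

  # K = 1, constant |beta_x| and se_y: obs and ratio weights coincide
  withr::with_seed(9, {
    uni <- make_frame(bx = rep(0.1, 9), sx = rep(0.005, 9),
                      by = 0.1 * 0.3 + rnorm(9, 0, 0.01),
                      sy = rep(0.01, 9))
  })
  med_l1 <- mvmr_median(uni, n_boot = 200, seed = 1)
  med_wm <- mr_weighted_median(uni, n_boot = 200, seed = 1)
  expect_equal(med_l1$estimates$beta, med_wm$estimates$beta,
               tolerance = 2 * med_wm$estimates$se)
})

test_that("multivariable median resists planted outliers that shift IVW", {
  n <- 40
  frame <- withr::with_seed(10, {
    x <- matrix(abs(rnorm(n * 2, 0.08, 0.04)), n, 2)
    tibble::tibble(rsid = sprintf("rs%03d", 1:n),
                   beta_x_e1 = x[, 1], se_x_e1 = 0.005,
                   beta_x_e2 = x[, 2], se_x_e2 = 0.005,
                   beta_y = drop(x %*% c(0.2, 0)) + rnorm(n, 0, 0.005),
                   se_y = 0.01)
  })
  out_idx <- 1:8  # 20% one-sided outliers
  frame$beta_y[out_idx] <- frame$beta_y[out_idx] + 0.05
  ivw_b <- mvmr_ivw(frame)$estimates$beta
  med_b <- mvmr_median(frame, n_boot = 0)$estimates$beta
  clean_b <- mvmr_ivw(frame[-out_idx, ])$estimates$beta
  # the median stays near the outlier-free fit; IVW is pulled away
  expect_lt(abs(med_b[1] - clean_b[1]), abs(ivw_b[1] - clean_b[1]))
  expect_lt(abs(med_b[2] - clean_b[2]), abs(ivw_b[2] - clean_b[2]))
})

test_that("odds-ratio conversion exponentiates the 1.96-SE interval", {
  est <- mr_ivw(make_frame(c(0.1, 0.1), c(0.01, 0.01), c(0, 0),
                           c(0.01, 0.01)))
  est$estimates$beta <- 0
  est$estimates$se <- 0.05
  orv <- to_odds_ratio(est)$estimates
  expect_equal(orv$or, 1)
  expect_equal(orv$or_low * orv$or_high, 1, tolerance = 1e-12)

  est$estimates$beta <- 0.1133
  est$estimates$se <- 0.0341
  orv <- to_odds_ratio(est)$estimates
  expect_equal(round(orv$or, 2), 1.12)
  expect_equal(round(orv$or_low, 2), 1.05)
  expect_equal(round(orv$or_high, 2), 1.20)

  # interval width is monotone in the SE
  est$estimates$se <- 0.05
  w1 <- with(to_odds_ratio(est)$estimates, or_high - or_low)
  est$estimates$se <- 0.1
  w2 <- with(to_odds_ratio(est)$estimates, or_high - or_low)
  expect_gt(w2, w1)
})

test_that("tidy and glance return broom-shaped tibbles", {
  frame <- random_frame(10, 11)
  td <- tidy(to_odds_ratio(mr_ivw(frame)))
  expect_true(all(c("method", "term", "estimate", "std.error", "p.value",
                    "conf.low", "conf.high", "or") %in% names(td)))
  expect_equal(nrow(td), 1)
  gl <- glance(mr_egger(frame))
  expect_equal(gl$method, "mr_egger")
  expect_false(is.na(gl$intercept_p))
  td3 <- tidy(mvmr_ivw(mvmr_frame(12, 3, 12)))
  expect_equal(nrow(td3), 3)
})
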