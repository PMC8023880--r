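test_that("regression recovers exact generating coefficients", {
  fta <- seq(-12, 10, length.out = 25)
  # exact-interpolation fixture on a published-scale line
  m <- fit_hkaa_model(fta, -2.182 + 0.995 * fta)
  expect_equal(unname(m$coefficients), c(-2.182, 0.995), tolerance = 1e-9)

  m_id <- fit_hkaa_model(fta, fta)
  expect_equal(unname(m_id$coefficients), c(0, 1), tolerance = 1e-12)

  mq <- fit_hkaa_model(fta, 1.5 - 0.8 * fta + 0.03 * fta^2, variant = "quadratic")
  expect_equal(unname(mq$coefficients), c(1.5, -0.8, 0.03), tolerance = 1e-9)

  sex <- rep(c("female", "male"), length.out = 25)
  y <- ifelse(sex == "male", -1.2 + 0.9 * fta, 0.4 + 1.1 * fta)
  ms <- fit_hkaa_model(fta, y, sex = sex, variant = "sex_adjusted")
  pred <- predict(ms, data.frame(fta = c(2, 2), sex = c("male", "female")))
  expect_equal(pred, c(-1.2 + 1.8, 0.4 + 2.2), tolerance = 1e-9)
})

test_that("degenerate regression inputs fail loudly", {
  expect_error(fit_hkaa_model(rep(3, 10), rnorm(10)), "constant")
  expect_error(fit_hkaa_model(1:2, 1:2), "at least 3")
  expect_error(fit_hkaa_model(1:10, 1:10, variant = "sex_adjusted"), "requires sex")
  expect_error(fit_hkaa_model(1:10, 1:10, sex = rep("male", 10),
                              variant = "sex_adjusted"), "both sexes")
})

test_that("fold assignment is a balanced, seeded partition", {
  f <- kfold_assignment(100, k = 5, seed = 7)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  expect_identical(f, kfold_assignment(100, k = 5, seed = 7))
  expect_false(identical(f, kfold_assignment(100, k = 5, seed = 8)))
  f2 <- kfold_assignment(23, k = 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("cross-validation is unbiased for the true model class", {
  fta <- seq(-10, 10, length.out = 40)
  hk <- -2 + 0.98 * fta
  cv <- kfold_predict(fta, hk, k = 5, seed = 3)
  expect_equal(cv$pred, hk, tolerance = 1e-6)        # zero CV error
  expect_equal(nrow(cv), 40)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(anyDuplicated(cv$case_id), 0)         # each case predicted once

  cv2 <- kfold_predict(fta, hk, k = 5, seed = 3)
  expect_identical(cv, cv2)                          # determinism

  expect_error(kfold_predict(1:8, 1:8, k = 5, seed = 1), "at least 10")
  # training sets of size 2 cannot fit even the simple model
  expect_error(kfold_predict(1:4, 1:4, k = 2, seed = 1), "fold too small")
  expect_error(kfold_predict(1:20, 1:20, sex = rep("male", 20),
                             variant = "sex_adjusted", k = 5, seed = 1),
               "single sex")
})

test_that("pearson matches a direct summation oracle", {
  x <- c(1.2, 3.4, -2.1, 0.5, 7.8, -4.4, 2.2, 9.1, -0.7, 5.5)
  y <- c(0.8, 2.9, -1.5, 1.1, 6.9, -3.8, 1.9, 8.2, 0.1, 4.9)
  oracle <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) * (sum(y^2) - length(y) * mean(y)^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("ICC(A,1) equals the brute-force ANOVA oracle and penalises bias", {
  obs <- c(4.1, -2.3, 0.8, 6.5, -5.2, 3.3, 1.1, -0.4)
  pred <- c(3.8, -2.9, 1.5, 6.0, -4.6, 2.7, 0.6, 0.2)
  got <- icc_agreement(obs, pred)
  expect_equal(got$value, oracle_icc_a1(obs, pred), tolerance = 1e-10)
  expect_true(got$lower < got$value && got$value < got$upper)

  # perfect agreement
  expect_equal(icc_agreement(obs, obs)$value, 1)

  # a pure constant shift leaves pearson at 1 but pulls the ICC below it
  shifted <- icc_agreement(obs, obs + 1)
  expect_lt(shifted$value, 1)
  expect_equal(pearson_r(obs, obs + 1), 1)

  expect_error(icc_agreement(1:4, 1:4), "at least 5")
  expect_error(icc_agreement(rep(1, 6), rep(1, 6)), "between-subject")
})

test_that("ICC matches the oracle on random instances (property)", {
  withr::with_seed(101, {
    for (i in 1:25) {
      n <- sample(5:30, 1)
      obs <- rnorm(n, sd = runif(1, 0.5, 5))
      pred <- obs * runif(1, 0.6, 1.4) + rnorm(n, sd = runif(1, 0.1, 2)) + runif(1, -2, 2)
      expect_equal(icc_agreement(obs, pred)$value, oracle_icc_a1(obs, pred),
                   tolerance = 1e-10)
    }
  })
})

test_that("agreement summary reports MAE and Bland-Altman as documented", {
  obs <- c(-3.2, 1.4, 0.7, -6.1, 4.9, 2.2, -1.8)
  s0 <- agreement_summary(obs, obs)
  expect_equal(s0$mae, 0)
  expect_equal(s0$bland_altman$loa_lower, 0)
  expect_equal(s0$bland_altman$loa_upper, 0)
  expect_equal(s0$icc$value, 1)

  # differences oriented observed - predicted
  s1 <- agreement_summary(obs, obs - 1)
  expect_equal(s1$mae, 1)
  expect_equal(s1$mae_sd, 0)
  expect_equal(s1$bland_altman$bias, 1)
  expect_equal(s1$bland_altman$sd_diff, 0)
})

test_that("Bland-Altman limits converge to +/-1.96 sigma (Monte Carlo)", {
  withr::with_seed(7, {
    obs <- rnorm(5000, 0, 4)
    pred <- obs + rnorm(5000, 0, 2)   # pure additive error, sd 2
    ba <- bland_altman(obs, pred)
    expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * 2, tolerance = 0.05)
    expect_equal(ba$bias, 0, tolerance = 0.15)
  })
})

test_that("slope/intercept and CV error recover the generating process", {
  withr::with_seed(17, {
    n <- 2000; sigma <- 1.5
    fta <- rnorm(n, 1, 4)
    hk <- -2.2 + 0.99 * fta + rnorm(n, 0, sigma)
    m <- fit_hkaa_model(fta, hk)
    se <- sqrt(diag(vcov(m$fit)))
    expect_lt(abs(m$coefficients[1] - (-2.2)), 3 * se[1])
    expect_lt(abs(m$coefficients[2] - 0.99), 3 * se[2])
    cv <- kfold_predict(fta, hk, k = 5, seed = 2)
    mae <- mean(abs(cv$hkaa - cv$pred))
    expect_lt(abs(mae - sigma * sqrt(2 / pi)) / (sigma * sqrt(2 / pi)), 0.15)
  })
})

test_that("sex-specific error comparison behaves under the null", {
  withr::with_seed(23, {
    obs <- rnorm(60, 0, 4)
    pred <- obs + rnorm(60, 0, 1.5)
    sex <- rep(c("male", "female"), 30)
    s <- agreement_summary(obs, pred, sex = sex)
    expect_true(is.finite(s$sex_error_p))
    expect_gt(s$sex_error_p, 0.001)   # no fabricated sex effect
  })
})
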