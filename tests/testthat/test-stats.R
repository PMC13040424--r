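test_that("Shapiro-Wilk wrapper enforces its domain and detects skew", {
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rnorm(5001)), "3 <= n")
  set.seed(3)
  sk <- shapiro_wilk(rexp(100))
  expect_lt(sk$p, 0.01)
  expect_true(sk$W > 0 && sk$W <= 1)
})

test_that("Shapiro-Wilk p-values are uniform under the null", {
  set.seed(17)
  ps <- vapply(1:100, function(i) shapiro_wilk(rnorm(200))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("IQR filter reproduces hand-computed type-7 fences", {
  res <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  # type-7 quartiles of n=5: Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_equal(res$fences, c(-1, 7))
  expect_identical(res$removed_indices, 5L)
  expect_equal(res$kept, c(1, 2, 3, 4))

  # constant list: IQR 0, fences collapse onto the value, nothing removed
  res2 <- iqr_outlier_filter(rep(7, 6))
  expect_length(res2$removed_indices, 0)
  expect_equal(res2$kept, rep(7, 6))

  # symmetric list without extremes is untouched
  res3 <- iqr_outlier_filter(c(-2, -1, 0, 1, 2))
  expect_length(res3$removed_indices, 0)

  expect_error(iqr_outlier_filter(c(1, 2, 3)), "n >= 4")
})

test_that("IQR filter is idempotent on representative data", {
  sets <- list(c(1, 2, 3, 4, 100), rep(7, 6), c(-2, -1, 0, 1, 2),
               c(seq(10, 20, by = 0.5), 80, -40))
  for (x in sets) {
    once <- iqr_outlier_filter(x)$kept
    twice <- iqr_outlier_filter(once)$kept
    expect_equal(twice, once)
  }
})

# independent mean-squares oracle for ICC(2,1) via aov()
icc21_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

test_that("ICC(2,1) equals the aov mean-squares oracle on random matrices", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:15, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, rep(rnorm(n, 0, sample(c(1, 5, 10), 1)), k),
                      sample(c(0.5, 1, 3), 1)), n, k)
    r <- icc(m)
    expect_equal(r$coefficient, icc21_oracle(m), tolerance = 1e-10)
    expect_lte(r$ci_low, r$coefficient + 1e-12)
    expect_gte(r$ci_high, r$coefficient - 1e-12)
  }
})

test_that("ICC degenerate cases behave as the variance model dictates", {
  # identical raters, varying subjects: perfect agreement
  v <- c(10, 20, 30, 40, 50)
  expect_equal(icc(cbind(v, v, v))$coefficient, 1.0)
  # no subject variance, raters differ: non-positive ICC
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_lte(icc(m)$coefficient, 0)
  expect_error(icc(matrix(1:3, 1, 3)), ">= 2 subjects")
  mm <- matrix(rnorm(12), 4, 3); mm[2, 2] <- NA
  expect_error(icc(mm), "complete")
})

test_that("linear fit is exact on noiseless data and flags collinearity", {
  x <- 1:20
  # noiseless data: lm warns about the perfect fit, which is the point here
  f <- suppressWarnings(fit_linear(2 * x, data.frame(x = x),
                                   filter_outliers = FALSE))
  sl <- f$terms[f$terms$term == "x", ]
  expect_equal(sl$estimate, 2, tolerance = 1e-10)
  expect_lt(sl$p_value, 1e-12)

  expect_error(fit_linear(rnorm(20), data.frame(a = x, b = x)),
               "collinear")
})

test_that("linear fit applies the IQR response filter per protocol", {
  set.seed(4)
  x <- rnorm(50)
  y <- 1 + 0.5 * x + rnorm(50, 0, 0.3)
  y[7] <- 100  # gross outlier
  f <- fit_linear(y, data.frame(x = x))
  expect_identical(f$outliers_removed, 1L)
  expect_identical(f$n_used, 49L)
  sl <- f$terms[f$terms$term == "x", ]
  expect_lt(abs(sl$estimate - 0.5), 0.3)
})

test_that("OLS recovers the generator slope within 3 SE at n = 10^4", {
  co <- make_cohort(cohort_sim_params(n = 10000, stroma_vol_age_slope = 0.25,
                                      seed = 77))
  f <- fit_linear(co$stroma_vol_cm3,
                  data.frame(age = co$age, length_2pt_mm = co$length_2pt_mm),
                  filter_outliers = FALSE)
  sl <- f$terms[f$terms$term == "age", ]
  se <- (sl$ci_high - sl$ci_low) / (2 * 1.96)
  expect_lt(abs(sl$estimate - 0.25), 3 * se)
})

test_that("logistic OR equals the 2x2 cross-product to 1e-6 relative", {
  # a=10, b=20, c=5, d=40 -> OR = (10*40)/(20*5) = 4
  x <- c(rep(1, 30), rep(0, 45))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 5), rep(0, 40))
  f <- fit_logistic(y, data.frame(x = x))
  or <- f$terms$odds_ratio[f$terms$term == "x"]
  expect_lt(abs(or - 4) / 4, 1e-6)

  # balanced table with identical rates: OR exactly 1
  x2 <- c(rep(1, 40), rep(0, 40))
  y2 <- rep(c(rep(1, 10), rep(0, 30)), 2)
  f2 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(f2$terms$odds_ratio[f2$terms$term == "x"], 1,
               tolerance = 1e-8)
})

test_that("logistic oracle holds across random 2x2 tables", {
  set.seed(31)
  for (i in 1:20) {
    tab <- sample(3:40, 4)  # a, b, c, d all nonzero: no separation
    x <- rep(c(1, 1, 0, 0), tab)
    y <- rep(c(1, 0, 1, 0), tab)
    f <- fit_logistic(y, data.frame(x = x))
    or_cp <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    expect_lt(abs(f$terms$odds_ratio[2] - or_cp) / or_cp, 1e-6)
  }
})

test_that("logistic fit guards its domain and flags separation", {
  expect_error(fit_logistic(rep(1, 20), data.frame(x = rnorm(20))),
               "single class")
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)  # perfectly separated
  expect_warning(f <- fit_logistic(y, data.frame(x = x)), "separation")
  expect_true(f$separation)
})

test_that("estimates are invariant to row permutation and covariate scaling", {
  set.seed(8)
  x <- rnorm(200); z <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.3 + 0.8 * x - 0.4 * z))
  f1 <- fit_logistic(y, data.frame(x = x, z = z))
  per <- sample(200)
  f2 <- fit_logistic(y[per], data.frame(x = x[per], z = z[per]))
  expect_equal(f1$terms$estimate, f2$terms$estimate, tolerance = 1e-8)
  # affine rescaling of x: slope back-transforms exactly
  f3 <- fit_logistic(y, data.frame(x = 10 * x + 5, z = z))
  expect_equal(f3$terms$estimate[f3$terms$term == "x"] * 10,
               f1$terms$estimate[f1$terms$term == "x"], tolerance = 1e-6)

  yl <- 2 + x - 0.5 * z + rnorm(200, 0, 0.1)
  g1 <- fit_linear(yl, data.frame(x = x, z = z), filter_outliers = FALSE)
  g2 <- fit_linear(yl[per], data.frame(x = x[per], z = z[per]),
                   filter_outliers = FALSE)
  expect_equal(g1$terms$estimate, g2$terms$estimate, tolerance = 1e-10)
})
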