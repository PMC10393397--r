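test_that("identical group means give zero group coefficients", {
  f <- fit_lm(rep(c(5, 7), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(unname(coef(f$fit)[-1]), c(0, 0), tolerance = 1e-10)
})

test_that("with two groups the squared t equals the F statistic", {
  set.seed(20)
  y <- rnorm(20, mean = rep(c(0, 1), each = 10))
  g <- rep(c("a", "b"), each = 10)
  f <- fit_lm(y, g)
  sm <- summary(f$fit)
  expect_equal(sm$coefficients[2, "t value"]^2,
               unname(sm$fstatistic["value"]), tolerance = 1e-10)
})

test_that("the stored logLik matches the closed-form Gaussian likelihood", {
  set.seed(21)
  y <- rnorm(24, rep(c(0, 2, 3), each = 8))
  g <- rep(letters[1:3], each = 8)
  f <- fit_lm(y, g)
  rss <- sum(resid(f$fit)^2)
  n <- length(y)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  expect_equal(f$log_lik, ll, tolerance = 1e-10)
})

test_that("undersized groups are reported by name", {
  expect_error(fit_lm(c(1, 2, 3), c("a", "a", "tiny")), "tiny")
  expect_error(fit_lm(1:4, rep("a", 4)), "2 groups")
})

test_that("the LRT behaves at its boundary and reference points", {
  set.seed(22)
  y <- rnorm(30, rep(c(0, 1), each = 15))
  full <- fit_lm(y, rep(c("a", "b"), each = 15))
  same <- fit_lm(y, rep(c("a", "b"), each = 15))
  r <- lrt(full, same)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # df = 1, chi2 = 3.841 -> p ~ 0.050
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # a genuine reduction
  null <- cardioTPC:::.fit_lm_null(y)
  r2 <- lrt(full, null)
  expect_equal(r2$df, 1L)
  expect_equal(r2$chi2, 2 * (full$log_lik - null$log_lik))
  expect_equal(r2$p, pchisq(r2$chi2, 1, lower.tail = FALSE))
  # non-nested (full smaller than reduced) is refused
  expect_error(lrt(null, full), "not nested")
})

test_that("two-group Tukey p equals the pooled two-sided t-test p", {
  set.seed(23)
  y <- rnorm(20, rep(c(0, 0.8), each = 10))
  g <- rep(c("a", "b"), each = 10)
  tk <- tukey_hsd(fit_lm(y, g))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$table$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$table$q_stat, sqrt(2) * abs(tt$statistic[[1]]),
               tolerance = 1e-9)
})

test_that("Tukey p-values agree with stats::TukeyHSD on balanced data", {
  set.seed(24)
  y <- rnorm(30, rep(c(0, 1, 3), each = 10))
  g <- factor(rep(letters[1:3], each = 10))
  tk <- tukey_hsd(fit_lm(y, g))
  ref <- TukeyHSD(aov(y ~ g))$g
  key <- paste(tk$table$level_j, tk$table$level_i, sep = "-")
  expect_equal(tk$table$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
})

test_that("three identical groups share one letter with p near 1", {
  y <- rep(c(10, 11, 9, 10.5), 3) + rep(c(0, 1e-3, -1e-3), each = 4)
  g <- rep(letters[1:3], each = 4)
  tk <- tukey_hsd(fit_lm(y, g))
  expect_true(all(tk$table$p_adj > 0.99))
  expect_equal(unname(tk$letters), rep("a", 3))
})

test_that("letters separate clearly different groups", {
  set.seed(25)
  y <- rnorm(30, rep(c(0, 0.2, 8), each = 10), 0.5)
  g <- rep(c("lo1", "lo2", "hi"), each = 10)
  tk <- tukey_hsd(fit_lm(y, g))
  expect_equal(tk$letters[["lo1"]], tk$letters[["lo2"]])
  expect_false(tk$letters[["hi"]] == tk$letters[["lo1"]])
})

test_that("Tukey adjustment is conservative relative to pairwise t-tests", {
  set.seed(26)
  y <- rnorm(30, rep(c(0, 0.5, 1), each = 10))
  g <- factor(rep(letters[1:3], each = 10))
  tk <- tukey_hsd(fit_lm(y, g))
  for (r in seq_len(nrow(tk$table))) {
    a <- tk$table$level_i[r]
    b <- tk$table$level_j[r]
    p_t <- t.test(y[g == a], y[g == b], var.equal = TRUE)$p.value
    expect_gte(tk$table$p_adj[r], p_t - 1e-10)
  }
})

test_that("zero residual variance is flagged", {
  expect_warning(tk <- tukey_hsd(fit_lm(rep(c(1, 2), each = 3),
                                        rep(c("a", "b"), each = 3))),
                 "zero residual variance")
  expect_equal(tk$table$p_adj, 0)
})

test_that("CV% follows its formula and the Kelvin convention", {
  tab <- data.frame(species = rep("s1", 3), habitat = "h",
                    individual = 1:3, trait = "hr_max_bpm",
                    value = c(300, 300, 300))
  expect_equal(cv_summary(tab, "hr_max_bpm")$mean_cv, 0)
  # sigma = 3, mu = 300 -> exactly 1%
  v <- c(297, 300, 303)
  sigma <- sd(v)
  tab2 <- data.frame(species = rep("s1", 3), habitat = "h",
                     individual = 1:3, trait = "hr_max_bpm",
                     value = v * 3 / sigma + (300 - mean(v * 3 / sigma)))
  expect_equal(cv_summary(tab2, "hr_max_bpm")$mean_cv, 1, tolerance = 1e-9)
  # temperature traits are shifted to Kelvin first
  tab3 <- data.frame(species = rep("s1", 3), habitat = "h",
                     individual = 1:3, trait = "ult_C",
                     value = c(51, 52, 53))
  got <- cv_summary(tab3, "ult_C")
  expect_true(got$kelvin_applied)
  expect_equal(got$mean_cv, 100 * sd(c(51, 52, 53)) / (52 + 273.15))
  expect_false(cv_summary(tab2, "hr_max_bpm")$kelvin_applied)
})

test_that("CV% is scale invariant and reduced by the Kelvin shift", {
  set.seed(27)
  v <- rnorm(9, 100, 12)
  tab <- function(x, tr) data.frame(species = "s", habitat = "h",
                                    individual = seq_along(x), trait = tr,
                                    value = x)
  cv1 <- cv_summary(tab(v, "hr_max_bpm"), "hr_max_bpm")$mean_cv
  cv2 <- cv_summary(tab(v * 7.3, "hr_max_bpm"), "hr_max_bpm")$mean_cv
  expect_equal(cv1, cv2, tolerance = 1e-10)
  tc <- rnorm(9, 45, 2)
  cv_c <- 100 * sd(tc) / mean(tc)
  cv_k <- cv_summary(tab(tc, "t_opt_C"), "t_opt_C")$mean_cv
  expect_lt(cv_k, cv_c)
})
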