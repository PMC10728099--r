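test_that("mean split assigns high strictly above the mean", {
  g <- split_by_mean(c(0.2, 0.4, 0.9))  # mean 0.5
  expect_equal(as.character(g), c("low", "low", "high"))
  # symmetric scores: balanced groups
  g <- split_by_mean(c(0.1, 0.3, 0.7, 0.9))
  expect_equal(sum(g == "high"), 2)
  # a score exactly at the mean goes low
  g <- split_by_mean(c(0.2, 0.4, 0.6))  # mean 0.4
  expect_equal(as.character(g)[2], "low")
  expect_error(split_by_mean(rep(0.5, 5)), "degenerate")
  expect_error(split_by_mean(0.5), "at least 2")
})

test_that("KM estimator matches closed forms and hand-computed fixture", {
  # no censoring, events at 1..n: S drops by 1/n each time
  n <- 5
  km <- km_estimate(1:n, rep(1, n))
  expect_equal(km$surv, 1 - (1:n) / n)

  # all censored: S stays 1
  km <- km_estimate(1:4, rep(0, 4))
  expect_true(all(km$surv == 1))

  # 5-subject mixed-censoring fixture, hand product-limit:
  # t=1 (5 at risk, 1 event) S=4/5; t=3 (3 at risk) S=4/5*2/3=8/15; t=5 S=0
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 5))
  expect_equal(ev$surv, c(4 / 5, 8 / 15, 0))

  # equals the empirical survival function without censoring
  set.seed(2)
  t <- sample(1:50, 20, replace = TRUE)
  km <- km_estimate(t, rep(1, 20))
  emp <- vapply(km$time, function(x) mean(t > x), 0)
  expect_equal(km$surv, emp)
})

test_that("log-rank chi-square equals the textbook O-E-V formula", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30
    time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.8)
    scores <- rnorm(n)
    g <- split_by_mean(scores)
    lr <- logrank_test(g, time, event)
    hand <- logrank_chisq_hand(g == "high", time, event)
    expect_equal(lr$chi_square, hand, tolerance = 1e-8)
    expect_equal(lr$p, pchisq(hand, 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("identical groups give a null log-rank result", {
  time <- rep(c(2, 4, 6, 8), 2); event <- rep(c(1, 1, 0, 1), 2)
  g <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
  lr <- logrank_test(g, time, event)
  expect_lt(lr$chi_square, 1e-10)
  expect_gt(lr$p, 0.999)
  expect_equal(lr$obs_minus_exp_high, 0, tolerance = 1e-10)
  # O - E = 0 exactly: positive sign by convention
  expect_equal(signed_p(g, time, event)$sign, 1)
})

test_that("log-rank degenerate inputs error", {
  g <- factor(rep("low", 4), levels = c("low", "high"))
  expect_error(logrank_test(g, 1:4, rep(1, 4)), "empty")
  g2 <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  expect_error(logrank_test(g2, 1:4, rep(0, 4)), "no events")
})

test_that("separated event times give strong significance", {
  # high group survives uniformly longer, n = 40
  time <- c(1:20, 101:120)
  event <- rep(1, 40)
  g <- factor(rep(c("low", "high"), each = 20), levels = c("low", "high"))
  lr <- logrank_test(g, time, event)
  expect_lt(lr$p, 0.001)
  sp <- signed_p(g, time, event)
  expect_equal(sp$sign, 1)
  expect_gt(sp$signed_value, 0)
})

test_that("signed P is antisymmetric under group swap", {
  set.seed(12)
  time <- rexp(20, 0.1); event <- rbinom(20, 1, 0.9)
  g <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  swapped <- factor(ifelse(g == "low", "high", "low"), levels = c("low", "high"))
  a <- signed_p(g, time, event)
  b <- signed_p(swapped, time, event)
  expect_equal(a$p, b$p)
  if (abs(a$chi_square) > 1e-10) {
    expect_equal(a$sign, -b$sign)
    # the one-sided directional P of the swap is the complement
    expect_equal(a$directional_p + b$directional_p, 1)
  }
  # directional P is monotone where the raw signed value is not:
  # strong confirming < null < strong reversed
  expect_true(a$directional_p >= 0 && a$directional_p <= 1)
})

test_that("log-rank P ordering agrees with the exact permutation oracle", {
  fixtures <- list(
    list(time = c(1, 2, 3, 10, 12, 14), event = rep(1, 6),
         g1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),   # strong separation
    list(time = c(1, 9, 3, 8, 5, 7), event = rep(1, 6),
         g1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),   # interleaved
    list(time = c(2, 4, 6, 3, 5, 7), event = c(1, 1, 0, 1, 1, 1),
         g1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))    # weak
  )
  chi_p <- perm_p <- numeric(length(fixtures))
  for (i in seq_along(fixtures)) {
    f <- fixtures[[i]]
    g <- factor(ifelse(f$g1, "high", "low"), levels = c("low", "high"))
    chi_p[i] <- logrank_test(g, f$time, f$event)$p
    perm_p[i] <- logrank_permutation_p(f$g1, f$time, f$event)
  }
  expect_equal(order(chi_p), order(perm_p))
})

test_that("bootstrap returns exactly R paired signed values, reproducibly", {
  set.seed(8)
  n <- 60
  scores <- runif(n); time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.8)
  a <- bootstrap_signed_p(scores, time, event, resamples = 200, seed = 4)
  expect_length(a$signed_values, 200)
  expect_true(all(abs(a$signed_values) > 0 & abs(a$signed_values) <= 1))
  b <- bootstrap_signed_p(scores, time, event, resamples = 200, seed = 4)
  expect_identical(a$signed_values, b$signed_values)

  # matrix form: identical predictors get identical paired distributions
  m <- bootstrap_signed_p(cbind(x = scores, y = scores), time, event,
                          resamples = 100, seed = 9)
  expect_identical(m$x$signed_values, m$y$signed_values)

  tiny <- bootstrap_signed_p(c(0.1, 0.9), c(5, 6), c(1, 1),
                             resamples = 10, seed = 1, max_redraw = 50)
  expect_length(tiny$signed_values, 10)
  expect_error(bootstrap_signed_p(c(0.5, 0.5), c(5, 6), c(1, 1),
                                  resamples = 5, seed = 1, max_redraw = 5),
               "no valid resample")
})

test_that("predictor comparison follows the Wilcoxon signed-rank contract", {
  x <- runif(100, 0.2, 0.8)
  expect_equal(compare_predictors(x, x)$p, 1)

  set.seed(6)
  b <- abs(rnorm(1000, 0.3, 0.05))
  a <- b / 100  # a strictly below b in every pair
  cmp <- compare_predictors(a, b)
  expect_lt(cmp$p, 1e-4)
  expect_equal(cmp$stars, "****")
  # two-sided symmetry
  expect_equal(compare_predictors(a, b)$p, compare_predictors(b, a)$p)
  expect_error(compare_predictors(a[1:10], b), "length")
})

test_that("significance stars follow the reporting bands", {
  expect_equal(p_stars(5e-5), "****")
  expect_equal(p_stars(5e-4), "***")
  expect_equal(p_stars(5e-3), "**")
  expect_equal(p_stars(0.03), "*")
  expect_equal(p_stars(0.2), "ns")
})
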