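test_that("activity fraction spans its range and matches the formula", {
  expect_equal(activity_fraction(c(5, 5, 5, 5)), 0)
  expect_equal(activity_fraction(c(9, 0, 0, 0)), 1)
  # direct formula evaluation: (1 - 2.5^2 / 7.5) / 0.75
  expect_equal(activity_fraction(c(1, 2, 3, 4)),
               (1 - (2.5^2) / 7.5) / 0.75, tolerance = 1e-12)
  expect_equal(activity_fraction(c(1, 2, 3, 4)), 0.2222222,
               tolerance = 1e-6)
  expect_true(is.na(activity_fraction(c(0, 0, 0))))
  expect_error(activity_fraction(5), "at least 2")
  expect_error(activity_fraction(c(-1, 2)), "non-negative")
})

test_that("activity fraction is scale invariant", {
  set.seed(2)
  r <- runif(20, 0, 40)
  for (a in c(0.1, 3, 1000))
    expect_equal(activity_fraction(a * r), activity_fraction(r),
                 tolerance = 1e-12)
})

test_that("rate discretization uses equal-width right-closed-top bins", {
  r <- c(0, 7, 15, 23, 30)
  b <- discretize_rates(r, 15)          # width 2 over [0, 30]
  expect_equal(as.integer(b), c(1L, 4L, 8L, 12L, 15L))
  expect_false(attr(b, "degenerate"))

  b2 <- discretize_rates(0:14, 15)
  expect_equal(as.integer(b2), 1:15)    # one per bin

  b3 <- discretize_rates(rep(4, 10), 15)
  expect_true(attr(b3, "degenerate"))
  expect_true(all(b3 == 1L))
  expect_error(discretize_rates(1:3, 1), "n_bins")
})

test_that("entropies reproduce hand-computed values", {
  # deterministic code: 2 equiprobable classes in distinct bins
  e <- entropies(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(e$H_T, 1)
  expect_equal(e$H_N, 0)
  expect_equal(e$MI, 1)
  expect_equal(e$efficiency, 1)

  # class-independent responses: MI = 0
  e0 <- entropies(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(e0$MI, 0, tolerance = 1e-12)
  expect_equal(e0$efficiency, 0, tolerance = 1e-12)

  # 2 classes x 2 trials, bins {A: (0,0), B: (0,1)}:
  # p(r): r0 3/4, r1 1/4 -> H_T = 0.811278; H_N = 0.5; MI = 0.311278
  e2 <- entropies(c(0, 0, 0, 1), c("A", "A", "B", "B"))
  expect_equal(e2$H_T, -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(e2$H_T, 0.8112781, tolerance = 1e-6)
  expect_equal(e2$H_N, 0.5)
  expect_equal(e2$MI, 0.3112781, tolerance = 1e-6)
  expect_error(entropies(integer(0), character(0)), "empty")
})

test_that("entropies are invariant to bin and class relabeling", {
  set.seed(5)
  bins <- sample(1:6, 60, replace = TRUE)
  cls <- sample(letters[1:5], 60, replace = TRUE)
  e1 <- entropies(bins, cls)
  perm <- sample(1:6)
  e2 <- entropies(perm[bins], toupper(cls))
  expect_equal(e1, e2)
  expect_lte(e1$H_N, e1$H_T + 1e-9)
  expect_gte(e1$MI, -1e-9)
})

test_that("response_metrics ties the pieces together", {
  tbl <- data.frame(class = rep(c("A", "B"), each = 2), trial = c(1, 2),
                    count = c(2, 2, 0, 1), duration = 0.1,
                    rate = c(20, 20, 0, 10))
  m <- response_metrics(tbl, n_bins = 15)
  expect_equal(m$N, 2)
  expect_equal(m$A, activity_fraction(c(20, 5)))
  expect_gte(m$MI, 0)
  expect_equal(m$MI, m$H_T - m$H_N, tolerance = 1e-12)
})

test_that("paired comparison matches the textbook t statistic", {
  res <- paired_compare(c(1, 2, 3), c(2, 4, 5))
  d <- c(-1, -2, -2)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$n_neg, 3)

  same <- paired_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$mean_diff, 0)

  set.seed(1)
  up <- paired_compare(2:21 + 1 + rnorm(20, sd = 1e-3), 2:21)
  expect_gt(up$t, 100)
})

test_that("Pearson correlation handles signs and degeneracy", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 3)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  xs <- c(1, 3, 4, 7); ys <- c(2, 3, 7, 9)
  hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(correlate(xs, ys)$r, hand, tolerance = 1e-12)
  expect_true(is.na(correlate(rep(1, 5), 1:5)$r))
})

test_that("KS test flags distribution separation", {
  expect_equal(rate_distribution_test(1:10, 1:10)$D, 0)
  expect_equal(rate_distribution_test(1:5, 11:15)$D, 1)
  # hand case by CDF enumeration: max gap between ECDFs of
  # {1,2,3} and {2,3,4} is 1/3
  expect_equal(rate_distribution_test(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3,
               tolerance = 1e-12)
})

test_that("interaction F test isolates a slope difference", {
  # slopes differ by construction -> F on the interaction is exact via
  # closed-form least squares on this balanced 8-point design
  eps <- c(0.01, -0.02, 0.015, -0.005, -0.01, 0.02, -0.015, 0.005)
  df <- data.frame(y = c(1, 2, 3, 4, 1, 3, 5, 7) + eps,
                   g = rep(c("a", "b"), each = 4),
                   x = rep(1:4, 2))
  res <- interaction_test(df, "y", "g", "x")
  fit <- lm(y ~ g * x, df)
  expect_equal(res$F, anova(fit)["g:x", "F value"], tolerance = 1e-12)
  expect_gt(res$F, 1e3)   # near-perfectly linear groups with distinct slopes

  set.seed(4)
  null_df <- data.frame(y = rnorm(200), g = rep(c("a", "b"), 100),
                        x = rep(1:10, 20))
  resn <- interaction_test(null_df, "y", "g", "x")
  expect_lt(resn$F, 6)
  expect_error(interaction_test(data.frame(y = 1:4, g = "a", x = 1:4),
                                "y", "g", "x"), "rank")
})
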