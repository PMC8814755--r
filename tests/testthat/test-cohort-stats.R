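# Cohort statistics: pooled t, Tukey-Kramer, post hoc power, notched medians.

test_that("pooled t test agrees with the reference implementation", {
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(20 + s); b <- rnorm(31 - s, 0.4)
    r <- compare_two(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$statistic, unname(ref$statistic))
    expect_equal(r$p_value, ref$p.value)
    d_ref <- (mean(a) - mean(b)) /
      sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
    expect_equal(r$effect_size, d_ref)
  }
  # Welch variant against its reference
  set.seed(6)
  a <- rnorm(25, sd = 2); b <- rnorm(40)
  rw <- compare_two(a, b, var_equal = FALSE)
  refw <- t.test(a, b)
  expect_equal(rw$p_value, refw$p.value)
})

test_that("degenerate comparisons are handled explicitly", {
  x <- c(1, 2, 3)
  same <- compare_two(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  con1 <- rep(2, 5); con2 <- rep(3, 5)
  deg <- compare_two(con1, con2)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)

  eqc <- compare_two(rep(2, 5), rep(2, 6))
  expect_equal(eqc$p_value, 1)
  expect_false(eqc$degenerate)
})

test_that("power matches the noncentral-t benchmark and is monotone", {
  pp <- posthoc_power(0.5, 64, 64, alpha = 0.05)
  expect_equal(pp$power, 0.80, tolerance = 0.005)
  expect_equal(pp$min_effect_for_power80, 0.50, tolerance = 0.01)

  # cross-check against the independent implementation in base R
  for (case in list(c(0.3, 40, 40), c(0.8, 20, 20), c(0.5, 100, 100))) {
    mine <- posthoc_power(case[1], case[2], case[3])$power
    ref <- power.t.test(n = case[2], delta = case[1], sd = 1,
                        sig.level = 0.05, strict = TRUE)$power
    expect_equal(mine, ref, tolerance = 1e-6)
  }

  expect_equal(posthoc_power(0, 30, 30)$power, 0.05, tolerance = 1e-10)
  p_d <- vapply(seq(0.1, 1.5, by = 0.2),
                function(d) posthoc_power(d, 30, 30)$power, numeric(1))
  expect_true(all(diff(p_d) > 0))
  p_n <- vapply(c(10, 20, 40, 80, 160),
                function(n) posthoc_power(0.4, n, n)$power, numeric(1))
  expect_true(all(diff(p_n) > 0))

  # root-finding is consistent with the forward power function
  pp2 <- posthoc_power(0.3, 50, 70)
  expect_equal(posthoc_power(pp2$min_effect_for_power80, 50, 70)$power,
               0.80, tolerance = 1e-6)
})

test_that("Tukey-Kramer all-pairs agrees with TukeyHSD", {
  set.seed(13)
  g <- list(x = rnorm(20), y = rnorm(25, 1), z = rnorm(30, 0.2))
  r <- tukey_all_pairs(g)
  df <- data.frame(v = unlist(g),
                   f = factor(rep(names(g), times = lengths(g))))
  ref <- TukeyHSD(aov(v ~ f, df))$f
  key <- paste0(r$group_b, "-", r$group_a)
  expect_equal(r$p_value, unname(ref[key, "p adj"]), tolerance = 1e-10)

  # a group shifted by 3 pooled sd separates from both others
  set.seed(14)
  g2 <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, 3))
  r2 <- tukey_all_pairs(g2)
  sig <- r2$significant[order(paste(r2$group_a, r2$group_b))]
  expect_equal(sig, c(FALSE, TRUE, TRUE))  # ab, ac, bc
})

test_that("two-group input delegates to the pooled t test", {
  set.seed(15)
  g <- list(a = rnorm(20), b = rnorm(22, 0.7))
  r <- tukey_all_pairs(g)
  ref <- compare_two(g$a, g$b, group_a = "a", group_b = "b")
  expect_equal(r$p_value, ref$p_value)
  expect_equal(r$statistic, ref$statistic)
})

test_that("long-format cohort tables are accepted", {
  set.seed(16)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    metric = "wcdi",
                    value = c(rnorm(30), rnorm(30, 2), rnorm(30)))
  r <- tukey_all_pairs(tab, metric = "wcdi")
  expect_equal(nrow(r), 3L)
  expect_true(all(r$metric == "wcdi"))
})

test_that("notched summaries follow the McGill convention", {
  s <- notched_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$notch_high - s$median, 1.57 * 2 / sqrt(5))
  expect_equal(s$notch_low, 3 - 1.57 * 2 / sqrt(5))

  sc <- notched_summary(rep(4.2, 10))
  expect_equal(sc$notch_low, 4.2)
  expect_equal(sc$notch_high, 4.2)

  set.seed(17)
  v <- rlnorm(40)
  s1 <- notched_summary(v)
  s3 <- notched_summary(3 * v)
  for (f in c("median", "q1", "q3", "notch_low", "notch_high"))
    expect_equal(s3[[f]], 3 * s1[[f]])
})
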