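# Group summaries, one-way ANOVA and Duncan's multiple range test.

test_that("group summary: mean and SEM with the n-1 denominator", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_warning(s1 <- group_summary(5), "size 1")
  expect_equal(s1$sem, 0)
  expect_error(group_summary(numeric(0)), class = "validation_error")
})

test_that("SEM estimates track sigma/sqrt(n) in repeated sampling", {
  set.seed(17)
  sems <- replicate(400, group_summary(rnorm(10, 100, 30))$sem)
  expect_equal(mean(sems), 30 / sqrt(10), tolerance = 0.1)
})

test_that("ANOVA F matches an explicit sum-of-squares computation", {
  groups <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
                 c = c(13, 9, 11, 8, 7, 12))
  # independent oracle: classical ANOVA table assembled by hand
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1.0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(f_oracle, 9.2647059, tolerance = 1e-6)
  r <- one_way_anova(groups)
  expect_equal(r$F, f_oracle, tolerance = 1e-10)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 15)
  expect_equal(r$p, stats::pf(f_oracle, 2, 15, lower.tail = FALSE))
})

test_that("identical groups give F = 0, p = 1; degenerate variance errors", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_error(one_way_anova(list(a = c(2, 2), b = c(5, 5))),
               class = "degenerate_variance_error")
  expect_error(one_way_anova(list(a = c(1, 2))), class = "validation_error")
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), class = "validation_error")
})

test_that("four groups of ten give the (3, 36) df structure", {
  set.seed(23)
  r <- one_way_anova(setNames(lapply(1:4, function(i) rnorm(10)), letters[1:4]))
  expect_equal(r$df_between, 3)
  expect_equal(r$df_within, 36)
})

test_that("F is invariant to shifting and scaling the data", {
  set.seed(29)
  for (i in 1:20) {
    g <- list(a = rnorm(6), b = rnorm(8, 1), c = rnorm(5))
    f0 <- one_way_anova(g)$F
    shifted <- lapply(g, function(v) 3.7 * v + 12)
    expect_equal(one_way_anova(shifted)$F, f0, tolerance = 1e-10)
  }
})

test_that("protection-level quantiles reproduce Duncan's published table", {
  # Duncan's significant studentized ranges, alpha = 0.05, df = 20:
  # r = 2: 2.95, r = 3: 3.10, r = 4: 3.19
  q <- vapply(2:4, function(r)
    stats::qtukey(1 - (1 - (1 - 0.05)^(r - 1)), r, 20), 1.0)
  expect_equal(q, c(2.95, 3.10, 3.19), tolerance = 0.005)
})

test_that("Duncan with two groups reproduces the pooled t-test decision", {
  set.seed(41)
  agree <- replicate(100, {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    g <- list(a = rnorm(n1), b = rnorm(n2, sample(c(0, 1.5), 1)))
    alpha <- runif(1, 0.005, 0.2)
    d <- suppressMessages(duncan_posthoc(g, alpha = alpha, pvalues = FALSE))
    t <- stats::t.test(g$a, g$b, var.equal = TRUE)$p.value <= alpha
    d$pairs$significant == t
  })
  expect_true(all(agree))
})

test_that("Duncan p-values agree with the t-test p for two groups", {
  g <- list(a = c(5.1, 4.9, 5.3, 5.0), b = c(6.2, 6.0, 6.4, 6.1))
  d <- duncan_posthoc(g)
  expect_equal(d$pairs$p_value,
               stats::t.test(g$a, g$b, var.equal = TRUE)$p.value,
               tolerance = 1e-3)
  expect_equal(d$pairs$star_level, 3)
})

test_that("identical groups yield no significant pairs and zero stars", {
  d <- duncan_posthoc(list(a = c(1, 2, 3), b = c(1.0, 2.0, 3.0) + 1e-9,
                           c = c(1, 2, 3)))
  expect_false(any(d$pairs$significant))
  expect_true(all(d$pairs$star_level == 0))
})

test_that("star levels are monotone and imply significance", {
  set.seed(43)
  for (i in 1:25) {
    g <- setNames(lapply(1:4, function(k) rnorm(6, k * runif(1, 0, 2))), letters[1:4])
    d <- duncan_posthoc(g, alpha = 0.05)
    p <- d$pairs
    expect_true(all(p$star_level[p$star_level >= 2] >= 1))
    expect_true(all(p$significant[p$star_level > 0]))
    # star levels consistent with the bisected p-values
    expect_equal(p$star_level, rowSums(outer(p$p_value, c(0.05, 0.01, 0.001), "<=")))
  }
})

test_that("a group mean shifted by 3 sigma is flagged against all others", {
  set.seed(47)
  hits <- replicate(150, {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10, 3))
    p <- duncan_posthoc(g, 0.05, pvalues = FALSE)$pairs
    dd <- p[p$group_a == "d" | p$group_b == "d", ]
    all(dd$significant)
  })
  expect_gte(mean(hits), 0.95)
})
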