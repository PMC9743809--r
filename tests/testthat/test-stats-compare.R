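test_that("the normality gate routes skewed data to the nonparametric path", {
  set.seed(4)
  skewed <- rlnorm(500, 0, 1)
  g <- shapiro_gate(skewed)
  expect_lt(g$p, 0.001)
  expect_true(g$nonparametric)

  normal <- rnorm(500)
  g2 <- shapiro_gate(normal)
  expect_false(g2$degenerate)
  expect_true(is.logical(g2$nonparametric))

  gd <- shapiro_gate(rep(1, 10))
  expect_true(gd$degenerate)
  expect_true(is.na(gd$p))
  expect_error(shapiro_gate(c(1, 2)), "unsupported-size")
})

test_that("the rank-sum statistic and exact p match hand enumeration", {
  rt <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(rt$W, 3)
  expect_true(rt$exact)
  expect_equal(rt$p, 2 / 6)
  # descriptives mirror the table schema
  expect_equal(rt$median1, 1.5)
  expect_equal(rt$mean2, 3.5)
})

test_that("rank sums of the two orderings always partition N(N+1)/2", {
  set.seed(9)
  for (i in 1:40) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    # ties on purpose: values drawn from a small integer support
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    N <- n1 + n2
    expect_equal(mann_whitney(x, y)$W + mann_whitney(y, x)$W,
                 N * (N + 1) / 2)
    expect_gte(mann_whitney(x, y)$W, n1 * (n1 + 1) / 2)
  }
})

test_that("the normal-approximation path agrees with the reference rank test", {
  set.seed(13)
  for (i in 1:20) {
    x <- round(rnorm(30, 0, 2), 1)  # rounding induces ties
    y <- round(rnorm(35, 0.5, 2), 1)
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_false(ours$exact)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic))
  }
})

test_that("exact p-values match the brute-force enumeration oracle", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- sample(setdiff(1:100, x), n2)
    ours <- mann_whitney(x, y)
    expect_true(ours$exact)
    dist <- oracle_ranksum_dist(n1, n2)
    expect_equal(ours$p, oracle_ranksum_p(ours$W, dist))
  }
})

test_that("empty or non-finite samples are rejected", {
  expect_error(mann_whitney(numeric(0), 1:3), "invalid-input")
  expect_error(mann_whitney(c(1, NA), 1:3), "invalid-input")
})

test_that("Spearman's rho matches rank algebra and its reference p-values", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  r <- spearman_cor(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r$rho, 0.5)
  expect_true(r$exact)

  # permutation path against direct enumeration through cor.test's exact p
  set.seed(2)
  x <- rnorm(7); y <- rnorm(7)
  ours <- spearman_cor(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  # t-approximation path equals the Pearson t test applied to midranks
  set.seed(3)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ours2 <- spearman_cor(x, y)
  ref2 <- stats::cor.test(rank(x), rank(y), method = "pearson")
  expect_false(ours2$exact)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)

  expect_error(spearman_cor(rep(1, 5), 1:5), "undefined-correlation")
  expect_error(spearman_cor(1:2, 1:2), "invalid-input")
})

test_that("comparison tables have one row pair per measure with shared W/p", {
  set.seed(5)
  d <- do.call(rbind, lapply(sprintf("M%02d", 1:12), function(mm) {
    data.frame(measure = mm,
               condition = rep(1:2, each = 30),
               value = c(rnorm(30), rnorm(30, 0.5)))
  }))
  tab <- comparison_table(d)
  expect_identical(nrow(tab), 24L)
  expect_identical(sum(!is.na(tab$W)), 12L)
  expect_identical(sum(!is.na(tab$p_value)), 12L)

  # adjusted p column appears on request
  tadj <- comparison_table(d, adjust = "holm")
  expect_true("p_adj" %in% names(tadj))
  expect_true(all(tadj$p_adj >= tadj$p_value, na.rm = TRUE))
})

test_that("identical groups produce p near 1 and no significance flags", {
  d <- data.frame(measure = "flat", condition = rep(1:2, each = 20),
                  value = rep(1:20, 2))
  tab <- comparison_table(d)
  expect_gt(tab$p_value[1], 0.9)
  expect_identical(tab$signif[1], "")
})

test_that("simulated reaction times order their condition medians as configured", {
  set.seed(8)
  b <- simulate_session(102, eeg = NULL, gaze = NULL, seed = 8)
  log <- b$task_log
  keep <- log$choice != "none"
  d <- data.frame(measure = "Reaction time", condition = log$n_back[keep],
                  value = log$reaction_time[keep])
  tab <- comparison_table(d)
  expect_gt(tab$Median[tab$N_back == "2"], tab$Median[tab$N_back == "1"])
})
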