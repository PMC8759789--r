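test_that("quantile splits assign threshold ties to the lower group", {
  # value exactly at the median goes low
  v <- c(1, 2, 3, 4, 5)
  g <- quantile_split(v, "median")
  expect_identical(as.character(g), c("low", "low", "low", "high", "high"))
  # 26 distinct values split 13 / 13
  set.seed(61)
  v26 <- sample(seq(0.1, 26, by = 1))
  g26 <- quantile_split(v26, "median")
  expect_equal(as.vector(table(g26)), c(13L, 13L))
  # tertile split of 1..9 gives 3/3/3
  g9 <- quantile_split(1:9, "tertile")
  expect_equal(as.vector(table(g9)), c(3L, 3L, 3L))
  # property: no value equal to the threshold lands in the upper group
  for (i in 1:20) {
    x <- sample(1:10, 12, replace = TRUE)
    med <- quantile(x, 0.5, type = 7, names = FALSE)
    gx <- quantile_split(x, "median")
    expect_false(any(gx == "high" & x <= med))
  }
  expect_warning(quantile_split(rep(2, 5), "median"), "all values equal")
})

test_that("log-rank O/E, variance and p match the hand-tabulation oracle", {
  # 6-subject textbook-style instance, tabulated independently
  times <- c(6, 7, 10, 15, 19, 25)
  events <- c(1, 0, 1, 1, 0, 1)
  groups <- factor(c("low", "low", "low", "high", "high", "high"),
                   levels = c("low", "high"))
  res <- logrank_hr(times, events, groups)
  ref <- oracle_logrank(times, events, groups)
  expect_equal(res$observed, ref$O, tolerance = 1e-12)
  expect_equal(res$expected, ref$E, tolerance = 1e-9)
  expect_equal(res$p_logrank, ref$p, tolerance = 1e-9)
  expect_equal(res$hr, ref$hr, tolerance = 1e-9)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)

  # random instances, including tied times and heavy censoring
  set.seed(62)
  for (i in 1:25) {
    n <- sample(c(10, 20, 40), 1)
    tt <- sample(1:15, n, replace = TRUE)
    ev <- runif(n) < 0.7
    gg <- factor(sample(c("low", "high"), n, replace = TRUE),
                 levels = c("low", "high"))
    if (length(unique(gg)) < 2 || sum(ev) == 0) next
    r <- suppressWarnings(logrank_hr(tt, ev, gg))
    o <- oracle_logrank(tt, ev, gg)
    expect_equal(r$observed, o$O, tolerance = 1e-9)
    expect_equal(r$expected, o$E, tolerance = 1e-9)
    expect_equal(r$p_logrank, o$p, tolerance = 1e-9)
  }
})

test_that("log-rank is symmetric under label swap and null under duplication", {
  times <- c(3, 5, 8, 8, 12, 16, 20, 22)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g1 <- factor(rep(c("a", "b"), 4), levels = c("a", "b"))
  g2 <- factor(rep(c("b", "a"), 4), levels = c("a", "b"))
  r1 <- logrank_hr(times, events, g1)
  r2 <- logrank_hr(times, events, g2)
  expect_equal(r1$p_logrank, r2$p_logrank, tolerance = 1e-12)
  expect_equal(r1$hr, 1 / r2$hr, tolerance = 1e-12)
  # identical groups duplicated -> HR 1, p 1
  rd <- logrank_hr(rep(c(4, 9, 13), 2), rep(c(1, 1, 0), 2),
                   factor(rep(c("a", "b"), each = 3)))
  expect_equal(rd$hr, 1, tolerance = 1e-12)
  expect_equal(rd$p_logrank, 1, tolerance = 1e-12)
})

test_that("Mann-Whitney exact path equals full enumeration", {
  # complete separation at n1 = n2 = 3: two-sided exact p = 2/20
  res <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$U, 9)
  # identical samples -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # random small tie-free instances vs enumeration
  set.seed(63)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    pool <- sample(seq(0.01, 1, by = 0.01), n1 + n2)
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    got <- mann_whitney(x, y)
    ref <- oracle_mw_exact(x, y)
    expect_equal(got$U, ref$U, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H matches the direct rank formula and Dunn flags pairs", {
  g <- list(a = c(27, 2, 4), b = c(18, 7, 9), c = c(20, 10, 1))
  res <- kruskal_dunn(g)
  # direct rank-sum formula, no ties: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  r <- rank(unlist(g))
  Ri <- tapply(r, rep(names(g), lengths(g)), sum)
  H <- 12 / (9 * 10) * sum(Ri^2 / 3) - 3 * 10
  expect_equal(unname(res$H), H, tolerance = 1e-12)
  expect_equal(res$p_overall,
               pchisq(H, df = 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))

  # identical copies -> H = 0, p = 1
  same <- list(a = 1:4, b = 1:4, c = 1:4)
  res0 <- kruskal_dunn(same)
  expect_equal(unname(res0$H), 0, tolerance = 1e-12)
  expect_equal(res0$p_overall, 1)

  # strong separation yields a significant adjusted pair
  far <- list(a = 1:5, b = 101:105, c = 1001:1005)
  resf <- kruskal_dunn(far)
  expect_true(any(resf$pairwise$p_adj < 0.05))

  # zero-variance pooled ranks -> p 1
  flat <- kruskal_dunn(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_equal(flat$p_overall, 1)
})

test_that("Spearman rho and t-approximation p match the ranks oracle", {
  expect_equal(spearman_test(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_test(1:8, -(1:8))$rho, -1)
  set.seed(64)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties likely
    y <- x + rnorm(n, sd = 3)
    got <- spearman_test(x, y)
    ref <- oracle_spearman(x, y)
    expect_equal(got$rho, ref$rho, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
  expect_warning(z <- spearman_test(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$rho))
})

test_that("two-proportion z matches the pooled formula and the chi-square identity", {
  res <- two_prop_z(20, 100, 10, 100)
  expect_equal(res$z, oracle_two_prop_z(20, 100, 10, 100), tolerance = 1e-12)
  # z^2 equals the uncorrected 2x2 chi-square
  set.seed(65)
  for (i in 1:30) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- rbinom(1, n1, 0.3); k2 <- rbinom(1, n2, 0.4)
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
    r <- two_prop_z(k1, n1, k2, n2)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(r$z^2, unname(chi), tolerance = 1e-9)
    expect_equal(r$p,
                 suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                 tolerance = 1e-9)
  }
  expect_equal(two_prop_z(3, 10, 6, 20)$p, 1)  # equal proportions
  expect_equal(two_prop_z(0, 10, 0, 20), list(z = 0, p = 1))
})

test_that("rank tests are calibrated under the null", {
  set.seed(66)
  reps <- 400
  rej_mw <- mean(replicate(reps, {
    mann_whitney(rnorm(8), rnorm(8))$p < 0.05
  }))
  expect_lt(rej_mw, 0.08)
  rej_sp <- mean(replicate(reps, {
    spearman_test(rnorm(10), rnorm(10))$p < 0.05
  }))
  expect_gt(rej_sp, 0.02)
  expect_lt(rej_sp, 0.08)
})
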