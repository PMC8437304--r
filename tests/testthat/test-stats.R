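test_that("Friedman statistic matches hand computation and base R", {
  # full ties: Q = 0, p = 1
  tied <- matrix(rep(c(2, 2, 2), 4), 4, 3, byrow = TRUE)
  ft <- friedman_test(tied)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)

  # two subjects both ranking the columns 1, 2, 3: Q = 4
  m <- rbind(c(1.1, 2.3, 3.0), c(0.9, 2.1, 3.3))
  expect_equal(friedman_test(m)$statistic, 4)

  # agrees with stats::friedman.test on untied data
  set.seed(9)
  x <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(friedman_test(x)$statistic,
               unname(stats::friedman.test(x)$statistic), tolerance = 1e-12)
  expect_equal(friedman_test(x)$p.value,
               stats::friedman.test(x)$p.value, tolerance = 1e-12)

  expect_error(friedman_test(matrix(c(1, 2, NA, 3, 4, 5), 2, 3)), "missing")
  expect_error(friedman_test(matrix(rnorm(4), 2, 2)), "3 timepoints")
})

test_that("chi-squared p matches exact permutation enumeration (n = 8, k = 3)", {
  set.seed(12)
  n <- 8; k <- 3
  x <- matrix(rnorm(n * k), n, k)
  obs <- friedman_test(x)

  # exact enumeration over all 6^8 within-subject rank orders, carried as a
  # dynamic program over the (R1, R2) rank-sum lattice
  ords <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cnt <- matrix(0, 3 * n + 1, 3 * n + 1)
  cnt[1, 1] <- 1
  for (s in seq_len(n)) {
    nxt <- matrix(0, 3 * n + 1, 3 * n + 1)
    for (o in 1:6) {
      i <- ords[o, 1]; j <- ords[o, 2]
      idx <- which(cnt > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(idx)))
        nxt[idx[r, 1] + i, idx[r, 2] + j] <-
          nxt[idx[r, 1] + i, idx[r, 2] + j] + cnt[idx[r, 1], idx[r, 2]]
    }
    cnt <- nxt
  }
  states <- which(cnt > 0, arr.ind = TRUE)
  R1 <- states[, 1] - 1; R2 <- states[, 2] - 1; R3 <- 6 * n - R1 - R2
  q <- 12 / (n * k * (k + 1)) * (R1^2 + R2^2 + R3^2) - 3 * n * (k + 1)
  p_exact <- sum(cnt[states][q >= obs$statistic - 1e-9]) / 6^n
  expect_lt(abs(p_exact - obs$p.value), 0.05)
})

test_that("baseline contrasts are Bonferroni-adjusted and handle degeneracy", {
  set.seed(3)
  tab <- expand.grid(eye_id = paste0("e", 1:8),
                     timepoint = c("baseline", "1m", "2m", "3m", "6m"),
                     stringsAsFactors = FALSE)
  tab$value <- rnorm(nrow(tab), 0.5, 0.05)
  res <- paired_tests_bonferroni(tab, method = "t")
  expect_equal(nrow(res), 4)
  expect_equal(res$p_adj, pmin(1, 4 * res$p_raw))

  # dropout: complete cases per contrast
  tab2 <- tab[!(tab$eye_id %in% c("e1", "e2") & tab$timepoint == "6m"), ]
  res2 <- paired_tests_bonferroni(tab2, method = "wilcoxon")
  expect_equal(res2$n[res2$timepoint == "6m"], 6)
  expect_equal(res2$n[res2$timepoint == "1m"], 8)

  # zero-variance differences: degenerate, p = 1
  tab3 <- tab
  tab3$value <- 0.5
  res3 <- paired_tests_bonferroni(tab3)
  expect_true(all(res3$degenerate))
  expect_true(all(res3$p_adj == 1))
})

test_that("null longitudinal tables keep the family-wise error below 5%", {
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    tab <- expand.grid(eye_id = paste0("e", 1:11),
                       timepoint = c("baseline", "1m", "2m", "3m", "6m"),
                       stringsAsFactors = FALSE)
    tab$value <- rnorm(nrow(tab), 0.5, 0.05)
    any(paired_tests_bonferroni(tab, method = "wilcoxon")$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("Pearson correlation matches closed forms and cor.test", {
  x <- seq(-3, 3, length.out = 11)
  r1 <- pearson_corr(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$r_squared, 1)

  # anti-symmetric x against even y: exactly uncorrelated
  r0 <- pearson_corr(x, x^2)
  expect_equal(r0$r, 0, tolerance = 1e-12)

  set.seed(5)
  a <- rnorm(25); b <- 0.6 * a + rnorm(25)
  ct <- stats::cor.test(a, b)
  mine <- pearson_corr(a, b)
  expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(mine$p.value, ct$p.value, tolerance = 1e-10)

  # affine invariance (positive slope)
  tr <- pearson_corr(3 * a - 2, 0.5 * b + 7)
  expect_equal(tr$r, mine$r, tolerance = 1e-12)

  # degenerate input flagged
  dg <- pearson_corr(rep(1, 5), rnorm(5))
  expect_true(dg$degenerate)
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("estimated r-squared recovers the population value", {
  b <- 1; sx <- 0.3; se <- 0.3
  pop_r2 <- b^2 * sx^2 / (b^2 * sx^2 + se^2)  # 0.5
  set.seed(11)
  r2 <- vapply(1:100, function(i) {
    x <- rnorm(40, 0, sx)
    y <- 2 + b * x + rnorm(40, 0, se)
    pearson_corr(x, y)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - pop_r2), 0.05)
})

test_that("change rates are relative to a positive baseline", {
  expect_equal(change_rate(400, 320), -0.2)
  expect_equal(change_rate(250, 250), 0)
  expect_equal(change_rate(0.30, 0.36), 0.2)
  expect_error(change_rate(0, 1), "positive")
})

test_that("two-group comparisons use the standard formulas", {
  set.seed(2)
  a <- rnorm(10)
  t_same <- group_compare(a, a, kind = "t")
  expect_equal(t_same$p.value, 1)
  mw <- group_compare(a, a, kind = "mann_whitney")
  expect_equal(mw$statistic, 10 * 10 / 2)

  # 2x2 table (6,5; 9,2): hand formula without continuity correction
  cs <- group_compare(c(6, 5), c(9, 2), kind = "chi_square")
  n <- 22
  hand <- n * (6 * 2 - 5 * 9)^2 / (11 * 11 * 15 * 7)
  expect_equal(cs$statistic, hand, tolerance = 1e-12)
  expect_equal(round(cs$p.value, 2), 0.17)

  expect_error(group_compare(numeric(0), a), "empty")
})

test_that("the t comparison holds its nominal type-I error", {
  set.seed(8)
  n_rep <- 4000
  rej <- vapply(seq_len(n_rep), function(i) {
    group_compare(rnorm(10), rnorm(10), kind = "t")$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.012)
})
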