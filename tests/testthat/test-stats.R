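test_that("group summaries average replicates within sample before mean/SEM across samples", {
  d <- data.frame(group = "g", sample = rep(1:3, each = 2),
                  replicate = rep(1:2, 3), t_min = 120,
                  value = c(1.5, 2.5, 3, 5, 6, 6))   # sample means 2, 4, 6
  s <- summarize_group(d, "t_min", "value")
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  expect_equal(s$n_samples, 3L)

  one <- data.frame(group = "g", sample = 1, replicate = 1:4, t_min = 0,
                    value = 1:4)
  s1 <- summarize_group(one, "t_min", "value")
  expect_equal(s1$mean, 2.5)
  expect_true(is.na(s1$sem))
  expect_false(s1$sem_defined)

  # missing replicate value: sample mean over the remaining replicates
  miss <- d; miss$value[2] <- NA
  sm <- summarize_group(miss, "t_min", "value")
  expect_equal(sm$mean, mean(c(1.5, 4, 6)))

  # invariant to replicate ordering
  perm <- d[sample(nrow(d)), ]
  expect_equal(summarize_group(perm, "t_min", "value")$mean, s$mean)
})

test_that("exact Mann-Whitney reproduces enumeration on the textbook case and symmetric inputs", {
  r <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$statistic, 0)

  same <- mann_whitney_exact(c(3, 1, 4, 1, 5), c(1, 5, 4, 3, 1))
  expect_equal(same$statistic, 25 / 2)       # U = n^2 / 2 on identical multisets
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney equals the pair-counting permutation oracle for all n1, n2 <= 6", {
  set.seed(61)
  for (trial in 1:50) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(1:8, n1, replace = TRUE)     # ties likely
    y <- sample(1:8, n2, replace = TRUE)
    mine <- mann_whitney_exact(x, y)
    expect_true(mine$exact)
    expect_equal(mine$p_value, oracle_mw_p(x, y),
                 info = sprintf("x=%s y=%s", toString(x), toString(y)))
  }
})

test_that("Mann-Whitney p is label-symmetric and invariant under monotone transforms", {
  set.seed(62)
  x <- rnorm(6); y <- rnorm(7, 1)
  a <- mann_whitney_exact(x, y); b <- mann_whitney_exact(y, x)
  expect_equal(a$p_value, b$p_value)
  mono <- function(v) exp(3 * v) - 5
  expect_equal(mann_whitney_exact(mono(x), mono(y))$p_value, a$p_value)
})

test_that("Kruskal-Wallis matches the hand-rank oracle and handles degenerate input", {
  g <- list(c(27.0, 14.5, 8.8, 9.1), c(38.7, 26.3, 21.2, 30.0),
            c(11.1, 15.6, 20.0, 16.2))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, oracle_kw_h(g), tolerance = 1e-10)
  expect_equal(kw$df, 2L)

  tied <- list(c(1, 2, 2), c(2, 3, 1), c(2, 2, 4))
  expect_equal(kruskal_wallis(tied)$statistic, oracle_kw_h(tied),
               tolerance = 1e-10)

  degen <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis holds its nominal type-I error on three null groups", {
  set.seed(63)
  rej <- mean(replicate(1000, {
    kruskal_wallis(list(rnorm(5), rnorm(5), rnorm(5)))$p_value <= 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("the Grubbs statistic and p-value follow the two-sided t relation", {
  g <- grubbs_test(c(-1, 0, 1))
  expect_equal(g$statistic, 1)

  # p decreases monotonically as the extreme point moves outward
  ps <- vapply(c(3, 5, 8, 15), function(ext)
    grubbs_test(c(1.2, 0.8, 1.0, 1.1, 0.9, ext))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))

  # formula oracle on random samples
  set.seed(64)
  for (trial in 1:30) {
    x <- rnorm(sample(4:12, 1))
    n <- length(x)
    gg <- max(abs(x - mean(x))) / sd(x)
    gsc <- gg * sqrt(n) / (n - 1)
    p_ref <- if (gsc >= 1) 0 else {
      tval <- sqrt((n - 2) * gsc^2 / (1 - gsc^2))
      min(1, 2 * n * pt(tval, n - 2, lower.tail = FALSE))
    }
    expect_equal(grubbs_test(x)$p_value, p_ref, tolerance = 1e-8)
  }
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  expect_error(grubbs_test(c(2, 2, 2)), "variability")
})

test_that("Grubbs p-values are calibrated against a Monte Carlo null", {
  set.seed(65)
  n <- 7L
  sim <- replicate(4000, grubbs_test(rnorm(n))$p_value)
  rej <- mean(sim <= 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("the curve permutation test is symmetric, calibrated on identical groups and powered", {
  mk <- function(lam_by_sample, group, noise_sd = 3, seed) {
    set.seed(seed)
    grid <- seq(20, 120, by = 20)
    do.call(rbind, lapply(seq_along(lam_by_sample), function(s)
      do.call(rbind, lapply(1:4, function(r)
        data.frame(group = group, sample = s, replicate = r, t_min = grid,
                   value = lam_by_sample[s] * (1 - exp(-grid / 40)) +
                     rnorm(length(grid), 0, noise_sd))))))
  }
  null_d <- rbind(mk(rep(60, 5), "a", seed = 1), mk(rep(60, 5), "b", seed = 2))
  pn <- curve_permutation_test(null_d, "t_min", "value", seed = 3)
  expect_gt(pn$p_value, 0.1)
  # swapping labels leaves p unchanged
  swapped <- null_d
  swapped$group <- ifelse(null_d$group == "a", "b", "a")
  expect_equal(curve_permutation_test(swapped, "t_min", "value", seed = 3)$p_value,
               pn$p_value)
  # exhaustive enumeration below n_perm
  small <- rbind(mk(rep(60, 3), "a", seed = 4), mk(rep(60, 3), "b", seed = 5))
  expect_true(curve_permutation_test(small, "t_min", "value",
                                     n_perm = 999, seed = 6)$exact)
  # power: schedules saturating at 37 vs 115 um, n = 7 x 4, 20 harness seeds
  hits <- vapply(1:20, function(s) {
    d <- rbind(mk(rep(37, 7), "suckling", noise_sd = 6, seed = 100 + s),
               mk(rep(115, 7), "weaned", noise_sd = 6, seed = 200 + s))
    curve_permutation_test(d, "t_min", "value", n_perm = 299,
                           seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
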