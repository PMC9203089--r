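test_that("r-squared matches the brute-force covariance formula", {
  pred <- c(1.1, 1.9, 3.2, 3.8)
  tsb <- c(1, 2, 3, 4)
  rs <- r_squared(pred, tsb)
  byhand <- (sum((pred - mean(pred)) * (tsb - mean(tsb))))^2 /
    (sum((pred - mean(pred))^2) * sum((tsb - mean(tsb))^2))
  expect_equal(rs$r_squared, byhand, tolerance = 1e-12)
  expect_equal(r_squared(tsb, tsb)$r_squared, 1)
  expect_equal(r_squared(-tsb + 10, tsb)$r_squared, 1)
  expect_error(r_squared(rep(2, 4), tsb), "undefined-correlation")
  expect_error(r_squared(1:2, 1:2), "insufficient-data")
})

test_that("Bland-Altman bias, limits and span follow the 1.96-SD definition", {
  tsb <- c(3, 7, 12)
  ba <- bland_altman(tsb + 1, tsb)
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_span, 0)
  d <- c(-2, 0, 2)
  ba2 <- bland_altman(tsb + d, tsb)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, 2)
  expect_equal(ba2$loa_upper, 3.92)
  expect_equal(ba2$loa_lower, -3.92)
  expect_equal(ba2$loa_span, ba2$loa_upper - ba2$loa_lower)
  expect_error(bland_altman(1, 1), "insufficient-data")
})

test_that("RMSE by range bins by TSB and drops empty bins", {
  tsb <- c(2, 4, 8, 14, 20)
  pred <- tsb
  expect_true(all(rmse_by_range(pred, tsb) == 0))
  pred2 <- tsb + c(1, 2, 2, 0, 0)
  out <- rmse_by_range(pred2, tsb, edges = c(0, 10, 25))
  expect_equal(unname(out[1]), sqrt(mean(c(1, 4, 4))))
  expect_equal(unname(out[2]), 0)
  out3 <- rmse_by_range(3, 3, edges = c(0, 10, 20, 25))
  expect_length(out3, 1L)   # single member, error 0; empty bins absent
  expect_equal(unname(rmse_by_range(6, 3, edges = c(0, 10))[1]), 3)
})

test_that("group RMSE and the Welch test match hand computation", {
  tsb <- rep(10, 6)
  pred <- 10 + c(1, 2, 3, 2, 3, 4)
  grp <- rep(c("light", "dark"), each = 3)
  out <- rmse_by_group(pred, tsb, grp, compare = c("light", "dark"))
  expect_equal(unname(out$rmse["light"]), sqrt(mean(c(1, 4, 9))))
  expect_equal(unname(out$rmse["dark"]), sqrt(mean(c(4, 9, 16))))
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(out$t, tstat, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(abs(tstat), df, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate group comparisons are handled", {
  tsb <- rep(10, 10)
  grp <- rep(c("a", "b"), each = 5)
  same <- rmse_by_group(tsb + rep(c(1, 2, 1, 2, 1), 2), tsb, grp,
                        compare = c("a", "b"))
  expect_equal(same$p, 1, tolerance = 1e-9)
  sep <- rmse_by_group(tsb + rep(c(0, 5), each = 5), tsb, grp,
                       compare = c("a", "b"))
  expect_lt(sep$p, 0.05)
  expect_warning(rmse_by_group(tsb + 1, tsb, c(rep("a", 9), "b"),
                               compare = c("a", "a")),
                 "excluded")
})

test_that("agreement statistics are scale-equivariant and permutation-invariant", {
  set.seed(31)
  tsb <- runif(20, 1, 20)
  pred <- tsb * 0.9 + rnorm(20)
  rep1 <- agreement_report(pred, tsb)
  # scaling both measurements scales mg/dL quantities and preserves r^2
  c0 <- 2.5
  rep2 <- agreement_report(c0 * pred, c0 * tsb, range_edges = c(0, 10, 25) * c0)
  expect_equal(rep2$r_squared, rep1$r_squared, tolerance = 1e-12)
  expect_equal(rep2$bias, c0 * rep1$bias, tolerance = 1e-12)
  expect_equal(rep2$loa_span, c0 * rep1$loa_span, tolerance = 1e-12)
  expect_equal(unname(rep2$rmse_by_range), unname(c0 * rep1$rmse_by_range),
               tolerance = 1e-12)
  # permutation invariance
  perm <- sample(20)
  rep3 <- agreement_report(pred[perm], tsb[perm])
  expect_equal(rep3$r_squared, rep1$r_squared, tolerance = 1e-12)
  expect_equal(rep3$bias, rep1$bias, tolerance = 1e-12)
  expect_equal(rep3$rmse_by_range, rep1$rmse_by_range, tolerance = 1e-12)
})
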