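test_that("reference-positive conditionals reduce correctly under a perfect reference", {
  # perfect reference: the conditional is the PPV (resp. 1 - NPV)
  expect_equal(p_dpos_given_tpos(0.5, 0.5, 0.5, 1, 1), 0.5)
  ppv <- function(sT, cT, prev) prev * sT / (prev * sT + (1 - prev) * (1 - cT))
  expect_equal(p_dpos_given_tpos(0.9, 0.95, 0.3, 1, 1), ppv(0.9, 0.95, 0.3),
               tolerance = 1e-12)
  one_minus_npv <- function(sT, cT, prev) {
    prev * (1 - sT) / (prev * (1 - sT) + (1 - prev) * cT)
  }
  expect_equal(p_dpos_given_tneg(0.9, 0.95, 0.3, 1, 1),
               one_minus_npv(0.9, 0.95, 0.3), tolerance = 1e-12)
  # no false negatives: a negative test guarantees absence of disease
  expect_equal(p_dpos_given_tneg(1, 0.8, 0.4, 1, 1), 0)
  expect_error(p_dpos_given_tpos(0, 1, 0.5, 1, 1), "undefined")
})

test_that("imperfect-reference conditionals match the joint-probability-table oracle", {
  grid <- expand.grid(sT = c(0.6, 0.9), cT = c(0.7, 0.95),
                      prev = c(0.2, 0.6), sD = c(0.85, 1), cD = c(0.85, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    want <- eq_oracle(g$sT, g$cT, g$prev, g$sD, g$cD)
    expect_equal(p_dpos_given_tpos(g$sT, g$cT, g$prev, g$sD, g$cD),
                 want[["p_rpos_tpos"]], tolerance = 1e-12)
    expect_equal(p_dpos_given_tneg(g$sT, g$cT, g$prev, g$sD, g$cD),
                 want[["p_rpos_tneg"]], tolerance = 1e-12)
    # probabilities stay in [0,1] across the grid
    expect_gte(p_dpos_given_tpos(g$sT, g$cT, g$prev, g$sD, g$cD), 0)
    expect_lte(p_dpos_given_tpos(g$sT, g$cT, g$prev, g$sD, g$cD), 1)
  }
  # monotone in prevalence under a perfect reference
  vals <- sapply(seq(0.05, 0.95, by = 0.1),
                 function(p) p_dpos_given_tpos(0.8, 0.9, p, 1, 1))
  expect_true(all(diff(vals) > 0))
})

test_that("log-posterior equals independently summed binomial and prior terms", {
  s <- stratum_data(804, 803, 139, 24, gold = "histology")
  priors <- default_priors("histology", "main")
  params <- c(sT = 0.86, cT = 0.998, prev = 0.62)
  got <- log_posterior(params, list(s), priors)
  # term-by-term arithmetic with the conditionals computed separately
  p1 <- p_dpos_given_tpos(0.86, 0.998, 0.62, 1, 1)
  p2 <- p_dpos_given_tneg(0.86, 0.998, 0.62, 1, 1)
  want <- 803 * log(p1) + 1 * log(1 - p1) + 24 * log(p2) + 115 * log(1 - p2)
  # flat Beta(1,1) priors contribute zero on the log scale
  expect_equal(got, want, tolerance = 1e-10)
  expect_true(is.finite(got))
  # empty data leaves only the log-prior
  prior_only <- log_posterior(params, list(), priors)
  expect_equal(prior_only, 0, tolerance = 1e-12)
  # boundary parameter values are -Inf, not an error
  expect_equal(log_posterior(c(sT = 0, cT = 0.9, prev = 0.5), list(s), priors),
               -Inf)
})

test_that("default prior configurations match their stated shapes", {
  h <- default_priors("histology", "main")
  expect_s3_class(h$sD, "fixed_prior")
  expect_equal(h$sD$value, 1)
  expect_equal(h$sT$alpha, 1)
  f <- default_priors("followup", "main")
  expect_equal(f$sD$alpha, 172.55)
  expect_equal(f$sD$beta, 30.45)
  expect_equal(prior_mean_oracle(172.55, 30.45), 0.8499, tolerance = 5e-4)
  s3 <- default_priors("histology", "sensitivity3")
  expect_equal(s3$sT$alpha, 525)
  expect_equal(s3$sT$beta, 55.1)
  expect_equal(s3$cT$alpha, 465)
  expect_equal(s3$cT$beta, 56)
  expect_error(default_priors("histology", "nope"), "arg")
})

test_that("prior-only sampling reproduces the analytic Beta means", {
  fit <- run_mcmc(list(stratum_data(0, 0, 0, 0, gold = "followup")),
                  default_priors("followup", "main"),
                  iterations = 8000, burn_in = 1000, chains = 2, seed = 3)
  m <- fit$summary
  sd_mean <- m$mean[m$parameter == "sD.followup"]
  expect_equal(sd_mean, 172.55 / (172.55 + 30.45), tolerance = 0.005)
  expect_equal(m$mean[m$parameter == "sT"], 0.5, tolerance = 0.03)
})

test_that("perfect-reference conjugacy: implied posterior of P(D+|T+) is Beta(k+1, n-k+1)", {
  set.seed(500)
  s <- stratum_data(40, 31, 0, 0, gold = "histology")
  fit <- run_mcmc(list(s), default_priors("histology", "main"),
                  iterations = 12000, burn_in = 2000, chains = 2, seed = 6)
  p1 <- p_dpos_given_tpos(fit$draws[, "sT"], fit$draws[, "cT"],
                          fit$draws[, "prev"], 1, 1)
  qs <- stats::quantile(p1, c(0.1, 0.25, 0.5, 0.75, 0.9))
  want <- stats::qbeta(c(0.1, 0.25, 0.5, 0.75, 0.9), 31 + 1, 40 - 31 + 1)
  expect_equal(unname(qs), want, tolerance = 0.03)
})

test_that("posterior means agree with a quadrature oracle on small counts", {
  # small, well-identified-enough counts so a grid is accurate
  s <- stratum_data(20, 16, 20, 4, gold = "histology")
  fit <- run_mcmc(list(s), default_priors("histology", "main"),
                  iterations = 15000, burn_in = 3000, chains = 2, seed = 4)
  g <- seq(0.0025, 0.9975, by = 0.005)
  grid <- expand.grid(sT = g, cT = g, prev = g)
  p1 <- with(grid, prev * sT / (prev * sT + (1 - prev) * (1 - cT)))
  p2 <- with(grid, prev * (1 - sT) / (prev * (1 - sT) + (1 - prev) * cT))
  ll <- 16 * log(p1) + 4 * log1p(-p1) + 4 * log(p2) + 16 * log1p(-p2)
  w <- exp(ll - max(ll))
  m <- fit$summary
  for (par in c("sT", "cT", "prev")) {
    want <- sum(w * grid[[par]]) / sum(w)
    expect_equal(m$mean[m$parameter == par], want, tolerance = 0.02)
  }
})

test_that("sampling is reproducible and recovers generating parameters", {
  s <- stratum_data(200, 150, 200, 30, gold = "histology")
  pr <- default_priors("histology", "main")
  a <- run_mcmc(list(s), pr, iterations = 4000, burn_in = 1000,
                chains = 2, seed = 11)
  b <- run_mcmc(list(s), pr, iterations = 4000, burn_in = 1000,
                chains = 2, seed = 11)
  expect_identical(a$summary, b$summary)

  # parameter recovery at large n with a perfect reference: generate arm
  # counts from known (sT, cT, prev) and check the 95% intervals cover the
  # implied arm probabilities
  set.seed(42)
  sT <- 0.85; cT <- 0.95; prev <- 0.55
  p1 <- p_dpos_given_tpos(sT, cT, prev, 1, 1)
  p2 <- p_dpos_given_tneg(sT, cT, prev, 1, 1)
  n <- 5000
  k1 <- stats::rbinom(1, n, p1)
  k2 <- stats::rbinom(1, n, p2)
  fit <- run_mcmc(list(stratum_data(n, k1, n, k2, gold = "histology")),
                  pr, iterations = 12000, burn_in = 2000, chains = 2,
                  seed = 12)
  p1_draws <- p_dpos_given_tpos(fit$draws[, "sT"], fit$draws[, "cT"],
                                fit$draws[, "prev"], 1, 1)
  p2_draws <- p_dpos_given_tneg(fit$draws[, "sT"], fit$draws[, "cT"],
                                fit$draws[, "prev"], 1, 1)
  expect_lt(stats::quantile(p1_draws, 0.025), p1)
  expect_gt(stats::quantile(p1_draws, 0.975), p1)
  expect_lt(stats::quantile(p2_draws, 0.025), p2)
  expect_gt(stats::quantile(p2_draws, 0.975), p2)
})

test_that("stratum construction from the study table gives the verified arms", {
  strata <- strata_from_table(builtin_study_table(), "both")
  h <- strata[[1]]; f <- strata[[2]]
  expect_equal(c(h$n_tpos, h$k_tpos, h$n_tneg, h$k_tneg), c(804, 803, 139, 24))
  expect_equal(c(f$n_tpos, f$k_tpos, f$n_tneg, f$k_tneg), c(12, 12, 472, 1))
  expect_error(stratum_data(5, 6, 10, 2), "0 <= k <= n")
})
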