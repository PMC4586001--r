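make_gaussian_arms <- function(n, mu_c = c(108000, 102000), sd_c = c(60000, 60000),
                               mu_q = c(0.319, 0.314), sd_q = c(0.06, 0.06),
                               seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    arm = rep(c("LC", "standard"), each = n),
    cost_total = c(rnorm(n, mu_c[1], sd_c[1]), rnorm(n, mu_c[2], sd_c[2])),
    qaly = c(rnorm(n, mu_q[1], sd_q[1]), rnorm(n, mu_q[2], sd_q[2]))
  ))
}

test_that("bootstrap draws are deterministic under a seed and degenerate data give zero draws", {
  d <- make_gaussian_arms(50)
  b1 <- bootstrap_incrementals(d, B = 200, seed = 9)
  b2 <- bootstrap_incrementals(d, B = 200, seed = 9)
  expect_equal(b1$draws, b2$draws)

  const <- tibble::tibble(arm = rep(c("LC", "standard"), each = 5),
                          cost_total = 1000, qaly = 0.3)
  b0 <- bootstrap_incrementals(const, B = 100, seed = 1)
  expect_true(all(b0$draws$delta_cost == 0))
  expect_true(all(b0$draws$delta_qaly == 0))
  s <- summary(b0)
  expect_equal(s$se, c(0, 0))
  expect_equal(s$conf_low, s$conf_high)

  empty <- const[const$arm == "LC", ]
  expect_error(bootstrap_incrementals(empty, B = 10, seed = 1),
               class = "cueval_validation_error")
  withNA <- const; withNA$qaly[1] <- NA
  expect_error(bootstrap_incrementals(withNA, B = 10, seed = 1),
               class = "cueval_validation_error")
})

test_that("point estimates come from the original data, not the resamples", {
  d <- make_gaussian_arms(30)
  b <- bootstrap_incrementals(d, B = 50, seed = 3)
  expect_equal(b$delta_cost,
               mean(d$cost_total[d$arm == "LC"]) -
                 mean(d$cost_total[d$arm == "standard"]))
  expect_equal(b$delta_qaly,
               mean(d$qaly[d$arm == "LC"]) - mean(d$qaly[d$arm == "standard"]))
})

test_that("bootstrap SE matches exhaustive enumeration of all resamples at n = 3", {
  d <- tibble::tibble(
    arm = rep(c("LC", "standard"), each = 3),
    cost_total = c(100, 250, 700, 80, 300, 400),
    qaly = c(0.30, 0.32, 0.29, 0.31, 0.28, 0.33)
  )
  # oracle: every one of the 3^3 x 3^3 equally likely resample pairs
  enum_means <- function(v) rowMeans(expand.grid(v, v, v))
  mc <- enum_means(d$cost_total[1:3]); ms <- enum_means(d$cost_total[4:6])
  diffs <- outer(mc, ms, "-")
  exact_se <- sqrt(mean((diffs - mean(diffs))^2))

  b <- bootstrap_incrementals(d, B = 50000, seed = 4)
  expect_lt(abs(sd(b$draws$delta_cost) - exact_se) / exact_se, 0.02)
})

test_that("bootstrap SE matches the closed-form two-sample SE on Gaussian data", {
  n <- 400
  d <- make_gaussian_arms(n, seed = 12)
  b <- bootstrap_incrementals(d, B = 10000, seed = 13)
  v1 <- var(d$cost_total[d$arm == "LC"]); v2 <- var(d$cost_total[d$arm == "standard"])
  analytic <- sqrt(v1 / n + v2 / n)
  expect_lt(abs(sd(b$draws$delta_cost) - analytic) / analytic, 0.05)
  q1 <- var(d$qaly[d$arm == "LC"]); q2 <- var(d$qaly[d$arm == "standard"])
  analytic_q <- sqrt(q1 / n + q2 / n)
  expect_lt(abs(sd(b$draws$delta_qaly) - analytic_q) / analytic_q, 0.05)
  # percentile CI brackets the point estimate
  s <- summary(b)
  expect_true(all(s$conf_low <= s$estimate & s$estimate <= s$conf_high))
})

test_that("bootstrap SEs shrink like 1/sqrt(n)", {
  b1 <- bootstrap_incrementals(make_gaussian_arms(150, seed = 21), B = 4000, seed = 22)
  b4 <- bootstrap_incrementals(make_gaussian_arms(600, seed = 23), B = 4000, seed = 24)
  ratio <- sd(b1$draws$delta_cost) / sd(b4$draws$delta_cost)
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("net benefit is the money-valued QALY gain minus the cost", {
  expect_equal(net_benefit(6043, 0.005, 0), -6043)
  expect_equal(net_benefit(6043, 0.005, 100000), -5543)
  # linear in lambda
  dq <- 0.007; dc <- 1234; l <- 40000
  expect_equal(net_benefit(dc, dq, 2 * l) - net_benefit(dc, dq, l), l * dq)
  expect_error(net_benefit(0, 0, -5), class = "cueval_validation_error")
})

test_that("CEAC probabilities match a manual enumeration, ties count as not cost-effective", {
  draws <- manual_draws(delta_cost = c(-100, 200, 500, -50),
                        delta_qaly = c(0.01, 0.02, -0.01, -0.005))
  curve <- ceac(draws, c(0, 1e4, 1e5))
  # by hand: lambda 0 -> draws 1 and 4 save money; lambda 1e4 -> draw 1 only
  # (draws 2 and 4 land exactly on zero net benefit); lambda 1e5 -> 1 and 2
  expect_equal(curve$probability, c(0.5, 0.25, 0.5))
  expect_error(ceac(draws, numeric(0)), class = "cueval_validation_error")
  expect_error(ceac(draws, c(5, 1)), class = "cueval_validation_error")
})

test_that("CEAC limits equal the cost-saving and QALY-gain probabilities", {
  d <- make_gaussian_arms(120, seed = 31)
  b <- bootstrap_incrementals(d, B = 2000, seed = 32)
  curve <- ceac(b, c(0, 1e12))
  expect_equal(curve$probability[1], mean(b$draws$delta_cost < 0))
  expect_equal(curve$probability[2], mean(b$draws$delta_qaly > 0))
  # dominance corners
  dom <- manual_draws(delta_cost = rep(-10, 4), delta_qaly = rep(0.01, 4))
  expect_true(all(ceac(dom, c(0, 1e4, 1e6))$probability == 1))
  dominated <- manual_draws(delta_cost = rep(10, 4), delta_qaly = rep(-0.01, 4))
  expect_true(all(ceac(dominated, c(0, 1e4, 1e6))$probability == 0))
})

test_that("pooled MI CEAC equals the average of per-imputation CEACs", {
  set.seed(41)
  m <- 4; B <- 300
  dc <- rnorm(m * B, 6000, 5000); dq <- rnorm(m * B, 0.005, 0.003)
  pooled <- manual_draws(dc, dq, imputation = rep(1:m, each = B))
  grid <- seq(0, 5e5, 5e4)
  per_imp <- sapply(1:m, function(i) {
    ceac(manual_draws(dc[(i - 1) * B + 1:B], dq[(i - 1) * B + 1:B]),
         grid)$probability
  })
  expect_equal(ceac(pooled, grid)$probability, rowMeans(per_imp))
})

test_that("MI bootstrapping pools across completions and keeps arm sizes", {
  costed <- tiny_costed()
  holes <- costed; holes$u5[c(1, 5)] <- NA
  imps <- impute_chained(holes, m = 3, seed = 51)
  b <- bootstrap_incrementals(imps, B = 100, seed = 52, complete_fn = add_qaly)
  expect_equal(nrow(b$draws), 300)
  expect_equal(sort(unique(b$draws$imputation)), 1:3)
  expect_equal(b$n_treatment, 4)
  expect_equal(b$n_control, 4)
  # BCa intervals need the jackknife, which pooled MI draws do not carry
  expect_error(summary(b, ci = "bca"), class = "cueval_validation_error")
})

test_that("independent cross-check: stratified boot package SE agrees", {
  skip_if_not_installed("boot")
  d <- make_gaussian_arms(80, seed = 61)
  b <- bootstrap_incrementals(d, B = 8000, seed = 62)
  stat <- function(dat, idx) {
    x <- dat[idx, ]
    mean(x$cost_total[x$arm == "LC"]) - mean(x$cost_total[x$arm == "standard"])
  }
  withr::with_seed(63, {
    bo <- boot::boot(as.data.frame(d), stat, R = 8000,
                     strata = as.integer(factor(d$arm)))
  })
  expect_lt(abs(sd(b$draws$delta_cost) - sd(bo$t)) / sd(bo$t), 0.05)
})

test_that("summary warns on unstable percentile CIs and normal/bca options work", {
  d <- make_gaussian_arms(40, seed = 71)
  b <- bootstrap_incrementals(d, B = 50, seed = 72)
  expect_warning(summary(b), "100")
  b2 <- bootstrap_incrementals(d, B = 2000, seed = 73)
  sn <- summary(b2, ci = "normal")
  expect_equal(sn$conf_high - sn$estimate, sn$estimate - sn$conf_low,
               tolerance = 1e-9)
  sb <- summary(b2, ci = "bca")
  expect_true(all(sb$conf_low < sb$conf_high))
})
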