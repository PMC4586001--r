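test_that("generation is deterministic under a seed and respects bounds", {
  p <- trial_params(n = c(LC = 120, standard = 110))
  d1 <- generate_trial(p, seed = 8)
  d2 <- generate_trial(p, seed = 8)
  expect_equal(d1, d2)
  expect_equal(sum(d1$arm == "LC"), 120)
  expect_equal(sum(d1$arm == "standard"), 110)

  u <- as.matrix(d1[, c("u0", "u2", "u5")])
  expect_true(all(u >= 0 & u <= 1))
  costs <- as.matrix(d1[, grep("^cost_", names(d1))])
  expect_true(all(costs >= 0))
  expect_true(all(d1$attend_training >= 1 & d1$attend_training <= 24))
  expect_true(all(d1$attend_education >= 0 & d1$attend_education <= 9))
  lc_range <- range(d1$age[d1$arm == "LC"])
  expect_gte(lc_range[1], 33); expect_lte(lc_range[2], 92)
  expect_true(all(d1$interviews[d1$arm == "LC"] == 2))
  expect_true(all(d1$interviews[d1$arm == "standard"] == 0))
})

test_that("zero variances collapse every patient onto the arm means", {
  p <- trial_params(
    n = c(LC = 5, standard = 5),
    age_sd = c(LC = 0, standard = 0),
    male_prop = c(LC = 1, standard = 1),
    ihd_prop = c(LC = 1, standard = 1),
    attend_training_sd = c(LC = 0, standard = 0),
    attend_education_sd = c(LC = 0, standard = 0),
    utility_sd = list(LC = rep(0, 3), standard = rep(0, 3)),
    cost_table = dplyr::mutate(cueval:::default_cost_moments(),
                               sd_LC = 0, sd_standard = 0),
    weeks_table = dplyr::mutate(cueval:::default_week_moments(),
                                sd_LC = 0, sd_standard = 0),
    post_admission_prob = 0
  )
  d <- generate_trial(p, seed = 2)
  for (a in c("LC", "standard")) {
    da <- d[d$arm == a, setdiff(names(d), "id")]
    expect_equal(nrow(dplyr::distinct(da)), 1)   # all identical
  }
  expect_equal(unique(d$u0[d$arm == "LC"]), 0.720)
  expect_equal(unique(d$cost_outpatient[d$arm == "standard"]), 41513)
})

test_that("large samples recover the calibrated moments", {
  p <- trial_params(n = c(LC = 10000, standard = 10000))
  d <- generate_trial(p, seed = 14)
  for (a in c("LC", "standard")) {
    da <- d[d$arm == a, ]
    n <- nrow(da)
    for (t in 1:3) {
      cl <- c("u0", "u2", "u5")[t]
      sdu <- p$utility_sd[[a]][t]
      # the generator's LLN limit is the [0,1]-clipped normal mean
      target <- cueval:::clipped_normal_mean(p$utility_mean[[a]][t], sdu)
      mcse <- sdu / sqrt(n)
      expect_lt(abs(mean(da[[cl]]) - target), 3 * mcse)
      # clipping moves the mean by well under the printed precision
      expect_lt(abs(target - p$utility_mean[[a]][t]), 0.003)
    }
    # skewed cost categories hit their target means too
    sdc <- p$cost_table[[paste0("sd_", a)]][7]
    expect_lt(abs(mean(da$cost_outpatient) -
                    p$cost_table[[paste0("mean_", a)]][7]),
              3 * sdc / sqrt(n))
  }
  # within-patient utility correlation near the copula parameter
  expect_lt(abs(cor(d$u0, d$u2) - 0.6), 0.05)
  # sicker patients cost more: negative utility-cost association
  expect_lt(cor(d$u0, d$cost_outpatient), -0.1)
})

test_that("infeasible moment targets are rejected", {
  bad <- cueval:::default_cost_moments()
  bad$sd_LC[1] <- -1
  expect_error(trial_params(cost_table = bad),
               class = "cueval_validation_error")
  expect_error(trial_params(nonresponse_rate = 1),
               class = "cueval_validation_error")
  expect_error(trial_params(utility_cor = 1.2),
               class = "cueval_validation_error")
  expect_error(trial_params(utility_mean = list(LC = c(0.7, 1.2, 0.8),
                                                standard = c(0.7, 0.75, 0.8))),
               class = "cueval_validation_error")
})

test_that("MCAR masking hits the marginal rate; zero rate is the identity", {
  p <- trial_params()
  d <- generate_trial(p, seed = 20)
  expect_equal(apply_missingness(d, "MCAR", rate = 0, seed = 1), d)
  masked <- apply_missingness(d, "MCAR", rate = 0.42, seed = 21)
  cells <- 3 * nrow(d)
  realised <- sum(is.na(masked[, c("u0", "u2", "u5")])) / cells
  expect_lt(abs(realised - 0.42), 3 * sqrt(0.42 * 0.58 / cells))
  expect_error(apply_missingness(d, "MCAR", rate = 1),
               class = "cueval_validation_error")
})

test_that("MAR masking is calibrated and selects worse-off patients", {
  p <- trial_params()
  d <- generate_trial(p, seed = 25)
  masked <- apply_missingness(d, "MAR", rate = 0.43, seed = 26)
  cells <- 3 * nrow(d)
  realised <- sum(is.na(masked[, c("u0", "u2", "u5")])) / cells
  expect_lt(abs(realised - 0.43), 3 * sqrt(0.43 * 0.57 / cells))
  # with a negative cost-utility correlation the deleted cells hide lower
  # utilities, so responders look better off than non-responders
  del <- is.na(masked$u0)
  expect_gt(mean(d$u0[!del]), mean(d$u0[del]))
})

test_that("the analytic truth matches a very large simulated trial", {
  p <- trial_params(n = c(LC = 20000, standard = 20000))
  tr <- true_increments(p)
  d <- generate_trial(p, seed = 30)
  costed <- compute_patient_costs(d, table2_catalogue(), lc_course(),
                                  std_course())
  costed <- add_qaly(costed)
  sim_cost <- mean(costed$cost_total[costed$arm == "LC"]) -
    mean(costed$cost_total[costed$arm == "standard"])
  sim_qaly <- mean(costed$qaly[costed$arm == "LC"]) -
    mean(costed$qaly[costed$arm == "standard"])
  se_cost <- sqrt(var(costed$cost_total[costed$arm == "LC"]) / 20000 +
                    var(costed$cost_total[costed$arm == "standard"]) / 20000)
  se_qaly <- sqrt(var(costed$qaly[costed$arm == "LC"]) / 20000 +
                    var(costed$qaly[costed$arm == "standard"]) / 20000)
  expect_lt(abs(sim_cost - tr$delta_cost), 3 * se_cost)
  expect_lt(abs(sim_qaly - tr$delta_qaly), 3 * se_qaly)
  # the defaults encode the trial's headline increments
  expect_lt(abs(tr$delta_qaly - 0.005), 0.001)
  expect_lt(abs(tr$delta_cost - 6043) / 6043, 0.05)
})

test_that("generator parameters round-trip through the fixture format", {
  p <- trial_params()
  expect_equal(unclass(read_trial_params(cueval_example("trial-params-default.yaml"))),
               unclass(p))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  p2 <- trial_params(n = c(LC = 77, standard = 66), utility_cor = 0.5)
  write_trial_params(p2, tmp)
  expect_equal(unclass(read_trial_params(tmp)), unclass(p2))
})
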