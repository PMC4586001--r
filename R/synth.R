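# between-patient SDs are the published arm SEs scaled by the published
# arm sizes (413 LC, 412 standard); they are population properties and do
# not change when a smaller trial is generated
default_cost_moments <- function() {
  tribble(
    ~category,        ~mean_LC, ~se_LC,   ~mean_standard, ~se_standard,
    "gp",             1361,     60.42,    1314,           66.33,
    "specialist",     252,      33.16,    234,            35.65,
    "physio",         120,      28.35,    112,            26.01,
    "dentist",        186,      14.38,    160,            10.30,
    "other_primary",  28,       9.47,     31,             12.60,
    "medicine_rx",    2064,     95.18,    2022,           108.45,
    "outpatient",     44050,    800.01,   41513,          1018.42,
    "admissions",     17644,    3056.81,  19250,          3027.52
  ) |>
    mutate(sd_LC = .data$se_LC * sqrt(413),
           sd_standard = .data$se_standard * sqrt(412)) |>
    select(-"se_LC", -"se_standard")
}

default_week_moments <- function() {
  tribble(
    ~category,      ~mean_LC, ~se_LC, ~mean_standard, ~se_standard,
    "sick",         2.13,     0.31,   2.33,           0.31,
    "reschooling",  0.02,     0.02,   0.05,           0.05,
    "disability",   2.12,     0.31,   1.60,           0.28
  ) |>
    mutate(sd_LC = .data$se_LC * sqrt(413),
           sd_standard = .data$se_standard * sqrt(412)) |>
    select(-"se_LC", -"se_standard")
}

#' Parameters of the synthetic two-arm trial generator
#'
#' Defines the study conditions the generator emulates: arm sizes and
#' covariate distributions of a 825-patient two-arm cardiac rehabilitation
#' trial, session attendance, correlated SF-6D utilities at 0/2/5 months,
#' right-skewed registry cost categories, weeks of inability to work, and a
#' missing-at-random utility nonresponse mechanism. All defaults are
#' calibrated to the trial's published arm-level moments (standard errors
#' are converted to between-patient SDs via `SE * sqrt(n)`).
#'
#' @param n Patients per arm (named: `LC`, `standard`).
#' @param age_mean,age_sd,age_range Age at randomisation: discretised
#'   normal, rounded and clamped to the per-arm observed range.
#' @param male_prop,ihd_prop Proportions male and with ischemic heart
#'   disease (the remainder has heart failure).
#' @param attend_training_mean,attend_training_sd,attend_training_range
#'   Attended training sessions (counts, clamped).
#' @param attend_education_mean,attend_education_sd,attend_education_range
#'   Attended education sessions.
#' @param interviews Individual clarifying interviews per patient (2 in
#'   the LC arm, 0 in standard).
#' @param utility_times Measurement times in months.
#' @param utility_mean,utility_sd Per-arm utility means and between-patient
#'   SDs at each timepoint (default: the published arm SEs of 0.006 scaled
#'   by the square root of the published arm sizes).
#' @param utility_cor Within-patient correlation of utilities across
#'   timepoints (Gaussian copula, equicorrelated; default 0.6, a typical
#'   test-retest value).
#' @param cost_table,weeks_table Tibbles of per-arm means and
#'   between-patient SDs for the registry cost categories and weeks of
#'   inability to work.
#' @param cost_utility_cor Correlation between the patient's latent
#'   utility level and the normal score of the secondary-care cost
#'   categories; negative means sicker patients cost more.
#' @param nonresponse_rate Marginal per-cell probability that a utility
#'   measurement is missing.
#' @param missing_mechanism `"MAR"` (default) or `"MCAR"`.
#' @param beta_cost,beta_attend Logistic coefficients of the MAR mechanism
#'   on standardised log secondary-care cost and attendance.
#' @param post_admission_prob Probability that a patient's hospital
#'   admission cost belongs to a stay discharged after the follow-up
#'   window (carries the exclusion flag for scenario analysis).
#' @return A validated `cueval_trial_params` list.
#' @export
trial_params <- function(
    n = c(LC = 413, standard = 412),
    age_mean = c(LC = 63, standard = 63),
    age_sd = c(LC = 10, standard = 10),
    age_range = list(LC = c(33, 92), standard = c(27, 89)),
    male_prop = c(LC = 0.76, standard = 0.76),
    ihd_prop = c(LC = 0.79, standard = 0.78),
    attend_training_mean = c(LC = 19.61, standard = 18.48),
    attend_training_sd = c(LC = 5, standard = 5),
    attend_training_range = c(1, 24),
    attend_education_mean = c(LC = 6.46, standard = 5.97),
    attend_education_sd = c(LC = 2.5, standard = 2.5),
    attend_education_range = c(0, 9),
    interviews = c(LC = 2, standard = 0),
    utility_times = c(0, 2, 5),
    utility_mean = list(LC = c(0.720, 0.771, 0.788),
                        standard = c(0.705, 0.754, 0.782)),
    utility_sd = list(LC = rep(0.006 * sqrt(413), 3),
                      standard = rep(0.006 * sqrt(412), 3)),
    utility_cor = 0.6,
    cost_table = default_cost_moments(),
    weeks_table = default_week_moments(),
    cost_utility_cor = -0.3,
    nonresponse_rate = 0.43,
    missing_mechanism = c("MAR", "MCAR"),
    beta_cost = 1, beta_attend = -0.5,
    post_admission_prob = 0.08) {
  p <- structure(
    list(
      n = n, age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      male_prop = male_prop, ihd_prop = ihd_prop,
      attend_training_mean = attend_training_mean,
      attend_training_sd = attend_training_sd,
      attend_training_range = attend_training_range,
      attend_education_mean = attend_education_mean,
      attend_education_sd = attend_education_sd,
      attend_education_range = attend_education_range,
      interviews = interviews,
      utility_times = utility_times, utility_mean = utility_mean,
      utility_sd = utility_sd, utility_cor = utility_cor,
      cost_table = as_tibble(cost_table), weeks_table = as_tibble(weeks_table),
      cost_utility_cor = cost_utility_cor,
      nonresponse_rate = nonresponse_rate,
      missing_mechanism = match.arg(missing_mechanism),
      beta_cost = beta_cost, beta_attend = beta_attend,
      post_admission_prob = post_admission_prob
    ),
    class = "cueval_trial_params"
  )
  validate_trial_params(p)
}

#' @rdname trial_params
#' @param p A `cueval_trial_params` object.
#' @export
validate_trial_params <- function(p) {
  arms <- c("LC", "standard")
  if (!all(arms %in% names(p$n)) || any(p$n < 1))
    validation_error("n", "need LC and standard arm sizes >= 1")
  for (a in arms) {
    if (any(p$utility_mean[[a]] < 0 | p$utility_mean[[a]] > 1))
      validation_error("utility_mean", "utility means must be in [0, 1]")
    if (any(p$utility_sd[[a]] < 0))
      validation_error("utility_sd", "must be >= 0")
  }
  if (abs(p$utility_cor) >= 1)
    validation_error("utility_cor", "must be in (-1, 1)")
  if (abs(p$cost_utility_cor) >= 1)
    validation_error("cost_utility_cor", "must be in (-1, 1)")
  if (p$nonresponse_rate < 0 || p$nonresponse_rate >= 1)
    validation_error("nonresponse_rate", "must be in [0, 1)")
  if (any(p$cost_table$sd_LC < 0) || any(p$cost_table$sd_standard < 0))
    validation_error("cost_table", "SDs must be >= 0")
  if (any(p$cost_table$mean_LC < 0) || any(p$cost_table$mean_standard < 0))
    validation_error("cost_table", "cost means must be >= 0")
  invisible(p)
}

#' Read or write generator parameters
#'
#' The shipped fixture `trial-params-default.yaml` records the calibrated
#' defaults as a structured text file.
#'
#' @param path File path.
#' @return `read_trial_params()` returns a `cueval_trial_params`.
#' @export
read_trial_params <- function(path) {
  raw <- read_yaml_file(path, "trial params")
  raw$cost_table <- bind_rows(lapply(raw$cost_table, as_tibble))
  raw$weeks_table <- bind_rows(lapply(raw$weeks_table, as_tibble))
  for (nm in c("n", "age_mean", "age_sd", "male_prop", "ihd_prop",
               "attend_training_mean", "attend_training_sd",
               "attend_education_mean", "attend_education_sd", "interviews"))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(trial_params, raw)
}

#' @rdname read_trial_params
#' @param p A `cueval_trial_params`.
#' @export
write_trial_params <- function(p, path) {
  validate_trial_params(p)
  out <- unclass(p)
  # yaml drops the names of atomic vectors; store per-arm values as maps
  for (nm in names(out))
    if (is.atomic(out[[nm]]) && !is.null(names(out[[nm]])))
      out[[nm]] <- as.list(out[[nm]])
  out$cost_table <- purrr::transpose(as.list(p$cost_table)) |>
    purrr::map(~ .x)
  out$weeks_table <- purrr::transpose(as.list(p$weeks_table)) |>
    purrr::map(~ .x)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# mean-and-sd matched gamma draws through a supplied normal score;
# degenerate cases (sd 0 or mean 0) collapse to constants
gamma_from_score <- function(score, mean, sd) {
  if (mean == 0) return(rep(0, length(score)))
  if (sd == 0) return(rep(mean, length(score)))
  shape <- mean^2 / sd^2
  qgamma(pnorm(score), shape = shape, scale = sd^2 / mean)
}

# discretised clamped normal: integer pmf of round(rnorm) clamped to [lo, hi]
disc_norm_pmf <- function(mean, sd, lo, hi) {
  vals <- lo:hi
  if (sd == 0) {
    pm <- as.numeric(vals == min(max(round(mean), lo), hi))
    return(tibble(value = vals, p = pm))
  }
  p <- pnorm(vals + 0.5, mean, sd) - pnorm(vals - 0.5, mean, sd)
  p[1] <- pnorm(lo + 0.5, mean, sd)
  p[length(p)] <- 1 - pnorm(hi - 0.5, mean, sd)
  tibble(value = vals, p = p)
}

draw_count <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(min(max(round(mean), range[1]), range[2]), n))
  pmin(pmax(round(rnorm(n, mean, sd)), range[1]), range[2])
}

#' Generate a synthetic two-arm trial
#'
#' Draws a complete patient-level dataset with the structure the analysis
#' pipeline consumes: covariates, attendance, three correlated utilities,
#' skewed registry cost categories (gamma, mean/SD matched, with the
#' secondary-care categories negatively coupled to the patient's utility
#' level through a Gaussian copula), weeks of inability to work (drawn for
#' patients below pension age, scaled so the population mean matches the
#' target), and a post-follow-up admission flag.
#'
#' @param params A [trial_params()].
#' @param seed Optional seed; the same seed reproduces the dataset.
#' @param pension_age Pension age used to allocate weeks of inability to
#'   work (default 67).
#' @return A tibble with one row per patient. Column dictionary: `id`,
#'   `arm`, `age`, `gender`, `diagnosis`, `attend_training`,
#'   `attend_education`, `interviews`, per-category registry costs
#'   (`cost_gp`, `cost_specialist`, `cost_physio`, `cost_dentist`,
#'   `cost_other_primary`, `cost_medicine_rx`, `cost_outpatient`,
#'   `cost_admissions`, `cost_admissions_post`), weeks (`weeks_sick`,
#'   `weeks_reschooling`, `weeks_disability`) and utilities `u0`, `u2`,
#'   `u5`.
#' @export
generate_trial <- function(params, seed = NULL, pension_age = 67) {
  validate_trial_params(params)
  with_seed(seed, {
    arms <- purrr::map(c("LC", "standard"), function(a) {
      generate_arm(params, a, pension_age)
    })
    out <- bind_rows(arms)
    out$id <- seq_len(nrow(out))
    relocate(out, "id")
  })
}

generate_arm <- function(p, a, pension_age) {
  n <- p$n[[a]]
  age <- draw_count(n, p$age_mean[[a]], p$age_sd[[a]], p$age_range[[a]])
  gender <- ifelse(runif(n) < p$male_prop[[a]], "male", "female")
  diagnosis <- ifelse(runif(n) < p$ihd_prop[[a]], "IHD", "HF")
  tr <- draw_count(n, p$attend_training_mean[[a]], p$attend_training_sd[[a]],
                   p$attend_training_range)
  ed <- draw_count(n, p$attend_education_mean[[a]], p$attend_education_sd[[a]],
                   p$attend_education_range)

  # correlated utility latents (equicorrelated Gaussian copula)
  k <- length(p$utility_times)
  Sigma <- matrix(p$utility_cor, k, k); diag(Sigma) <- 1
  Z <- matrix(rnorm(n * k), n, k) %*% chol(Sigma)
  sdu <- p$utility_sd[[a]]
  U <- sapply(seq_len(k), function(t)
    pmin(pmax(p$utility_mean[[a]][t] + sdu[t] * Z[, t], 0), 1))
  if (n == 1) U <- matrix(U, nrow = 1)

  # standardised patient utility level, shared with the secondary-care
  # cost scores so that sicker (low-utility) patients cost more
  vz <- (1 + (k - 1) * p$utility_cor) / k
  zbar <- rowMeans(Z) / sqrt(vz)
  r <- p$cost_utility_cor

  costs <- list()
  for (i in seq_len(nrow(p$cost_table))) {
    row <- p$cost_table[i, ]
    linked <- row$category %in% c("outpatient", "admissions")
    score <- if (linked) r * zbar + sqrt(1 - r^2) * rnorm(n) else rnorm(n)
    costs[[paste0("cost_", row$category)]] <-
      gamma_from_score(score, row[[paste0("mean_", a)]],
                       row[[paste0("sd_", a)]])
  }

  # weeks of inability to work: only patients below pension age at the end
  # of follow-up can lose productive weeks; the conditional mean is scaled
  # up so the population mean hits the target
  under <- age + 5 / 12 < pension_age
  weeks <- list()
  for (i in seq_len(nrow(p$weeks_table))) {
    row <- p$weeks_table[i, ]
    w <- numeric(n)
    if (any(under)) {
      f <- n / sum(under)
      w[under] <- gamma_from_score(rnorm(sum(under)),
                                   row[[paste0("mean_", a)]] * f,
                                   row[[paste0("sd_", a)]] * f)
    }
    weeks[[paste0("weeks_", row$category)]] <- w
  }

  post_flag <- rbinom(n, 1, p$post_admission_prob)
  tibble(
    arm = a, age = age, gender = gender, diagnosis = diagnosis,
    attend_training = tr, attend_education = ed,
    interviews = p$interviews[[a]],
    !!!costs,
    cost_admissions_post = post_flag * costs$cost_admissions,
    !!!weeks,
    u0 = U[, 1], u2 = U[, 2], u5 = U[, 3]
  )
}

#' Mask utilities missing-completely or missing-at-random
#'
#' MCAR deletes each utility cell independently with the marginal
#' probability. MAR deletes with a patient-specific logistic probability
#' increasing in (log) secondary-care cost and decreasing in attendance,
#' with the intercept calibrated by root-finding so the marginal cell rate
#' is attained; all of a patient's cells share the same probability and
#' are deleted independently given it.
#'
#' @param records Complete patient tibble from [generate_trial()].
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Marginal per-cell nonresponse probability in \[0, 1).
#' @param beta_cost,beta_attend MAR logistic coefficients.
#' @param cols Utility columns to mask.
#' @param seed Optional seed.
#' @return Records with `NA`s punched into the utility columns.
#' @export
apply_missingness <- function(records, mechanism = c("MAR", "MCAR"),
                              rate = 0.43, beta_cost = 1, beta_attend = -0.5,
                              cols = c("u0", "u2", "u5"), seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate >= 1 || rate < 0)
    validation_error("rate", "must be in [0, 1)")
  if (rate == 0) return(records)
  x <- as_tibble(records)
  n <- nrow(x)
  prob <- if (mechanism == "MCAR") rep(rate, n) else {
    sec <- x$cost_outpatient + x$cost_admissions
    att <- x$attend_training + x$attend_education
    zs <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
    lp <- beta_cost * zs(log1p(sec)) + beta_attend * zs(att)
    a <- uniroot(function(a0) mean(plogis(a0 + lp)) - rate, c(-30, 30))$root
    plogis(a + lp)
  }
  with_seed(seed, {
    for (cl in cols)
      x[[cl]][runif(n) < prob] <- NA_real_
    x
  })
}

# ---- analytic truth -----------------------------------------------------

# expectation of clamp(N(mean, sd), 0, 1)
clipped_normal_mean <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1))
  al <- (0 - mean) / sd; be <- (1 - mean) / sd
  mean * (pnorm(be) - pnorm(al)) + sd * (dnorm(al) - dnorm(be)) +
    1 * (1 - pnorm(be))
}

disc_mean <- function(mean, sd, range) {
  pm <- disc_norm_pmf(mean, sd, range[1], range[2])
  sum(pm$value * pm$p)
}

# expected wages over the discretised age x gender distribution of one arm
expected_rates <- function(p, a, salary, pension_age, horizon_months = 5) {
  pm <- disc_norm_pmf(p$age_mean[[a]], p$age_sd[[a]],
                      p$age_range[[a]][1], p$age_range[[a]][2])
  male <- p$male_prop[[a]]
  grid <- tidyr::crossing(gender = c("male", "female"), age = pm$value) |>
    left_join(rename(pm, age = "value"), by = "age") |>
    mutate(w = ifelse(.data$gender == "male", male, 1 - male) * .data$p,
           pensioner = .data$age + horizon_months / 12 >= pension_age,
           gross = lookup_salary(salary, .data$gender, .data$age, "productive"),
           net = lookup_salary(salary, .data$gender, .data$age, "leisure"),
           time_rate = ifelse(.data$pensioner, .data$net, .data$gross))
  p_under <- sum(grid$w[!grid$pensioner])
  list(
    time_rate = sum(grid$w * grid$time_rate),
    p_under = p_under,
    gross_under = if (p_under > 0)
      sum(grid$w[!grid$pensioner] * grid$gross[!grid$pensioner]) / p_under
    else 0
  )
}

#' Analytic expected increments of the generator
#'
#' Computes, from the generator parameters alone, the expected per-arm
#' societal (or healthcare) cost and QALY, and their between-arm
#' differences — the ground truth a parameter-recovery run is judged
#' against. Expectations account for the discretised/clamped covariate
#' distributions and the utility clipping at \[0, 1\].
#'
#' @param params A [trial_params()].
#' @inheritParams compute_patient_costs
#' @return A list with `per_arm` (tibble of expected cost and QALY by
#'   arm), `delta_cost` and `delta_qaly`.
#' @export
true_increments <- function(params,
                            catalogue = read_catalogue(cueval_example("catalogue-2013.yaml")),
                            course_lc = read_course_spec(cueval_example("course-lc.yaml")),
                            course_standard = read_course_spec(cueval_example("course-standard.yaml")),
                            salary = default_salary_table(),
                            perspective = "societal",
                            exclusions = character(),
                            pension_age = 67, hours_per_week = 37,
                            horizon_months = 5, session_hours = 1.5) {
  p <- params
  tariff <- catalogue$items$patient_transport_per_km %||% 3.82
  cc <- list(LC = course_cost(course_lc, catalogue),
             standard = course_cost(course_standard, catalogue))
  per_arm <- purrr::map_dfr(c("LC", "standard"), function(a) {
    rates <- expected_rates(p, a, salary, pension_age, horizon_months)
    interv <- if (perspective == "healthcare")
      cc[[a]]$healthcare_total / cc[[a]]$patients_per_course
    else cc[[a]]$total_per_course / cc[[a]]$patients_per_course
    registry <- sum(p$cost_table[[paste0("mean_", a)]])
    if ("post_followup_admissions" %in% exclusions)
      registry <- registry - p$post_admission_prob *
        p$cost_table[[paste0("mean_", a)]][p$cost_table$category == "admissions"]
    weeks <- sum(p$weeks_table[[paste0("mean_", a)]])
    productivity <- if ("productivity_loss" %in% exclusions) 0 else
      weeks * hours_per_week * rates$gross_under
    e_tr <- disc_mean(p$attend_training_mean[[a]], p$attend_training_sd[[a]],
                      p$attend_training_range)
    e_ed <- disc_mean(p$attend_education_mean[[a]], p$attend_education_sd[[a]],
                      p$attend_education_range)
    contacts <- e_tr + e_ed + p$interviews[[a]]
    course_h <- session_hours * (e_tr + e_ed) + p$interviews[[a]]
    informal <- if ("patient_time" %in% exclusions) 0 else
      (course_h + contacts * 2 / 3) * rates$time_rate
    transport <- if ("patient_transport" %in% exclusions) 0 else
      contacts * 2 * 10 * tariff
    societal_extra <- if (perspective == "healthcare") 0 else
      productivity + informal + transport
    u <- vapply(seq_along(p$utility_times), function(t)
      clipped_normal_mean(p$utility_mean[[a]][t], p$utility_sd[[a]][t]), 1)
    tibble(
      arm = a,
      expected_cost = interv + registry + societal_extra,
      expected_qaly = qaly_auc(u, p$utility_times)
    )
  })
  list(
    per_arm = per_arm,
    delta_cost = diff(rev(per_arm$expected_cost)),
    delta_qaly = diff(rev(per_arm$expected_qaly))
  )
}

#' End-to-end parameter recovery
#'
#' Runs the whole pipeline on one synthetic trial — generate, mask
#' utilities, cost, impute by chained equations, bootstrap, CEAC — and
#' compares the recovered incremental cost and QALY against the
#' generator's analytic truth.
#'
#' @param params A [trial_params()].
#' @param B Bootstrap replications per completed dataset.
#' @param m Number of imputations.
#' @param seed Master seed; all stage seeds derive from it.
#' @inheritParams compute_patient_costs
#' @param lambdas Willingness-to-pay grid for the CEAC.
#' @return A `cueval_recovery` tibble (`quantity`, `truth`, `estimate`,
#'   `se`, `conf_low`, `conf_high`, `z`) with the draws and CEAC attached
#'   as attributes `draws` and `ceac`.
#' @export
end_to_end_recovery <- function(params, B = 2000, m = 5, seed = NULL,
                                catalogue = read_catalogue(cueval_example("catalogue-2013.yaml")),
                                course_lc = read_course_spec(cueval_example("course-lc.yaml")),
                                course_standard = read_course_spec(cueval_example("course-standard.yaml")),
                                salary = default_salary_table(),
                                perspective = "societal",
                                lambdas = lambda_grid(by = 10000)) {
  records <- generate_trial(params, seed = child_seed(seed, 1))
  masked <- apply_missingness(records, mechanism = params$missing_mechanism,
                              rate = params$nonresponse_rate,
                              beta_cost = params$beta_cost,
                              beta_attend = params$beta_attend,
                              seed = child_seed(seed, 2))
  costed <- compute_patient_costs(masked, catalogue, course_lc,
                                  course_standard, salary,
                                  perspective = perspective)
  imps <- impute_chained(costed, m = m, seed = child_seed(seed, 3))
  draws <- bootstrap_incrementals(imps, B = B, seed = child_seed(seed, 4),
                                  complete_fn = add_qaly)
  curve <- ceac(draws, lambdas)
  truth <- true_increments(params, catalogue, course_lc, course_standard,
                           salary, perspective = perspective)
  s <- summary(draws)
  tr <- c(truth$delta_cost, truth$delta_qaly)
  out <- tibble(
    quantity = s$quantity,
    truth = tr,
    estimate = s$estimate, se = s$se,
    conf_low = s$conf_low, conf_high = s$conf_high,
    z = (s$estimate - tr) / s$se
  )
  class(out) <- c("cueval_recovery", class(out))
  attr(out, "draws") <- draws
  attr(out, "ceac") <- curve
  out
}
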