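# Shared fixtures, built in code.

table2_catalogue <- function() {
  read_catalogue(cueval_example("catalogue-2013.yaml"))
}

lc_course <- function() read_course_spec(cueval_example("course-lc.yaml"))
std_course <- function() read_course_spec(cueval_example("course-standard.yaml"))

# a minimal deterministic patient table covering both arms
tiny_records <- function(n_per_arm = 4) {
  n <- 2 * n_per_arm
  tibble::tibble(
    id = seq_len(n),
    arm = rep(c("LC", "standard"), each = n_per_arm),
    age = rep(c(62, 70, 55, 68), length.out = n),
    gender = rep(c("male", "female"), length.out = n),
    diagnosis = "IHD",
    attend_training = rep(c(20, 18, 22, 15), length.out = n),
    attend_education = rep(c(6, 5, 7, 4), length.out = n),
    interviews = rep(c(2, 0), each = n_per_arm),
    cost_gp = 1000, cost_specialist = 200, cost_physio = 100,
    cost_dentist = 150, cost_other_primary = 25,
    cost_medicine_rx = 2000,
    cost_outpatient = rep(c(40000, 45000), length.out = n),
    cost_admissions = rep(c(0, 20000), length.out = n),
    cost_admissions_post = rep(c(0, 5000), length.out = n),
    weeks_sick = rep(c(2, 0), length.out = n),
    weeks_reschooling = 0,
    weeks_disability = rep(c(0, 3), length.out = n),
    u0 = rep(c(0.70, 0.72, 0.68, 0.75), length.out = n),
    u2 = rep(c(0.78, 0.74, 0.71, 0.80), length.out = n),
    u5 = rep(c(0.79, 0.76, 0.73, 0.78), length.out = n)
  )
}

tiny_costed <- function(n_per_arm = 4, ...) {
  compute_patient_costs(tiny_records(n_per_arm), table2_catalogue(),
                        lc_course(), std_course(), ...)
}

# hand-built draws object for CEAC unit tests
manual_draws <- function(delta_cost, delta_qaly, imputation = 1L) {
  structure(
    list(
      draws = tibble::tibble(delta_cost = delta_cost,
                             delta_qaly = delta_qaly,
                             imputation = rep_len(as.integer(imputation),
                                                  length(delta_cost))),
      delta_cost = mean(delta_cost), delta_qaly = mean(delta_qaly),
      arm_means = NULL, B = length(delta_cost), m = 1L, seed = NULL,
      n_treatment = NA_integer_, n_control = NA_integer_, jackknife = NULL
    ),
    class = "cueval_draws"
  )
}
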