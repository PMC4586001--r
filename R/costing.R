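#' Apply the staff load factor
#'
#' Staff formal contact hours are multiplied by a load factor (default 1.5
#' in the shipped catalogue) so that the priced time also covers
#' non-productive time: breaks and walking distance between locations
#' (0.25) and vacation, sickness and continuing education (0.25). The
#' added `(load_factor - 1) * formal_hours` is reported separately as the
#' "load for unproductive time" line of the course cost breakdown.
#'
#' @param formal_hours Non-negative hours of formal contact time.
#' @param load_factor Multiplier >= 1; 1 leaves hours unchanged.
#' @return Loaded hours, `formal_hours * load_factor`.
#' @export
#' @examples
#' apply_load(62, 1.5)  # 93
apply_load <- function(formal_hours, load_factor) {
  if (any(formal_hours < 0)) validation_error("formal_hours", "must be >= 0")
  if (any(load_factor < 1)) validation_error("load_factor", "must be >= 1")
  formal_hours * load_factor
}

#' Micro-cost one rehabilitation course
#'
#' Bottom-up costing of one 8-week group course: each staff role's formal
#' hours are priced at its hourly wage, the load factor adds a separate
#' unproductive-time line per role, expert-patient (lay educator) hours are
#' priced unloaded at the pensioner net wage with their hospital-paid
#' transport added, and the hospital overhead rate is applied to the sum of
#' all role subtotals. The per-patient cost divides the course total by the
#' number of patients sharing it.
#'
#' Amounts are kept at full precision internally; only the reported
#' overhead, totals and per-patient lines are rounded to whole DKK.
#'
#' @param spec A [course_spec()].
#' @param catalogue A [cost_catalogue()] with items `nurse_hourly`,
#'   `physiotherapist_hourly`, `expert_patient_hourly`.
#' @return A `cueval_course_cost` object with a line-by-line `lines` tibble
#'   (role, item, units, cost) and fields `nurse_total`, `physio_total`,
#'   `expert_total`, `overhead`, `total_per_course`, `cost_per_patient`,
#'   `loaded_hours`, and the formal-care share used under the healthcare
#'   perspective (`healthcare_total`, `healthcare_per_patient`).
#' @export
#' @examples
#' cc <- course_cost(read_course_spec(cueval_example("course-lc.yaml")),
#'                   read_catalogue(cueval_example("catalogue-2013.yaml")))
#' cc$total_per_course   # 48072
#' cc$cost_per_patient   # 4807
course_cost <- function(spec, catalogue) {
  validate_course_spec(spec)
  validate_catalogue(catalogue)
  if (spec$patients_per_course < 1)
    validation_error("patients_per_course", "must be >= 1")
  lf <- catalogue$load_factor
  wage <- function(key) {
    if (is.null(catalogue$items[[key]]))
      validation_error(paste0("items.", key), "missing from catalogue")
    catalogue$items[[key]]
  }

  staff_lines <- function(role, key) {
    w <- wage(key)
    h <- spec[[role]]
    formal <- h$training_h + h$education_h + h$interview_h + h$team_eval_h
    load_h <- (lf - 1) * formal
    tibble(
      role = role,
      item = c("training_sessions", "education_sessions", "interviews",
               "team_evaluation", "load_unproductive"),
      units = c(h$training_h, h$education_h, h$interview_h, h$team_eval_h,
                load_h),
      cost = .data$units * w
    )
  }
  nurse <- staff_lines("nurse", "nurse_hourly")
  physio <- staff_lines("physiotherapist", "physiotherapist_hourly")

  ew <- wage("expert_patient_hourly")
  eh <- spec$expert_patient
  expert <- tibble(
    role = "expert_patient",
    item = c("training_sessions", "education_sessions", "team_evaluation",
             "transport_time", "transport"),
    units = c(eh$training_h, eh$education_h, eh$team_eval_h,
              eh$transport_time_h, NA_real_),
    cost = c(eh$training_h * ew, eh$education_h * ew, eh$team_eval_h * ew,
             eh$transport_time_h * ew, spec$expert_transport_cost_total)
  )

  nurse_total <- sum(nurse$cost)
  physio_total <- sum(physio$cost)
  expert_total <- sum(expert$cost)
  role_sum <- nurse_total + physio_total + expert_total
  overhead <- round(catalogue$overhead_rate * role_sum)
  total <- role_sum + overhead
  # healthcare perspective: formal care only (staff + overhead on staff),
  # plus expert transport which the hospital pays; expert time is informal
  hc_total <- nurse_total + physio_total +
    round(catalogue$overhead_rate * (nurse_total + physio_total)) +
    spec$expert_transport_cost_total

  structure(
    list(
      arm = spec$arm,
      lines = bind_rows(nurse, physio, expert),
      loaded_hours = c(
        nurse = apply_load(sum(unlist(spec$nurse)), lf),
        physiotherapist = apply_load(sum(unlist(spec$physiotherapist)), lf)
      ),
      nurse_total = nurse_total,
      physio_total = physio_total,
      expert_total = expert_total,
      overhead = overhead,
      total_per_course = total,
      cost_per_patient = round(total / spec$patients_per_course),
      healthcare_total = hc_total,
      healthcare_per_patient = round(hc_total / spec$patients_per_course),
      patients_per_course = spec$patients_per_course
    ),
    class = "cueval_course_cost"
  )
}

#' @export
print.cueval_course_cost <- function(x, ...) {
  cat(sprintf("<cueval_course_cost> arm %s\n", x$arm))
  print(as.data.frame(x$lines), row.names = FALSE)
  cat(sprintf("  overhead %12.0f\n  total    %12.0f\n  per patient %9.0f\n",
              x$overhead, x$total_per_course, x$cost_per_patient))
  invisible(x)
}

#' @export
tidy.cueval_course_cost <- function(x, ...) {
  bind_rows(
    x$lines,
    tibble(role = "overhead", item = "overhead", units = NA_real_,
           cost = x$overhead)
  ) |>
    mutate(arm = x$arm, .before = 1)
}

#' @export
glance.cueval_course_cost <- function(x, ...) {
  tibble(
    arm = x$arm,
    nurse_total = x$nurse_total,
    physio_total = x$physio_total,
    expert_total = x$expert_total,
    overhead = x$overhead,
    total_per_course = x$total_per_course,
    cost_per_patient = x$cost_per_patient,
    healthcare_per_patient = x$healthcare_per_patient
  )
}

#' Value informal time by the opportunity-cost method
#'
#' Hours of informal time (patient course attendance, transport time) are
#' valued at the person's wage rate: the net wage for leisure time, the
#' gross wage for productive time. Vectorised.
#'
#' @param hours Non-negative hours.
#' @inheritParams lookup_salary
#' @return DKK (unrounded; round at aggregation).
#' @export
informal_time_cost <- function(hours, gender, age,
                               time_type = c("leisure", "productive"),
                               table = default_salary_table()) {
  if (any(hours < 0)) validation_error("hours", "must be >= 0")
  hours * lookup_salary(table, gender, age, time_type)
}

#' Patient transport cost and time
#'
#' Every contact with the programme is assumed to involve a fixed-distance
#' drive each way (default 10 km and 20 minutes per way) priced at the
#' government car tariff. Supplying `total_km` directly (e.g. registry
#' kilometres) bypasses the contact-count calculation.
#'
#' @param n_contacts Number of attended contacts (sessions + interviews).
#' @param km_per_way Kilometres each way (default 10).
#' @param tariff DKK per kilometre.
#' @param total_km Optional total kilometres, overriding
#'   `n_contacts * 2 * km_per_way`.
#' @param min_per_way Minutes of travel time each way (default 20).
#' @return A tibble with columns `km`, `cost_dkk` (rounded to whole DKK)
#'   and `time_hours`.
#' @export
#' @examples
#' transport_cost(total_km = 557.71, tariff = 3.82)$cost_dkk  # 2130
transport_cost <- function(n_contacts = NULL, km_per_way = 10, tariff,
                           total_km = NULL, min_per_way = 20) {
  if (is.null(total_km)) {
    if (is.null(n_contacts))
      validation_error("n_contacts", "supply n_contacts or total_km")
    if (any(n_contacts < 0)) validation_error("n_contacts", "must be >= 0")
    total_km <- n_contacts * 2 * km_per_way
  }
  if (any(total_km < 0)) validation_error("total_km", "must be >= 0")
  if (any(tariff < 0)) validation_error("tariff", "must be >= 0")
  time_h <- if (is.null(n_contacts)) NA_real_ else
    n_contacts * 2 * min_per_way / 60
  tibble(km = total_km, cost_dkk = round(total_km * tariff),
         time_hours = time_h)
}

#' Productivity loss from weeks of inability to work
#'
#' Weeks of sick leave, re-schooling and disability pension are priced at
#' the gross wage for a standard working week, but only for patients who
#' have not reached the public pension age by the end of follow-up; the
#' loss is zero for pensioners. Vectorised.
#'
#' @param weeks Non-negative weeks of inability to work.
#' @param gender,age Patient covariates (age at randomisation, years).
#' @param table A [salary_table()].
#' @param pension_age Public pension age (default 67).
#' @param hours_per_week Working hours per week (default 37, the Danish
#'   standard full-time week).
#' @param horizon_months Follow-up length in months (default 5); a patient
#'   counts as a pensioner if `age + horizon_months/12 >= pension_age`.
#' @return DKK (unrounded).
#' @export
productivity_loss_cost <- function(weeks, gender, age,
                                   table = default_salary_table(),
                                   pension_age = 67, hours_per_week = 37,
                                   horizon_months = 5) {
  if (any(weeks < 0)) validation_error("weeks", "must be >= 0")
  n <- max(length(weeks), length(gender), length(age))
  weeks <- rep_len(weeks, n)
  gender <- rep_len(gender, n)
  age <- rep_len(age, n)
  pensioner <- age + horizon_months / 12 >= pension_age
  out <- numeric(n)
  if (any(!pensioner)) {
    gross <- lookup_salary(table, gender[!pensioner], age[!pensioner],
                           "productive")
    out[!pensioner] <- weeks[!pensioner] * hours_per_week * gross
  }
  out
}

#' Inflate an amount to a common price year
#'
#' @param amount DKK amount(s).
#' @param from_year Year the amount is expressed in.
#' @param cpi_index Named numeric vector or list mapping year to consumer
#'   price index.
#' @param to_year Target price year (default 2013).
#' @return `amount * index(to_year) / index(from_year)`.
#' @export
adjust_price_year <- function(amount, from_year, cpi_index, to_year = 2013) {
  cpi_index <- unlist(cpi_index)
  for (y in c(from_year, to_year))
    if (!as.character(y) %in% names(cpi_index))
      abort(sprintf("year %s missing from the CPI index", y),
            class = "cueval_validation_error", field = "cpi_index")
  amount * cpi_index[[as.character(to_year)]] / cpi_index[[as.character(from_year)]]
}

# ---- per-patient aggregation -------------------------------------------

cost_category_cols <- c(
  "cost_intervention", "cost_primary_care", "cost_medicine",
  "cost_secondary_care", "cost_productivity", "cost_informal_time",
  "cost_transport"
)

#' Cost categories counted under a perspective
#'
#' The healthcare perspective counts the intervention's formal-care share,
#' primary care, prescribed medicine and secondary care. The societal
#' perspective adds productivity losses, informal (patient and expert)
#' time, and patient transport.
#'
#' @param perspective `"societal"` or `"healthcare"`.
#' @return Character vector of per-patient cost column names.
#' @export
perspective_categories <- function(perspective = c("societal", "healthcare")) {
  perspective <- tryCatch(match.arg(perspective), error = function(e)
    abort(sprintf("unknown perspective '%s' (use societal or healthcare)",
                  perspective[1]),
          class = "cueval_validation_error", field = "perspective"))
  hc <- c("cost_intervention", "cost_primary_care", "cost_medicine",
          "cost_secondary_care")
  if (perspective == "healthcare") hc
  else c(hc, "cost_productivity", "cost_informal_time", "cost_transport")
}

cost_exclusion_choices <- c("patient_time", "patient_transport",
                            "post_followup_admissions", "productivity_loss")

#' Compute per-patient costs over all categories
#'
#' Takes patient-level trial records (see [generate_trial()] for the column
#' dictionary) and attaches per-category cost columns and the
#' perspective-filtered total:
#'
#' * `cost_intervention`: the per-patient micro-costed course cost of the
#'   patient's arm (formal-care share only under the healthcare
#'   perspective);
#' * `cost_primary_care`: general practice + specialist + physiotherapist +
#'   dentist + other, passed through from the records;
#' * `cost_medicine`, `cost_secondary_care`: passed through (admissions
#'   discharged after follow-up can be excluded);
#' * `cost_productivity`: weeks of inability to work priced by
#'   [productivity_loss_cost()];
#' * `cost_informal_time`: attended course hours plus transport time,
#'   valued at the net wage for pensioners and the gross wage otherwise;
#' * `cost_transport`: attended contacts at 2 x 10 km by car tariff.
#'
#' @param records Patient-level tibble.
#' @param catalogue A [cost_catalogue()].
#' @param course_lc,course_standard [course_spec()]s for the two arms.
#' @param salary A [salary_table()].
#' @param perspective `"societal"` (default) or `"healthcare"`.
#' @param exclusions Character vector of category exclusions for scenario
#'   analysis: any of `"patient_time"`, `"patient_transport"`,
#'   `"post_followup_admissions"`, `"productivity_loss"`.
#' @param pension_age,hours_per_week,horizon_months See
#'   [productivity_loss_cost()].
#' @param session_hours Hours per attended training/education session
#'   (default 1.5) and per interview (1).
#' @return The records with cost category columns and `cost_total` added.
#' @export
compute_patient_costs <- function(records, catalogue,
                                  course_lc, course_standard,
                                  salary = default_salary_table(),
                                  perspective = c("societal", "healthcare"),
                                  exclusions = character(),
                                  pension_age = 67, hours_per_week = 37,
                                  horizon_months = 5, session_hours = 1.5) {
  perspective <- perspective[1]
  cats <- perspective_categories(perspective)
  bad <- setdiff(exclusions, cost_exclusion_choices)
  if (length(bad))
    abort(sprintf("unknown cost exclusion(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(cost_exclusion_choices, collapse = ", ")),
          class = "cueval_validation_error", field = "exclusions")
  validate_catalogue(catalogue)

  cc_lc <- course_cost(course_lc, catalogue)
  cc_std <- course_cost(course_standard, catalogue)
  per_patient <- if (perspective == "healthcare") {
    c(LC = cc_lc$healthcare_total / cc_lc$patients_per_course,
      standard = cc_std$healthcare_total / cc_std$patients_per_course)
  } else {
    c(LC = cc_lc$total_per_course / cc_lc$patients_per_course,
      standard = cc_std$total_per_course / cc_std$patients_per_course)
  }

  tariff <- catalogue$items$patient_transport_per_km %||% 3.82
  x <- as_tibble(records)
  arm <- as.character(x$arm)
  if (!all(arm %in% names(per_patient)))
    abort(sprintf("unknown arm label(s): %s",
                  paste(setdiff(unique(arm), names(per_patient)), collapse = ", ")),
          class = "cueval_validation_error", field = "arm")

  contacts <- x$attend_training + x$attend_education + x$interviews
  course_h <- session_hours * (x$attend_training + x$attend_education) +
    1 * x$interviews
  tr <- transport_cost(n_contacts = contacts, km_per_way = 10,
                       tariff = tariff)
  pensioner <- x$age + horizon_months / 12 >= pension_age
  time_rate <- ifelse(
    pensioner,
    lookup_salary(salary, x$gender, x$age, "leisure"),
    lookup_salary(salary, x$gender, x$age, "productive")
  )

  sec <- x$cost_outpatient + x$cost_admissions
  if ("post_followup_admissions" %in% exclusions)
    sec <- sec - x$cost_admissions_post

  x$cost_intervention <- unname(per_patient[arm])
  x$cost_primary_care <- x$cost_gp + x$cost_specialist + x$cost_physio +
    x$cost_dentist + x$cost_other_primary
  x$cost_medicine <- x$cost_medicine_rx
  x$cost_secondary_care <- sec
  x$cost_productivity <- productivity_loss_cost(
    x$weeks_sick + x$weeks_reschooling + x$weeks_disability,
    x$gender, x$age, table = salary, pension_age = pension_age,
    hours_per_week = hours_per_week, horizon_months = horizon_months
  )
  x$cost_informal_time <- (course_h + tr$time_hours) * time_rate
  x$cost_transport <- tr$cost_dkk
  if ("patient_time" %in% exclusions) x$cost_informal_time <- 0
  if ("patient_transport" %in% exclusions) x$cost_transport <- 0
  if ("productivity_loss" %in% exclusions) x$cost_productivity <- 0

  x$cost_total <- rowSums(as.matrix(x[, cats, drop = FALSE]))
  attr(x, "perspective") <- perspective
  attr(x, "exclusions") <- exclusions
  x
}

#' Aggregate category costs under a perspective
#'
#' Lower-level helper summing exactly the categories a perspective
#' includes; useful when category columns were produced elsewhere.
#'
#' @param components Data frame holding the per-patient category columns
#'   (`cost_intervention`, `cost_primary_care`, `cost_medicine`,
#'   `cost_secondary_care`, `cost_productivity`, `cost_informal_time`,
#'   `cost_transport`).
#' @inheritParams compute_patient_costs
#' @return The data with `cost_total` recomputed for the perspective.
#' @export
aggregate_costs <- function(components, perspective = c("societal", "healthcare")) {
  cats <- perspective_categories(perspective[1])
  miss <- setdiff(cats, names(components))
  if (length(miss))
    abort(sprintf("missing cost component column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "cueval_validation_error", field = miss[1])
  components$cost_total <- rowSums(as.matrix(components[, cats, drop = FALSE]))
  components
}

#' Table of per-category mean costs by arm
#'
#' Summarises a costed patient table into per-category arm means with
#' bootstrapped standard errors, mirroring the layout of a trial cost
#' table.
#'
#' @param costed Output of [compute_patient_costs()].
#' @param B Bootstrap replications for the SEs (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with one row per category and columns
#'   `mean_<arm>`, `se_<arm>`, `difference`.
#' @export
cost_summary_table <- function(costed, B = 1000, seed = NULL) {
  cols <- c(cost_category_cols, "cost_total")
  cols <- intersect(cols, names(costed))
  arms <- unique(as.character(costed$arm))
  boot_se <- function(v, B) {
    n <- length(v)
    m <- matrix(v[sample.int(n, n * B, replace = TRUE)], nrow = n)
    sd(colMeans(m))
  }
  with_seed(seed, {
    out <- purrr::map_dfr(cols, function(cl) {
      row <- tibble(category = sub("^cost_", "", cl))
      for (a in arms) {
        v <- costed[[cl]][costed$arm == a]
        row[[paste0("mean_", a)]] <- mean(v)
        row[[paste0("se_", a)]] <- boot_se(v, B)
      }
      if (length(arms) == 2)
        row$difference <- row[[paste0("mean_", arms[1])]] -
          row[[paste0("mean_", arms[2])]]
      row
    })
    out
  })
}
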