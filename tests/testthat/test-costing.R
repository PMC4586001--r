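test_that("the load factor adds the unproductive-time hours", {
  expect_equal(apply_load(62, 1.5), 93)
  expect_equal(apply_load(58, 1.5), 87)
  expect_equal(apply_load(44, 1.5), 66)
  expect_equal(apply_load(17.3, 1), 17.3)       # load 1 is the identity
  expect_error(apply_load(-1, 1.5), class = "cueval_validation_error")
  expect_error(apply_load(10, 0.9), class = "cueval_validation_error")
})

test_that("micro-costing reproduces the published course cost line by line", {
  cc <- course_cost(lc_course(), table2_catalogue())
  cs <- course_cost(std_course(), table2_catalogue())

  # nurse block, LC: 36 h training, 8 education, 10 interviews, 8 team eval,
  # 31 load hours at 197 DKK/h
  nurse <- cc$lines[cc$lines$role == "nurse", ]
  expect_equal(nurse$cost, c(7092, 1576, 1970, 1576, 6107))
  expect_equal(cc$nurse_total, 18321)
  expect_equal(cs$nurse_total, 13002)

  physio <- cc$lines[cc$lines$role == "physiotherapist", ]
  expect_equal(physio$cost, c(5760, 640, 1600, 1280, 4640))
  expect_equal(cc$physio_total, 13920)
  expect_equal(cs$physio_total, 9600)

  expert <- cc$lines[cc$lines$role == "expert_patient", ]
  expect_equal(expert$cost, c(1296, 1296, 864, 1728, 2304))
  expect_equal(cc$expert_total, 7488)
  expect_equal(cs$expert_total, 0)

  expect_equal(unname(cc$loaded_hours), c(93, 87))
  expect_equal(unname(cs$loaded_hours), c(66, 60))

  expect_equal(cc$overhead, 8343)
  expect_equal(cs$overhead, 4746)
  expect_equal(cc$total_per_course, 48072)
  expect_equal(cs$total_per_course, 27348)
  expect_equal(cc$cost_per_patient, 4807)
  expect_equal(cs$cost_per_patient, 2735)
  expect_equal(cc$cost_per_patient - cs$cost_per_patient, 2072)
})

test_that("course cost is linear in wages and decreases without the load", {
  cat2013 <- table2_catalogue()
  doubled <- cat2013
  doubled$items <- lapply(cat2013$items, function(v) 2 * v)
  spec2 <- lc_course()
  spec2$expert_transport_cost_total <- 2 * spec2$expert_transport_cost_total
  base <- course_cost(lc_course(), cat2013)$total_per_course
  twice <- course_cost(spec2, doubled)$total_per_course
  # rounding the overhead line can shift a doubled total by at most 1 DKK
  expect_lt(abs(twice - 2 * base), 1.5)

  unloaded <- cat2013
  unloaded$load_factor <- 1
  expect_lt(course_cost(lc_course(), unloaded)$total_per_course, base)
  # empty course costs nothing
  empty <- course_spec("none", patients_per_course = 10)
  expect_equal(course_cost(empty, cat2013)$total_per_course, 0)
})

test_that("informal time is valued at the wage rate", {
  tab <- default_salary_table()
  expect_equal(informal_time_cost(10, "male", 62, "leisure", tab), 1440)
  expect_equal(informal_time_cost(0, "male", 62, "leisure", tab), 0)
  expect_equal(informal_time_cost(1, "female", 62, "productive", tab),
               lookup_salary(tab, "female", 62, "productive"))
  expect_error(informal_time_cost(-1, "male", 62, "leisure", tab),
               class = "cueval_validation_error")
})

test_that("patient transport prices kilometres at the car tariff", {
  expect_equal(transport_cost(total_km = 557.71, tariff = 3.82)$cost_dkk, 2130)
  z <- transport_cost(n_contacts = 0, tariff = 3.82)
  expect_equal(z$cost_dkk, 0)
  expect_equal(z$time_hours, 0)
  one <- transport_cost(n_contacts = 1, km_per_way = 10, tariff = 3.82)
  expect_equal(one$cost_dkk, 76)  # 2 x 10 x 3.82 = 76.4
  expect_equal(one$time_hours, 2 / 3)
  expect_error(transport_cost(n_contacts = -1, tariff = 3.82),
               class = "cueval_validation_error")
})

test_that("productivity loss applies only below the pension age", {
  tab <- default_salary_table()
  expect_equal(productivity_loss_cost(5, "male", 70, tab), 0)
  expect_equal(productivity_loss_cost(0, "male", 50, tab), 0)
  expect_equal(productivity_loss_cost(4, "male", 62, tab), 4 * 37 * 164)
  # 66.9 years at randomisation crosses 67 before the 5-month follow-up ends
  expect_equal(productivity_loss_cost(4, "male", 66.9, tab), 0)
})

test_that("price-year adjustment scales by the CPI ratio", {
  idx <- c("2010" = 100, "2012" = 102, "2013" = 104)
  expect_equal(adjust_price_year(500, 2013, idx), 500)
  expect_equal(adjust_price_year(100, 2010, idx), 104)
  expect_equal(adjust_price_year(c(100, 200), 2010, idx), c(104, 208))
  expect_error(adjust_price_year(100, 2009, idx),
               class = "cueval_validation_error")
})

test_that("perspective totals sum exactly the included categories", {
  societal <- tiny_costed(perspective = "societal")
  healthcare <- tiny_costed(perspective = "healthcare")
  expect_equal(
    societal$cost_total,
    rowSums(societal[, perspective_categories("societal")])
  )
  expect_equal(
    healthcare$cost_total,
    rowSums(healthcare[, perspective_categories("healthcare")])
  )
  # societal covers healthcare plus the non-negative societal categories
  expect_true(all(societal$cost_total >= healthcare$cost_total))
  # the gap decomposes into the societal-only categories plus the wider
  # intervention attribution (expert-patient time is societal, not formal care)
  gap <- societal$cost_total - healthcare$cost_total
  expect_equal(
    gap,
    societal$cost_productivity + societal$cost_informal_time +
      societal$cost_transport +
      (societal$cost_intervention - healthcare$cost_intervention)
  )
  # in the standard arm (no expert patients) the attribution term vanishes
  std <- societal$arm == "standard"
  expect_equal(societal$cost_intervention[std],
               healthcare$cost_intervention[std])
  expect_error(tiny_costed(perspective = "galactic"),
               class = "cueval_validation_error")
  expect_error(tiny_costed(exclusions = "champagne"),
               class = "cueval_validation_error")
})

test_that("category exclusions zero exactly their category", {
  base <- tiny_costed()
  no_time <- tiny_costed(exclusions = "patient_time")
  expect_true(all(no_time$cost_informal_time == 0))
  expect_equal(base$cost_total - no_time$cost_total, base$cost_informal_time)
  no_post <- tiny_costed(exclusions = "post_followup_admissions")
  expect_equal(base$cost_secondary_care - no_post$cost_secondary_care,
               base$cost_admissions_post)
})

test_that("a patient with only outpatient cost totals exactly that cost under healthcare", {
  r <- tiny_records(1)
  r[, grep("^cost_", names(r))] <- 0
  r$weeks_sick <- 0; r$weeks_disability <- 0
  r$cost_outpatient <- c(12345, 0)
  # null out the intervention by pricing an empty course
  empty <- course_spec("LC", 10); empty_s <- course_spec("standard", 10)
  cat0 <- table2_catalogue()
  out <- compute_patient_costs(r, cat0, empty, empty_s,
                               perspective = "healthcare")
  expect_equal(out$cost_total, c(12345, 0))
})
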