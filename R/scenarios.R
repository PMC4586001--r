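scenario_override_keys <- function(catalogue) {
  c(names(catalogue$items), "load_factor", "overhead_rate",
    "patients_per_course")
}

#' Define a sensitivity scenario
#'
#' A scenario is a declarative modification of the main analysis: a cost
#' perspective, catalogue overrides (wages, load factor, overhead,
#' patients per course), cost-category exclusions, and the imputation
#' mode. The shipped fixtures carry the five standard sensitivity
#' scenarios: healthcare perspective, lower therapist salaries (nurse 150,
#' physiotherapist 120 DKK/h), no load factor, 12 patients per course, and
#' excluding patient time.
#'
#' @param name Unique scenario name.
#' @param perspective `"societal"` or `"healthcare"`.
#' @param overrides Named list of catalogue/course overrides; keys must be
#'   catalogue item names or `load_factor`, `overhead_rate`,
#'   `patients_per_course`.
#' @param exclusions Cost-category exclusions (see
#'   [compute_patient_costs()]).
#' @param imputation `"mice"` (chained equations, default), `"locf"` or
#'   `"complete_case"`.
#' @return A `cueval_scenario` object.
#' @export
scenario <- function(name, perspective = c("societal", "healthcare"),
                     overrides = list(), exclusions = character(),
                     imputation = c("mice", "locf", "complete_case")) {
  perspective <- match.arg(perspective)
  imputation <- match.arg(imputation)
  bad <- setdiff(exclusions, cost_exclusion_choices)
  if (length(bad))
    abort(sprintf("unknown exclusion(s): %s", paste(bad, collapse = ", ")),
          class = "cueval_validation_error", field = "exclusions")
  structure(
    list(name = as.character(name), perspective = perspective,
         overrides = as.list(overrides), exclusions = exclusions,
         imputation = imputation),
    class = "cueval_scenario"
  )
}

#' @export
print.cueval_scenario <- function(x, ...) {
  cat(sprintf("<cueval_scenario> %s (%s perspective, %s imputation)\n",
              x$name, x$perspective, x$imputation))
  if (length(x$overrides))
    cat("  overrides:",
        paste(sprintf("%s=%s", names(x$overrides), unlist(x$overrides)),
              collapse = ", "), "\n")
  if (length(x$exclusions))
    cat("  exclusions:", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a scenario file
#'
#' @param path File path of a scenario YAML document.
#' @return `read_scenario()` returns a `cueval_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- read_yaml_file(path, "scenario")
  scenario(
    name = raw$name %||% tools::file_path_sans_ext(basename(path)),
    perspective = raw$perspective %||% "societal",
    overrides = raw$overrides %||% list(),
    exclusions = unlist(raw$exclusions) %||% character(),
    imputation = raw$imputation %||% "mice"
  )
}

#' @rdname read_scenario
#' @param x A `cueval_scenario`.
#' @export
write_scenario <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' The five shipped sensitivity scenarios
#'
#' @return A named list of `cueval_scenario` objects read from the
#'   package fixtures.
#' @export
default_scenarios <- function() {
  files <- c("scenario-healthcare.yaml", "scenario-lower-salaries.yaml",
             "scenario-no-load-factor.yaml", "scenario-12-patients.yaml",
             "scenario-exclude-patient-time.yaml")
  out <- lapply(files, function(f) read_scenario(cueval_example(f)))
  setNames(out, vapply(out, `[[`, "", "name"))
}

#' Apply scenario overrides to the catalogue and course specs
#'
#' Validates every override key against the catalogue before any
#' computation and returns the modified configuration.
#'
#' @param scn A [scenario()].
#' @param catalogue A [cost_catalogue()].
#' @param course_lc,course_standard [course_spec()]s.
#' @return List with elements `catalogue`, `course_lc`, `course_standard`.
#' @export
apply_scenario <- function(scn, catalogue, course_lc, course_standard) {
  allowed <- scenario_override_keys(catalogue)
  bad <- setdiff(names(scn$overrides), allowed)
  if (length(bad))
    abort(sprintf("unknown override key(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
          class = "cueval_validation_error", field = bad[1])
  for (key in names(scn$overrides)) {
    v <- scn$overrides[[key]]
    if (key %in% names(catalogue$items)) catalogue$items[[key]] <- v
    else if (key %in% c("load_factor", "overhead_rate")) catalogue[[key]] <- v
    else if (key == "patients_per_course") {
      course_lc$patients_per_course <- v
      course_standard$patients_per_course <- v
    }
  }
  validate_catalogue(catalogue)
  list(catalogue = catalogue, course_lc = course_lc,
       course_standard = course_standard)
}

#' Run one sensitivity scenario end to end
#'
#' Re-runs costing, imputation, QALY estimation and the bootstrap CEA
#' under the scenario's modified configuration, producing a labelled
#' acceptability curve. A scenario with no modifications reproduces the
#' main analysis exactly (same seed).
#'
#' @param records Patient tibble (utilities may contain missing values).
#' @param scn A [scenario()].
#' @inheritParams compute_patient_costs
#' @param B Bootstrap replications per completed dataset.
#' @param m Imputations for the chained-equation mode.
#' @param seed Master seed.
#' @param lambdas Willingness-to-pay grid.
#' @return A `cueval_scenario_result`: list with the scenario, the
#'   `cueval_draws`, the `cueval_ceac` and a one-row `summary` tibble.
#' @export
run_scenario <- function(records, scn,
                         catalogue = read_catalogue(cueval_example("catalogue-2013.yaml")),
                         course_lc = read_course_spec(cueval_example("course-lc.yaml")),
                         course_standard = read_course_spec(cueval_example("course-standard.yaml")),
                         salary = default_salary_table(),
                         B = 1000, m = 5, seed = NULL,
                         lambdas = lambda_grid()) {
  cfg <- apply_scenario(scn, catalogue, course_lc, course_standard)
  costed <- compute_patient_costs(records, cfg$catalogue, cfg$course_lc,
                                  cfg$course_standard, salary,
                                  perspective = scn$perspective,
                                  exclusions = scn$exclusions)
  draws <- switch(
    scn$imputation,
    mice = {
      imps <- impute_chained(costed, m = m, seed = child_seed(seed, 101))
      bootstrap_incrementals(imps, B = B, seed = child_seed(seed, 102),
                             complete_fn = add_qaly)
    },
    locf = {
      filled <- suppressWarnings(impute_locf(costed))
      bootstrap_incrementals(add_qaly(filled), B = B,
                             seed = child_seed(seed, 102))
    },
    complete_case = {
      ccd <- complete_responders(costed)
      bootstrap_incrementals(add_qaly(ccd), B = B,
                             seed = child_seed(seed, 102))
    }
  )
  curve <- ceac(draws, lambdas)
  structure(
    list(name = scn$name, scenario = scn, draws = draws, ceac = curve,
         summary = mutate(glance(draws), scenario = scn$name, .before = 1)),
    class = "cueval_scenario_result"
  )
}

#' @export
print.cueval_scenario_result <- function(x, ...) {
  cat(sprintf("<cueval_scenario_result> %s\n", x$name))
  print(x$summary)
  invisible(x)
}

#' Run a suite of scenarios on a shared willingness-to-pay grid
#'
#' @param records Patient tibble.
#' @param scenarios List of [scenario()]s with unique names.
#' @param ... Passed to [run_scenario()] (catalogue, salary, `B`, `m`,
#'   `seed`, `lambdas`).
#' @param lambdas Shared grid for every curve.
#' @return A `cueval_scenario_suite`: list of results plus a combined
#'   `curves` tibble (`scenario`, `lambda`, `probability`).
#' @export
scenario_suite <- function(records, scenarios, ..., lambdas = lambda_grid()) {
  if (length(scenarios) == 0)
    abort("need at least one scenario", class = "cueval_validation_error",
          field = "scenarios")
  nms <- vapply(scenarios, `[[`, "", "name")
  if (anyDuplicated(nms))
    abort(sprintf("duplicate scenario name(s): %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          class = "cueval_validation_error", field = "name")
  results <- lapply(scenarios, function(s)
    run_scenario(records, s, ..., lambdas = lambdas))
  curves <- purrr::map_dfr(results, function(r)
    mutate(as_tibble(unclass(r$ceac)), scenario = r$name, .before = 1))
  structure(
    list(results = setNames(results, nms), curves = curves,
         lambdas = lambdas),
    class = "cueval_scenario_suite"
  )
}

#' @export
print.cueval_scenario_suite <- function(x, ...) {
  cat(sprintf("<cueval_scenario_suite> %d scenario(s)\n", length(x$results)))
  print(purrr::map_dfr(x$results, "summary"))
  invisible(x)
}

#' Plot all scenario acceptability curves together
#'
#' @param object A `cueval_scenario_suite`.
#' @param ... Unused.
#' @return A ggplot with one curve per scenario.
#' @export
autoplot.cueval_scenario_suite <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY (DKK)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
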