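#' Construct a cost catalogue
#'
#' A cost catalogue holds the unit costs used to price the rehabilitation
#' programme: staff wages (DKK/hour), the expert-patient pensioner wage, the
#' expert transport tariff (DKK/way), the patient car tariff (DKK/km),
#' together with the staff load factor, the hospital overhead rate, and the
#' price year all amounts are expressed in.
#'
#' @param items Named list or vector of non-negative unit costs. Expected
#'   names include `nurse_hourly`, `physiotherapist_hourly`,
#'   `expert_patient_hourly`, `expert_transport_per_way`,
#'   `patient_transport_per_km`.
#' @param load_factor Multiplier (>= 1) applied to staff formal hours to
#'   cover non-productive time (breaks, vacation, courses). 1 means no
#'   loading.
#' @param overhead_rate Fraction in \[0, 1\] added on top of staff costs for
#'   capital and indirect hospital costs.
#' @param price_year Calendar year the unit costs are expressed in.
#'
#' @return A `cueval_catalogue` object (a validated list).
#' @seealso [read_catalogue()], [course_cost()]
#' @export
#' @examples
#' cat2013 <- read_catalogue(cueval_example("catalogue-2013.yaml"))
#' cat2013$items$nurse_hourly
cost_catalogue <- function(items, load_factor = 1.5, overhead_rate = 0.21,
                           price_year = 2013) {
  x <- structure(
    list(
      items = as.list(items),
      load_factor = as.numeric(load_factor),
      overhead_rate = as.numeric(overhead_rate),
      price_year = as.integer(price_year)
    ),
    class = "cueval_catalogue"
  )
  validate_catalogue(x)
}

validation_error <- function(field, msg) {
  abort(sprintf("invalid value for `%s`: %s", field, msg),
        class = "cueval_validation_error", field = field)
}

#' Validate a cost catalogue
#'
#' Checks the catalogue invariants: all unit costs non-negative and numeric,
#' load factor at least 1, overhead rate in \[0, 1\].
#'
#' @param x A `cueval_catalogue`.
#' @return `x`, invisibly unchanged, if valid; otherwise a validation error
#'   naming the offending field.
#' @export
validate_catalogue <- function(x) {
  if (!is.list(x$items) || length(x$items) == 0)
    validation_error("items", "must be a non-empty named list")
  if (is.null(names(x$items)) || any(names(x$items) == ""))
    validation_error("items", "every item must be named")
  for (nm in names(x$items)) {
    v <- x$items[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      validation_error(paste0("items.", nm), "must be a single number")
    if (v < 0)
      validation_error(paste0("items.", nm), "unit costs must be >= 0")
  }
  for (fld in c("load_factor", "overhead_rate")) {
    v <- x[[fld]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      validation_error(fld, "must be a single number")
  }
  if (x$load_factor < 1)
    validation_error("load_factor", "must be >= 1 (1 = no loading)")
  if (x$overhead_rate < 0 || x$overhead_rate > 1)
    validation_error("overhead_rate", "must be in [0, 1]")
  if (is.na(x$price_year))
    validation_error("price_year", "must be a calendar year")
  invisible(x)
}

#' Read or write a cost catalogue file
#'
#' Catalogues are stored as flat YAML documents with keys `price_year`,
#' `load_factor`, `overhead_rate` and a nested `items` map. The shipped
#' fixture `catalogue-2013.yaml` carries the 2013 Danish unit costs used
#' throughout the package examples.
#'
#' @param path File path.
#' @return `read_catalogue()` returns a validated `cueval_catalogue`;
#'   `write_catalogue()` returns `path` invisibly.
#' @export
read_catalogue <- function(path) {
  raw <- read_yaml_file(path, "catalogue")
  for (key in c("items", "load_factor", "overhead_rate", "price_year"))
    if (is.null(raw[[key]]))
      validation_error(key, sprintf("missing from catalogue file '%s'", path))
  cost_catalogue(raw$items, raw$load_factor, raw$overhead_rate, raw$price_year)
}

#' @rdname read_catalogue
#' @param x A `cueval_catalogue`.
#' @export
write_catalogue <- function(x, path) {
  validate_catalogue(x)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

read_yaml_file <- function(path, what) {
  if (!file.exists(path))
    abort(sprintf("%s file '%s' does not exist", what, path),
          class = "cueval_validation_error", field = "path")
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort(sprintf("malformed %s file '%s': %s", what, path, conditionMessage(e)),
          class = "cueval_validation_error", field = "path"))
  if (!is.list(raw))
    abort(sprintf("malformed %s file '%s'", what, path),
          class = "cueval_validation_error", field = "path")
  raw
}

#' @export
print.cueval_catalogue <- function(x, ...) {
  cat(sprintf("<cueval_catalogue> price year %d, load factor %.2f, overhead %.0f%%\n",
              x$price_year, x$load_factor, 100 * x$overhead_rate))
  for (nm in names(x$items)) cat(sprintf("  %-26s %8.2f\n", nm, x$items[[nm]]))
  invisible(x)
}

# ---- course specification ----------------------------------------------

#' Construct a course specification
#'
#' Describes one 8-week group course of the rehabilitation programme in
#' role-hours: nurse and physiotherapist hours split over training sessions,
#' education sessions, individual interviews and weekly team evaluations;
#' expert-patient (lay educator) hours plus their transport time; the total
#' expert transport bill per course; and the number of patients sharing the
#' course. The standard arm has no interviews, team evaluations or expert
#' patients.
#'
#' @param arm Arm label, e.g. `"LC"` or `"standard"`.
#' @param patients_per_course Number of patients sharing one course (>= 1).
#' @param nurse,physiotherapist Named lists with hour counts `training_h`,
#'   `education_h`, `interview_h`, `team_eval_h` (all >= 0).
#' @param expert_patient Named list with `training_h`, `education_h`,
#'   `team_eval_h`, `transport_time_h`.
#' @param expert_transport_cost_total Total expert transport cost per course
#'   (DKK), paid by the hospital.
#'
#' @return A `cueval_course` object.
#' @seealso [course_cost()], [read_course_spec()]
#' @export
course_spec <- function(arm, patients_per_course = 10,
                        nurse = list(), physiotherapist = list(),
                        expert_patient = list(),
                        expert_transport_cost_total = 0) {
  fill <- function(x, keys) {
    out <- setNames(as.list(rep(0, length(keys))), keys)
    for (k in names(x)) {
      if (!k %in% keys)
        validation_error(k, sprintf("unknown hour field (expected %s)",
                                    paste(keys, collapse = ", ")))
      out[[k]] <- as.numeric(x[[k]])
    }
    out
  }
  staff_keys <- c("training_h", "education_h", "interview_h", "team_eval_h")
  x <- structure(
    list(
      arm = as.character(arm),
      patients_per_course = as.numeric(patients_per_course),
      nurse = fill(nurse, staff_keys),
      physiotherapist = fill(physiotherapist, staff_keys),
      expert_patient = fill(expert_patient,
                            c("training_h", "education_h", "team_eval_h",
                              "transport_time_h")),
      expert_transport_cost_total = as.numeric(expert_transport_cost_total)
    ),
    class = "cueval_course"
  )
  validate_course_spec(x)
}

#' @rdname course_spec
#' @param x A `cueval_course`.
#' @export
validate_course_spec <- function(x) {
  if (!is.numeric(x$patients_per_course) || is.na(x$patients_per_course) ||
      x$patients_per_course < 1)
    validation_error("patients_per_course", "must be >= 1")
  for (role in c("nurse", "physiotherapist", "expert_patient"))
    for (nm in names(x[[role]])) {
      v <- x[[role]][[nm]]
      if (!is.numeric(v) || is.na(v) || v < 0)
        validation_error(paste0(role, ".", nm), "hours must be >= 0")
    }
  if (x$expert_transport_cost_total < 0)
    validation_error("expert_transport_cost_total", "must be >= 0")
  invisible(x)
}

#' Read or write a course specification file
#'
#' Course specs are YAML documents with role sections; fixtures
#' `course-lc.yaml` and `course-standard.yaml` ship the two arms' planned
#' schedules.
#'
#' @param path File path.
#' @return `read_course_spec()` returns a validated `cueval_course`.
#' @export
read_course_spec <- function(path) {
  raw <- read_yaml_file(path, "course spec")
  if (is.null(raw$arm)) validation_error("arm", "missing from course file")
  course_spec(
    arm = raw$arm,
    patients_per_course = raw$patients_per_course %||% 10,
    nurse = raw$nurse %||% list(),
    physiotherapist = raw$physiotherapist %||% list(),
    expert_patient = raw$expert_patient %||% list(),
    expert_transport_cost_total = raw$expert_transport_cost_total %||% 0
  )
}

#' @rdname read_course_spec
#' @param x A `cueval_course`.
#' @export
write_course_spec <- function(x, path) {
  validate_course_spec(x)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

# ---- salary table -------------------------------------------------------

#' Construct a salary table
#'
#' Gender- and age-band-specific national average salaries used to value
#' time by the opportunity-cost method: leisure time at the net wage,
#' productive time at the gross wage.
#'
#' @param df Data frame with columns `gender` ("male"/"female"), `age_min`,
#'   `age_max`, `gross_hourly`, `net_hourly` (DKK/hour). Bands must satisfy
#'   `net_hourly <= gross_hourly` and, within gender, cover a contiguous age
#'   range without overlap.
#' @return A `cueval_salary` tibble.
#' @seealso [lookup_salary()], [default_salary_table()]
#' @export
salary_table <- function(df) {
  df <- as_tibble(df)
  need <- c("gender", "age_min", "age_max", "gross_hourly", "net_hourly")
  miss <- setdiff(need, names(df))
  if (length(miss))
    validation_error(miss[1], "missing salary table column")
  if (any(df$net_hourly > df$gross_hourly))
    validation_error("net_hourly", "net wage must not exceed gross wage")
  if (any(df$gross_hourly < 0))
    validation_error("gross_hourly", "wages must be >= 0")
  df <- arrange(df, .data$gender, .data$age_min)
  by_g <- split(df, df$gender)
  for (g in names(by_g)) {
    b <- by_g[[g]]
    if (any(b$age_max < b$age_min))
      validation_error("age_max", "band upper bound below lower bound")
    if (nrow(b) > 1 && any(b$age_min[-1] != b$age_max[-nrow(b)] + 1))
      validation_error("age_min",
                       sprintf("bands for gender '%s' must tile the age range", g))
  }
  class(df) <- c("cueval_salary", class(df))
  df
}

#' Default salary table
#'
#' Reads the shipped synthetic salary table
#' (`salary-table-synthetic.csv`). Only the four 60-64-year-old cells are
#' national figures; the remaining bands are a plausible synthetic age
#' profile constructed around them, scaled so the female/male and net/gross
#' ratios of the anchored cells hold approximately across bands.
#'
#' @return A `cueval_salary` tibble.
#' @export
default_salary_table <- function() {
  read_salary_table(cueval_example("salary-table-synthetic.csv"))
}

#' @rdname default_salary_table
#' @param path Path to a salary table CSV.
#' @export
read_salary_table <- function(path) {
  if (!file.exists(path))
    abort(sprintf("salary table '%s' does not exist", path),
          class = "cueval_validation_error", field = "path")
  salary_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Look up an hourly wage
#'
#' Resolves each (gender, age) pair to its 5-year salary band and returns
#' the net hourly wage for leisure time or the gross hourly wage for
#' productive time. Ages above the top band clamp to the top band; ages
#' below the bottom band are an error. Vectorised over `gender` and `age`.
#'
#' @param table A `cueval_salary` table.
#' @param gender Character vector, `"male"` or `"female"`.
#' @param age Numeric vector of ages in years.
#' @param time_type `"leisure"` (net wage) or `"productive"` (gross wage).
#' @return Numeric vector of DKK/hour.
#' @export
#' @examples
#' tab <- default_salary_table()
#' lookup_salary(tab, "male", 62, "productive")   # 164
#' lookup_salary(tab, "female", 62, "leisure")    # 111
lookup_salary <- function(table, gender, age, time_type = c("leisure", "productive")) {
  time_type <- match.arg(time_type)
  n <- max(length(gender), length(age))
  gender <- rep_len(as.character(gender), n)
  age <- rep_len(as.numeric(age), n)
  col <- if (time_type == "leisure") "net_hourly" else "gross_hourly"
  out <- rep(NA_real_, n)
  for (g in unique(gender)) {
    band <- table[table$gender == g, , drop = FALSE]
    if (nrow(band) == 0)
      abort(sprintf("gender '%s' not present in salary table", g),
            class = "cueval_lookup_error")
    idx <- which(gender == g)
    a <- pmin(age[idx], max(band$age_max))  # clamp above the top band
    if (any(a < min(band$age_min)))
      abort(sprintf("age %s below the salary table's supported range (%d+)",
                    paste(unique(a[a < min(band$age_min)]), collapse = ", "),
                    min(band$age_min)),
            class = "cueval_lookup_error")
    row <- findInterval(a, band$age_min)
    out[idx] <- band[[col]][row]
  }
  out
}

#' Path to a shipped example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
cueval_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "cueval")))
  path <- system.file("extdata", file, package = "cueval")
  if (path == "")
    abort(sprintf("no shipped example file '%s'", file))
  path
}
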