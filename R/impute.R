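#' Last observation carried forward (sensitivity imputation)
#'
#' Deterministic single imputation used as a sensitivity analysis: a
#' missing post-intervention utility is replaced by the baseline value, and
#' a missing follow-up utility by the (possibly just-imputed)
#' post-intervention value. Patients with a missing baseline have nothing
#' to carry forward and are excluded with a warning giving the count.
#'
#' Idempotent: applying it twice changes nothing.
#'
#' @param records Patient tibble with utility columns.
#' @param cols Utility columns in time order (default `c("u0","u2","u5")`).
#' @return The records with utilities carried forward; excluded-patient
#'   count in attribute `n_excluded`.
#' @export
impute_locf <- function(records, cols = c("u0", "u2", "u5")) {
  x <- as_tibble(records)
  base_missing <- is.na(x[[cols[1]]])
  if (any(base_missing)) {
    warn(sprintf("%d patient(s) excluded: baseline utility missing, nothing to carry forward",
                 sum(base_missing)))
    x <- x[!base_missing, , drop = FALSE]
  }
  for (j in seq_along(cols)[-1]) {
    cur <- x[[cols[j]]]
    prev <- x[[cols[j - 1]]]
    x[[cols[j]]] <- ifelse(is.na(cur), prev, cur)
  }
  attr(x, "n_excluded") <- sum(base_missing)
  x
}

#' Impute missing attendance by arm means
#'
#' Session attendance was not registered for an early part of the trial;
#' those missing counts are missing completely at random and are replaced
#' by the mean of the observed counts within the same randomisation arm.
#'
#' @param records Patient tibble with an `arm` column.
#' @param cols Attendance columns (default training and education counts).
#' @return Records with missing attendance filled in; the observed arm
#'   means are unchanged by construction.
#' @export
impute_attendance_mean <- function(records,
                                   cols = c("attend_training", "attend_education")) {
  x <- as_tibble(records)
  for (cl in cols) {
    if (!cl %in% names(x)) next
    for (a in unique(x$arm)) {
      i <- x$arm == a
      obs <- x[[cl]][i & !is.na(x[[cl]])]
      if (length(obs) == 0)
        abort(sprintf("arm '%s' has no observed values of %s to average", a, cl),
              class = "cueval_validation_error", field = cl)
      x[[cl]][i & is.na(x[[cl]])] <- mean(obs)
    }
  }
  x
}

# Bayesian linear regression imputation draw ("norm"): draw sigma^2 from
# its scaled inverse-chi-square posterior, beta from its conditional normal,
# then impute y_mis = X_mis beta* + N(0, sigma*^2) noise.
norm_draw <- function(y_obs, X_obs, X_mis) {
  qrx <- qr(X_obs)
  r <- qrx$rank
  keep <- qrx$pivot[seq_len(r)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  fit <- qr(Xo)
  beta_hat <- qr.coef(fit, y_obs)
  resid <- y_obs - Xo %*% beta_hat
  df <- max(length(y_obs) - r, 1)
  sigma2 <- sum(resid^2) / rchisq(1, df)
  R <- qr.R(fit)
  # V = (X'X)^-1 via R^-1 R^-T
  Rinv <- backsolve(R, diag(r))
  beta_star <- beta_hat + sqrt(sigma2) * (Rinv %*% rnorm(r))
  as.numeric(Xm %*% beta_star + rnorm(nrow(Xm)) * sqrt(sigma2))
}

#' Multiple imputation by chained equations
#'
#' Fills missing utility values with `m` stochastic completions. Each
#' incomplete variable is modelled by a linear regression on the supplied
#' predictors plus the other utility variables, with posterior draws of
#' the coefficients and residual variance so that imputation uncertainty
#' propagates into between-imputation variability. The chain visits the
#' incomplete variables in order for a fixed number of cycles (default
#' 10), which handles the non-monotone response pattern (a baseline
#' non-response can be followed by an observed follow-up). Imputed values
#' are clipped to the observed range of the variable being imputed.
#'
#' @param records Patient tibble.
#' @param vars Variables to impute (default the three utility columns).
#' @param predictors Complete covariate columns used in every conditional
#'   model. The default is the nonresponse-predictor set: arm, age,
#'   gender, attendance counts, secondary-care cost, medicine cost and
#'   productivity-loss cost.
#' @param m Number of completed datasets (default 20).
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @param seed Optional seed; the same seed reproduces the imputation set
#'   exactly.
#' @return A `cueval_imputation_set`: list with `imputations` (list of `m`
#'   completed tibbles), and the `m`, `vars`, `predictors`, `cycles`,
#'   `seed` used. Observed cells are identical across completions.
#' @export
impute_chained <- function(records,
                           vars = c("u0", "u2", "u5"),
                           predictors = c("arm", "age", "gender",
                                          "attend_training", "attend_education",
                                          "cost_secondary_care", "cost_medicine",
                                          "cost_productivity"),
                           m = 20, cycles = 10, seed = NULL) {
  x <- as_tibble(records)
  if (m < 1) abort("m must be >= 1", class = "cueval_validation_error", field = "m")
  miss_p <- setdiff(c(vars, predictors), names(x))
  if (length(miss_p))
    abort(sprintf("column(s) not in data: %s", paste(miss_p, collapse = ", ")),
          class = "cueval_validation_error", field = miss_p[1])
  if (anyNA(x[, predictors]))
    abort("predictor columns must be complete (impute attendance first)",
          class = "cueval_validation_error", field = "predictors")
  for (v in vars)
    if (all(is.na(x[[v]])))
      abort(sprintf("variable '%s' has no observed values to model", v),
            class = "cueval_validation_error", field = v)

  mm <- stats::model.matrix(~ ., data = x[, predictors, drop = FALSE])
  na_idx <- lapply(vars, function(v) which(is.na(x[[v]])))
  names(na_idx) <- vars
  incomplete <- vars[vapply(na_idx, length, 1L) > 0]

  impute_once <- function() {
    cur <- x
    # start the chain from random draws of the observed values
    for (v in incomplete) {
      obs <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]), replace = TRUE)
    }
    if (length(incomplete) == 0) return(cur)
    for (cyc in seq_len(cycles)) {
      for (v in incomplete) {
        others <- setdiff(vars, v)
        X <- cbind(mm, as.matrix(cur[, others, drop = FALSE]))
        idx <- na_idx[[v]]
        y_obs_mask <- !is.na(x[[v]])
        draw <- norm_draw(x[[v]][y_obs_mask], X[y_obs_mask, , drop = FALSE],
                          X[idx, , drop = FALSE])
        rng <- range(x[[v]][y_obs_mask])
        cur[[v]][idx] <- pmin(pmax(draw, rng[1]), rng[2])
      }
    }
    cur
  }

  imputations <- with_seed(seed, replicate(m, impute_once(), simplify = FALSE))
  structure(
    list(imputations = imputations, m = m, vars = vars,
         predictors = predictors, cycles = cycles, seed = seed,
         n_missing = vapply(na_idx, length, 1L)),
    class = "cueval_imputation_set"
  )
}

#' @export
print.cueval_imputation_set <- function(x, ...) {
  cat(sprintf("<cueval_imputation_set> m = %d completions of %d patients\n",
              x$m, nrow(x$imputations[[1]])))
  cat("  missing cells imputed:",
      paste(sprintf("%s=%d", names(x$n_missing), x$n_missing), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stack an imputation set into one long tibble
#'
#' @param x A `cueval_imputation_set`.
#' @param ... Unused.
#' @return Tibble of all completions with an `.imputation` index column.
#' @export
tidy.cueval_imputation_set <- function(x, ...) {
  purrr::imap_dfr(x$imputations, function(d, i) mutate(d, .imputation = i,
                                                       .before = 1))
}

#' Restrict to complete responders
#'
#' Keeps patients with every utility observed — the complete-response
#' scenario of the analysis.
#'
#' @param records Patient tibble.
#' @param cols Utility columns.
#' @return The complete-case subset.
#' @export
complete_responders <- function(records, cols = c("u0", "u2", "u5")) {
  records[complete.cases(records[, cols, drop = FALSE]), , drop = FALSE]
}

#' Nonresponse predictor analysis
#'
#' Compares responders (all utilities observed) with non-responders on
#' candidate predictors of nonresponse: Welch two-sample t tests for
#' numeric variables, a two-sample proportion test for binary factors.
#' Variables flagged significant at the 0.05 level are the candidates to
#' include as imputation predictors.
#'
#' @param records Patient tibble.
#' @param vars Variables to compare (defaults to the demographic, cost and
#'   attendance set).
#' @param utility_cols Utility columns defining response.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with per-variable responder/non-responder means, the
#'   difference, p value and significance flag. If either group is empty
#'   the table is returned degenerate with a `status` attribute
#'   `"degenerate"` and `NA` comparisons.
#' @export
nonresponse_analysis <- function(records,
                                 vars = c("age", "gender", "cost_primary_care",
                                          "cost_secondary_care", "cost_medicine",
                                          "cost_productivity", "attend_training",
                                          "attend_education"),
                                 utility_cols = c("u0", "u2", "u5"),
                                 alpha = 0.05) {
  x <- as_tibble(records)
  vars <- intersect(vars, names(x))
  responder <- complete.cases(x[, utility_cols, drop = FALSE])
  degenerate <- sum(responder) < 2 || sum(!responder) < 2
  rows <- purrr::map_dfr(vars, function(v) {
    col <- x[[v]]
    if (!is.numeric(col)) col <- as.numeric(factor(col)) - 1  # binary indicator
    mr <- mean(col[responder])
    mn <- mean(col[!responder])
    p <- NA_real_
    if (!degenerate)
      p <- tryCatch(t.test(col[responder], col[!responder])$p.value,
                    error = function(e) NA_real_)
    tibble(variable = v, mean_responders = mr, mean_nonresponders = mn,
           difference = mr - mn, p_value = p,
           significant = !is.na(p) & p < alpha)
  })
  attr(rows, "status") <- if (degenerate) "degenerate" else "ok"
  attr(rows, "n_responders") <- sum(responder)
  attr(rows, "n_nonresponders") <- sum(!responder)
  rows
}
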