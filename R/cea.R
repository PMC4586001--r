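#' Bootstrap the incremental cost and QALY
#'
#' Non-parametric bootstrap of the between-arm differences in mean cost
#' and mean QALY. Each replicate resamples patients with replacement
#' independently within each arm (the arms are independent randomised
#' groups), preserving the arm sizes, and records the pair
#' (mean cost difference, mean QALY difference). Point estimates are
#' computed on the original, un-resampled data. The default 10,000
#' replications follow standard practice for skewed trial cost data.
#'
#' For a [cueval_imputation_set][impute_chained()] the statistic is
#' bootstrapped within each completed dataset with `B` replicates each and
#' the draws are pooled across imputations, so the pooled draw cloud
#' carries both sampling and imputation uncertainty; the point estimate is
#' the average of the per-imputation point estimates.
#'
#' @param x A costed patient tibble with `arm`, cost and QALY columns, or
#'   a `cueval_imputation_set` whose completions carry those columns (see
#'   `complete_fn`).
#' @param B Bootstrap replications (per completed dataset for an
#'   imputation set).
#' @param seed Optional master seed; per-imputation streams are derived
#'   deterministically from it.
#' @param treatment,control Arm labels (defaults `"LC"`, `"standard"`).
#' @param cost_col,qaly_col Column names of per-patient cost and QALY.
#' @param complete_fn For an imputation set: function applied to each
#'   completed tibble before bootstrapping (e.g. [add_qaly()]); default
#'   identity.
#' @param ... Passed between methods.
#' @return A `cueval_draws` object: `draws` tibble
#'   (`delta_cost`, `delta_qaly`, `imputation`), point estimates
#'   `delta_cost`/`delta_qaly`, per-arm means, `B`, `seed`, arm sizes,
#'   and jackknife acceleration constants for BCa intervals (single
#'   dataset only).
#' @export
bootstrap_incrementals <- function(x, B = 10000, seed = NULL, ...) {
  UseMethod("bootstrap_incrementals")
}

arm_split <- function(data, treatment, control, cost_col, qaly_col) {
  arm <- as.character(data$arm)
  for (a in c(treatment, control))
    if (!any(arm == a))
      abort(sprintf("arm '%s' is empty", a),
            class = "cueval_validation_error", field = "arm")
  list(
    ct = data[[cost_col]][arm == treatment],
    qt = data[[qaly_col]][arm == treatment],
    cc = data[[cost_col]][arm == control],
    qc = data[[qaly_col]][arm == control]
  )
}

# B joint (cost, qaly) resampled means for one arm: same indices for both
# columns so the patient-level pairing is preserved.
boot_arm_means <- function(cost, qaly, B) {
  n <- length(cost)
  idx <- sample.int(n, n * B, replace = TRUE)
  dim(idx) <- c(n, B)
  list(cost = colMeans(matrix(cost[idx], n)), qaly = colMeans(matrix(qaly[idx], n)))
}

#' @rdname bootstrap_incrementals
#' @export
bootstrap_incrementals.data.frame <- function(x, B = 10000, seed = NULL,
                                              treatment = "LC",
                                              control = "standard",
                                              cost_col = "cost_total",
                                              qaly_col = "qaly", ...) {
  if (B < 1) abort("B must be >= 1", class = "cueval_validation_error", field = "B")
  if (anyNA(x[[qaly_col]]) || anyNA(x[[cost_col]]))
    abort("costs/QALYs contain missing values; run imputation before the CEA",
          class = "cueval_validation_error", field = qaly_col)
  s <- arm_split(x, treatment, control, cost_col, qaly_col)
  draws <- with_seed(seed, {
    t_ <- boot_arm_means(s$ct, s$qt, B)
    c_ <- boot_arm_means(s$cc, s$qc, B)
    tibble(delta_cost = t_$cost - c_$cost, delta_qaly = t_$qaly - c_$qaly,
           imputation = 1L)
  })
  # leave-one-out increments for BCa acceleration
  loo <- function(v) (sum(v) - v) / (length(v) - 1)
  jack <- c(loo(s$ct) - mean(s$cc), mean(s$ct) - loo(s$cc))
  jackq <- c(loo(s$qt) - mean(s$qc), mean(s$qt) - loo(s$qc))
  structure(
    list(draws = draws,
         delta_cost = mean(s$ct) - mean(s$cc),
         delta_qaly = mean(s$qt) - mean(s$qc),
         arm_means = tibble(
           arm = c(treatment, control),
           mean_cost = c(mean(s$ct), mean(s$cc)),
           mean_qaly = c(mean(s$qt), mean(s$qc)),
           n = c(length(s$ct), length(s$cc))
         ),
         B = B, m = 1L, seed = seed,
         n_treatment = length(s$ct), n_control = length(s$cc),
         jackknife = list(cost = jack, qaly = jackq)),
    class = "cueval_draws"
  )
}

#' @rdname bootstrap_incrementals
#' @export
bootstrap_incrementals.cueval_imputation_set <- function(x, B = 10000,
                                                         seed = NULL,
                                                         complete_fn = identity,
                                                         ...) {
  parts <- purrr::imap(x$imputations, function(d, i) {
    di <- complete_fn(d)
    bootstrap_incrementals(di, B = B, seed = child_seed(seed, i), ...)
  })
  draws <- purrr::imap_dfr(parts, function(p, i)
    mutate(p$draws, imputation = as.integer(i)))
  am <- purrr::map_dfr(parts, "arm_means") |>
    group_by(.data$arm) |>
    summarise(mean_cost = mean(.data$mean_cost),
              mean_qaly = mean(.data$mean_qaly), n = .data$n[1],
              .groups = "drop")
  structure(
    list(draws = draws,
         delta_cost = mean(vapply(parts, `[[`, 1, "delta_cost")),
         delta_qaly = mean(vapply(parts, `[[`, 1, "delta_qaly")),
         arm_means = am,
         B = B, m = x$m, seed = seed,
         n_treatment = parts[[1]]$n_treatment,
         n_control = parts[[1]]$n_control,
         jackknife = NULL),
    class = "cueval_draws"
  )
}

#' Net monetary benefit
#'
#' Converts an incremental (cost, QALY) pair to money at a
#' willingness-to-pay threshold: `lambda * delta_qaly - delta_cost`.
#' Vectorised over draws and over `lambda`.
#'
#' @param delta_cost Incremental cost (DKK).
#' @param delta_qaly Incremental QALYs (years).
#' @param lambda Willingness to pay per QALY (DKK), >= 0.
#' @return Net benefit in DKK.
#' @export
#' @examples
#' net_benefit(6043, 0.005, 100000)  # -5543
net_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0))
    abort("lambda must be >= 0", class = "cueval_validation_error",
          field = "lambda")
  lambda * delta_qaly - delta_cost
}

#' Willingness-to-pay grid
#'
#' @param from,to,by Grid limits and step in DKK per QALY; the default is
#'   0 to 500,000 DKK in steps of 1,000 (501 points).
#' @return Ascending numeric grid.
#' @export
lambda_grid <- function(from = 0, to = 5e5, by = 1000) seq(from, to, by = by)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold on the grid, the probability that
#' the intervention is cost-effective: the fraction of bootstrap draws
#' with strictly positive net benefit. (A net benefit of exactly zero
#' counts as not cost-effective; ties have measure zero for continuous
#' data.) At `lambda = 0` the curve equals the probability that the
#' intervention is cost-saving; as `lambda` grows it tends to the
#' probability of a positive QALY gain.
#'
#' @param draws A `cueval_draws` object.
#' @param lambdas Ascending non-negative grid (default [lambda_grid()]).
#' @return A `cueval_ceac` tibble with columns `lambda`, `probability`.
#' @export
ceac <- function(draws, lambdas = lambda_grid()) {
  if (length(lambdas) == 0)
    abort("empty willingness-to-pay grid",
          class = "cueval_validation_error", field = "lambdas")
  if (is.unsorted(lambdas) || any(lambdas < 0))
    abort("lambdas must be ascending and >= 0",
          class = "cueval_validation_error", field = "lambdas")
  dc <- draws$draws$delta_cost
  dq <- draws$draws$delta_qaly
  prob <- vapply(lambdas, function(l) mean(l * dq - dc > 0), numeric(1))
  out <- tibble(lambda = as.numeric(lambdas), probability = prob)
  class(out) <- c("cueval_ceac", class(out))
  attr(out, "B") <- draws$B
  attr(out, "m") <- draws$m
  out
}

#' Summarise bootstrapped increments
#'
#' Arm means, incremental point estimates, bootstrap standard errors (the
#' SD of the draws) and 95 % confidence intervals. The default interval is
#' the percentile bootstrap (2.5th/97.5th draw percentiles); `"normal"`
#' uses the normal approximation around the point estimate, and `"bca"`
#' the bias-corrected accelerated interval (single-dataset draws only,
#' since the jackknife acceleration is undefined for pooled
#' multiple-imputation draws).
#'
#' @param object A `cueval_draws` object.
#' @param ci One of `"percentile"`, `"normal"`, `"bca"`.
#' @param conf Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per quantity (`delta_cost`,
#'   `delta_qaly`): estimate, SE, CI bounds.
#' @export
summary.cueval_draws <- function(object,
                                 ci = c("percentile", "normal", "bca"),
                                 conf = 0.95, ...) {
  ci <- match.arg(ci)
  if (object$B < 100)
    warn("fewer than 100 bootstrap replications: percentile CIs are unstable")
  a <- (1 - conf) / 2
  one <- function(v, point, jack) {
    se <- sd(v)
    bounds <- switch(ci,
      percentile = quantile(v, c(a, 1 - a), names = FALSE),
      normal = point + qnorm(c(a, 1 - a)) * se,
      bca = {
        if (is.null(jack))
          abort("BCa intervals need single-dataset draws (jackknife unavailable for pooled MI draws)",
                class = "cueval_validation_error", field = "ci")
        z0 <- qnorm(mean(v < point))
        jm <- mean(jack)
        acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
        adj <- function(zz) pnorm(z0 + (z0 + zz) / (1 - acc * (z0 + zz)))
        quantile(v, c(adj(qnorm(a)), adj(qnorm(1 - a))), names = FALSE)
      })
    c(point, se, bounds)
  }
  dc <- one(object$draws$delta_cost, object$delta_cost, object$jackknife$cost)
  dq <- one(object$draws$delta_qaly, object$delta_qaly, object$jackknife$qaly)
  tibble(
    quantity = c("delta_cost", "delta_qaly"),
    estimate = c(dc[1], dq[1]),
    se = c(dc[2], dq[2]),
    conf_low = c(dc[3], dq[3]),
    conf_high = c(dc[4], dq[4]),
    ci_method = ci, conf_level = conf, B = object$B
  )
}

#' @export
print.cueval_draws <- function(x, ...) {
  cat(sprintf("<cueval_draws> B = %d x %d imputation(s)\n", x$B, x$m))
  cat(sprintf("  incremental cost %9.0f DKK, incremental QALY %7.4f\n",
              x$delta_cost, x$delta_qaly))
  invisible(x)
}

#' @export
tidy.cueval_draws <- function(x, ...) x$draws

#' @export
glance.cueval_draws <- function(x, ...) {
  s <- summary(x)
  tibble(
    delta_cost = s$estimate[1], se_cost = s$se[1],
    cost_conf_low = s$conf_low[1], cost_conf_high = s$conf_high[1],
    delta_qaly = s$estimate[2], se_qaly = s$se[2],
    qaly_conf_low = s$conf_low[2], qaly_conf_high = s$conf_high[2],
    B = x$B, m = x$m
  )
}

#' @export
tidy.cueval_ceac <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.cueval_ceac <- function(x, ...) {
  tibble(
    prob_at_zero = x$probability[1],
    prob_at_max = x$probability[nrow(x)],
    max_probability = max(x$probability),
    lambda_max = x$lambda[nrow(x)]
  )
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `cueval_ceac`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cueval_ceac <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY (DKK)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' @param object A `cueval_draws`.
#' @param ... Unused.
#' @return A ggplot of the bootstrap draw cloud with the point estimate.
#' @export
autoplot.cueval_draws <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate("point", x = object$delta_qaly, y = object$delta_cost,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (DKK)") +
    ggplot2::theme_minimal()
}
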