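# Class-stratified clinical-trial power ---------------------------------------

#' Group trajectory summary at trial horizons
#'
#' Fits a fixed-effects natural-cubic-spline mean model (two degrees of
#' freedom by default) to the raw composite within a group of subjects and
#' summarises it at each horizon: the mean is the covariate-averaged model
#' prediction at the horizon; the SD is the residual SD among visits within
#' a +/- `window`-year band around the horizon (so it captures the full
#' between- plus within-subject outcome spread a two-sample test would see).
#'
#' @param visits Visit-level tibble for the group.
#' @param baseline Optional baseline tibble supplying adjustment covariates.
#' @param horizons Numeric vector of horizon times in years.
#' @param covariates Baseline covariates to adjust for (plus the test-version
#'   indicator when present in `visits`); `NULL` for a time-only model.
#' @param spline_df Spline degrees of freedom for the time effect.
#' @param window Half-width (years) of the visit window for the SD.
#' @param group Optional label attached to the output.
#' @return A `group_summary` tibble: one row per horizon with `mean`, `sd`
#'   and `n_window` (visits contributing to the SD).
#' @export
group_trajectory_summary <- function(visits, baseline = NULL,
                                     horizons = c(2, 4), covariates = NULL,
                                     spline_df = 2, window = 0.5,
                                     group = NA_character_) {
  visits <- tibble::as_tibble(visits)
  for (h in horizons) {
    if (!any(abs(visits$time - h) <= window)) {
      abort(sprintf("group_trajectory_summary(): no visits within %.2g years of horizon %g.",
                    window, h))
    }
    if (min(visits$time) > h || max(visits$time) < h) {
      abort(sprintf("group_trajectory_summary(): observations do not bracket horizon %g.", h))
    }
  }
  if (nrow(visits) < spline_df + 2L) {
    abort("group_trajectory_summary(): too few visits to fit the mean model.")
  }
  bk <- c(min(0, min(visits$time)), max(visits$time))
  B <- natural_spline_basis(visits$time, spline_df, bk, knot_times = visits$time)
  X <- B
  has_tv <- "test_version" %in% names(visits)
  if (has_tv) X <- cbind(X, test_version_b = as.numeric(visits$test_version == "B"))
  if (length(covariates)) {
    if (is.null(baseline)) abort("group_trajectory_summary(): baseline table needed for covariates.")
    idx <- match(visits$subject_id, baseline$subject_id)
    Xc <- covariate_design(baseline, covariates)[idx, , drop = FALSE]
    X <- cbind(X, Xc)
  }
  D <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(D, visits$outcome)
  resid <- fit$residuals
  co <- fit$coefficients
  co[is.na(co)] <- 0

  rows <- purrr::map_dfr(horizons, function(h) {
    Bh <- natural_spline_basis(h, spline_df, bk,
                               interior_knots = attr(B, "interior_knots"))
    # covariate-averaged prediction: time terms at h, all other columns at
    # their observed visit-level means
    xbar <- colMeans(D)
    xbar[1L + seq_len(ncol(B))] <- Bh
    in_win <- abs(visits$time - h) <= window
    tibble::tibble(
      group = group, horizon = h,
      mean = sum(xbar * co),
      sd = stats::sd(resid[in_win]),
      n_window = sum(in_win)
    )
  })
  structure(rows, class = c("group_summary", class(tibble::tibble())))
}

#' Maximum possible treatment benefit at a horizon
#'
#' The reference group's mean outcome minus the target group's mean at the
#' horizon: the ceiling for a restorative treatment effect, taking the
#' biomarker-negative stable trajectory as the best attainable course.
#'
#' @param reference,group `group_summary` tibbles (or any tibble with
#'   `horizon` and `mean` columns).
#' @param horizon Horizon in years, present in both summaries.
#' @return The scalar mean difference (composite points).
#' @export
#' @examples
#' ref <- tibble::tibble(horizon = 2, mean = 1.14)
#' grp <- tibble::tibble(horizon = 2, mean = 0.88)
#' max_benefit(ref, grp, 2)  # 0.26
max_benefit <- function(reference, group, horizon) {
  r <- reference$mean[match(horizon, reference$horizon)]
  g <- group$mean[match(horizon, group$horizon)]
  if (anyNA(r) || anyNA(g)) {
    abort(sprintf("max_benefit(): horizon %g missing from a group summary.", horizon))
  }
  r - g
}

#' Two-sample t-test power with attrition
#'
#' Power of a two-sided two-sample t-test at level `alpha` for a mean
#' difference `delta` with common SD `sd`, after reducing each arm to its
#' completers: `n_eff = floor(n_per_arm * (1 - attrition))`. Uses the
#' noncentral t distribution with `2 (n_eff - 1)` degrees of freedom and
#' noncentrality `delta / (sd * sqrt(2 / n_eff))`.
#'
#' @param delta Mean outcome difference between arms at the horizon.
#' @param sd Outcome SD at the horizon.
#' @param n_per_arm Planned number of participants per arm.
#' @param attrition Fraction lost to follow-up by the horizon.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); vectorised over its arguments.
#' @export
#' @examples
#' two_sample_power(0.26, 2.19, 500, attrition = 0.10)  # about 0.43
two_sample_power <- function(delta, sd, n_per_arm = 500, attrition = 0,
                             alpha = 0.05) {
  if (any(sd <= 0)) abort("two_sample_power(): sd must be > 0.")
  if (any(attrition < 0 | attrition >= 1)) {
    abort("two_sample_power(): attrition must lie in [0, 1).")
  }
  if (any(alpha <= 0 | alpha >= 1)) abort("two_sample_power(): alpha must lie in (0, 1).")
  n_eff <- floor(n_per_arm * (1 - attrition))
  if (any(n_eff < 2)) abort("two_sample_power(): fewer than 2 completers per arm.")
  df <- 2 * (n_eff - 1)
  ncp <- delta / (sd * sqrt(2 / n_eff))
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
}

#' Class-stratified trial power report
#'
#' Builds the trial-design table: per analysis group (biomarker-negative
#' stable as reference, biomarker-positive stable, and the pooled decliner
#' classes), per horizon, the model-based mean and windowed SD, the maximum
#' possible benefit versus the reference, and the power to detect stated
#' fractions of that benefit.
#'
#' @param visits,baseline Cohort tables.
#' @param assignments Tibble with `subject_id` and `class` (e.g. the
#'   `assignment` element of an `lcmm_fit`); the first class level is treated
#'   as stable.
#' @param horizons Trial horizons in years.
#' @param n_per_arm Planned participants per arm.
#' @param attrition Attrition fraction per horizon (recycled or named by
#'   horizon).
#' @param alpha Two-sided level.
#' @param benefit_fractions Fractions of the maximum benefit to power for.
#' @param covariates Adjustment covariates for the group mean models.
#' @return A tibble: one row per group x horizon x benefit fraction, with a
#'   `note` flagging empty or degenerate groups.
#' @export
class_trial_report <- function(visits, baseline, assignments,
                               horizons = c(2, 4), n_per_arm = 500,
                               attrition = c(0.10, 0.20), alpha = 0.05,
                               benefit_fractions = c(0.2, 1),
                               covariates = c("apoe4", "sex_female", "age",
                                              "education", "ptau217", "amyloid")) {
  attrition <- rep_len(attrition, length(horizons))
  cls <- assignments$class[match(baseline$subject_id, assignments$subject_id)]
  stable_lab <- levels(assignments$class)[1L]
  neg <- baseline$arm == "negative-observational"
  groups <- list(
    "negative-stable" = baseline$subject_id[neg & cls == stable_lab],
    "positive-stable" = baseline$subject_id[!neg & cls == stable_lab],
    "decliners" = baseline$subject_id[!is.na(cls) & cls != stable_lab]
  )
  summaries <- purrr::imap(groups, function(ids, nm) {
    if (length(ids) < 5L) return(NULL)
    tryCatch(
      group_trajectory_summary(
        visits[visits$subject_id %in% ids, ], baseline,
        horizons = horizons, covariates = covariates, group = nm
      ),
      error = function(e) NULL
    )
  })
  ref <- summaries[["negative-stable"]]
  if (is.null(ref)) abort("class_trial_report(): reference group summary unavailable.")
  purrr::imap_dfr(summaries, function(sm, nm) {
    if (nm == "negative-stable") return(NULL)
    purrr::map_dfr(seq_along(horizons), function(i) {
      h <- horizons[i]
      if (is.null(sm)) {
        return(tibble::tibble(
          group = nm, horizon = h, mean = NA_real_, sd = NA_real_,
          delta_max = NA_real_, benefit_fraction = benefit_fractions,
          power = NA_real_, note = "empty or degenerate group"
        ))
      }
      row <- sm[sm$horizon == h, ]
      d <- max_benefit(ref, sm, h)
      tibble::tibble(
        group = nm, horizon = h, mean = row$mean, sd = row$sd,
        delta_max = d, benefit_fraction = benefit_fractions,
        power = two_sample_power(d * benefit_fractions, row$sd, n_per_arm,
                                 attrition[i], alpha),
        note = NA_character_
      )
    })
  })
}
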