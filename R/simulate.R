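# Synthetic-cohort generator -------------------------------------------------
#
# Emulates the statistical structure the downstream latent-class analysis
# assumes: a two-arm preclinical cohort (biomarker-negative observational arm
# plus a randomized biomarker-positive arm), baseline demographics and
# biomarkers with realistic moments and correlations, three latent trajectory
# classes whose membership follows a multinomial-logistic model of baseline
# covariates, class-specific spline mean trajectories of a cognitive composite
# with subject random intercepts, semiannual visits with geometric dropout,
# and an alternating test-version covariate.

#' Simulation parameters for a synthetic preclinical cohort
#'
#' Returns the full parameter set of the generator. The defaults constitute
#' the `"a4learn_like"` preset: a cohort of 1629 subjects (519 in the
#' biomarker-negative observational arm), three trajectory classes (stable,
#' slow decliner, fast decliner) in roughly 77/16/7 proportions, baseline
#' covariate moments matching a large preclinical Alzheimer's cohort, and
#' membership odds ratios per SD of roughly 3.2 (plasma p-tau217), 3.9
#' (hippocampal atrophy z), 1.4 (amyloid PET) and 1.9--2.9 (APOE e4). These
#' are approximate calibration targets, not fitted values.
#'
#' Membership and shared longitudinal coefficients are expressed on the
#' standardized scale: continuous covariates are z-scored by the nominal
#' population moments in `covariate_model`, binary covariates enter as 0/1
#' indicators, so `exp(coef)` is an odds ratio per SD (or per category).
#'
#' @param n_subjects Number of subjects.
#' @param prop_negative Fraction assigned to the biomarker-negative
#'   observational arm; the remainder split evenly between placebo and active.
#' @param include_tau_pet If `TRUE`, simulate a tau-PET composite covariate
#'   that carries additional information about class membership (odds ratios
#'   about 1.8 for the slow and 3.6 for the fast class per SD).
#' @param class_membership_coefs Matrix of multinomial log-odds coefficients,
#'   one row per non-reference class (`slow`, `fast`), columns
#'   `(Intercept)` plus covariate names; the `stable` reference class is all
#'   zero.
#' @param class_trajectory_curves Matrix of target composite values (raw
#'   scale), one row per class, evaluated at `curve_times`; converted
#'   internally to spline coefficients on the transformed scale.
#' @param curve_times Times (years) at which `class_trajectory_curves` pins
#'   each class mean trajectory.
#' @param shared_covariate_coefs Named vector of covariate effects on the
#'   transformed outcome, shared across classes.
#' @param sigma_b Random-intercept SD (transformed scale).
#' @param sigma_e Residual SD (transformed scale).
#' @param boxcox_lambda,boxcox_shift Outcome transform used by the generator;
#'   the default identity transform (`lambda = 1`) with a shift large enough
#'   to keep every shifted outcome positive.
#' @param visit_interval_years Scheduled visit spacing.
#' @param max_followup_years Administrative end of follow-up.
#' @param annual_dropout_prob Per-year probability of dropping out; the
#'   default gives a median follow-up of about 6 years.
#' @param spline_df,interior_knots Generator spline basis (defaults: two
#'   degrees of freedom, interior knot at 3 years, boundaries 0 and 7).
#' @param covariate_model Means/SDs/prevalences and the latent-normal
#'   correlation matrix of the baseline covariates; see the default for the
#'   expected structure.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_params` (a named list).
#' @export
#' @examples
#' p <- sim_params(n_subjects = 200, seed = 1)
#' cohort <- simulate_cohort(p)
#' dplyr::count(cohort$classes, class_true)
sim_params <- function(n_subjects = 1629,
                       prop_negative = 519 / 1629,
                       include_tau_pet = FALSE,
                       class_membership_coefs = NULL,
                       class_trajectory_curves = rbind(
                         stable = c(0.52, 0.90, 1.16),
                         slow   = c(-0.13, -2.20, -4.74),
                         fast   = c(-0.98, -7.50, -15.80)
                       ),
                       curve_times = c(0, 3, 6),
                       shared_covariate_coefs = c(
                         arm_active = 0, ptau217 = -0.30, amyloid = 0,
                         apoe4 = 0, sex_female = 0.30, age = 0,
                         education = 0.12, hipp_atrophy = -0.40,
                         test_version_b = -0.15
                       ),
                       sigma_b = 2.0,
                       sigma_e = 1.1,
                       boxcox_lambda = 1,
                       boxcox_shift = 30,
                       visit_interval_years = 0.5,
                       max_followup_years = 7,
                       annual_dropout_prob = 0.109,
                       spline_df = 2,
                       interior_knots = 3,
                       covariate_model = default_covariate_model(),
                       seed = 1L) {
  if (prop_negative < 0 || prop_negative > 1) {
    abort("sim_params(): prop_negative must lie in [0, 1].")
  }
  if (sigma_b < 0 || sigma_e <= 0) {
    abort("sim_params(): sigma_b must be >= 0 and sigma_e > 0.")
  }
  if (is.null(class_membership_coefs)) {
    class_membership_coefs <- default_membership_coefs(include_tau_pet)
  }
  p <- structure(list(
    n_subjects = as.integer(n_subjects),
    prop_negative = prop_negative,
    include_tau_pet = include_tau_pet,
    class_membership_coefs = class_membership_coefs,
    class_trajectory_curves = class_trajectory_curves,
    curve_times = curve_times,
    shared_covariate_coefs = shared_covariate_coefs,
    sigma_b = sigma_b,
    sigma_e = sigma_e,
    boxcox_lambda = boxcox_lambda,
    boxcox_shift = boxcox_shift,
    visit_interval_years = visit_interval_years,
    max_followup_years = max_followup_years,
    annual_dropout_prob = annual_dropout_prob,
    spline_df = spline_df,
    interior_knots = interior_knots,
    covariate_model = covariate_model,
    seed = as.integer(seed)
  ), class = "sim_params")
  validate_covariate_model(covariate_model)
  p
}

# Nominal covariate moments: pooled means/SDs target the published cohort's
# Total column; amyloid and p-tau217 differ by biomarker arm so that the
# negative-observational arm is genuinely amyloid-negative.
default_covariate_model <- function() {
  corr <- diag(5)
  nm <- c("age", "education", "ptau217", "amyloid", "hipp_atrophy")
  dimnames(corr) <- list(nm, nm)
  corr["age", "ptau217"] <- corr["ptau217", "age"] <- 0.20
  corr["age", "hipp_atrophy"] <- corr["hipp_atrophy", "age"] <- 0.30
  corr["age", "amyloid"] <- corr["amyloid", "age"] <- 0.10
  corr["ptau217", "amyloid"] <- corr["amyloid", "ptau217"] <- 0.65
  corr["ptau217", "hipp_atrophy"] <- corr["hipp_atrophy", "ptau217"] <- 0.40
  corr["amyloid", "hipp_atrophy"] <- corr["hipp_atrophy", "amyloid"] <- 0.35
  list(
    age = list(mean = 71.46, sd = 4.69),
    education = list(mean = 16.59, sd = 2.74),
    hipp_atrophy = list(mean = 0.01, sd = 1.03),
    ptau217 = list(
      meanlog = c(negative = log(0.16), positive = log(0.225)),
      sdlog = 0.45, mean = 0.24, sd = 0.15
    ),
    amyloid = list(
      mean_by_arm = c(negative = 8, positive = 64.6),
      sd_by_arm = c(negative = 10, positive = 32),
      mean = 46.53, sd = 40.23
    ),
    tau_pet = list(mean = 1.10, sd = 0.09,
                   cor = c(ptau217 = 0.50, amyloid = 0.40, hipp_atrophy = 0.30)),
    female_prob = 0.602,
    apoe4_prob = c(negative = 0.30, positive = 0.557),
    correlation = corr
  )
}

# Membership log-odds on the standardized scale. Intercepts were calibrated
# numerically (once) so the covariate-averaged class probabilities are close
# to 77/16/7 for the default covariate model.
default_membership_coefs <- function(include_tau_pet = FALSE) {
  covs <- c("(Intercept)", "arm_active", "ptau217", "amyloid", "apoe4",
            "sex_female", "age", "education", "hipp_atrophy")
  # headline per-SD odds ratios target the slow class; the fast class gets a
  # steeper biomarker gradient (1.5x on the log-odds scale), mirroring the
  # published monotone biomarker increase from slow to fast decliners
  xi <- rbind(
    slow = c(.SLOW_INTERCEPT, 0, 1.2 * log(3.2), 1.2 * log(1.4), log(1.9),
             0, log(1.4), 0, 1.2 * log(3.9)),
    fast = c(.FAST_INTERCEPT, 0, 1.8 * log(3.2), 1.8 * log(1.4), log(2.9),
             log(2.5), log(0.93), 0, 1.8 * log(3.9))
  )
  colnames(xi) <- covs
  if (include_tau_pet) {
    xi <- cbind(xi, tau_pet = c(log(1.8), log(3.6)))
    xi[, "(Intercept)"] <- c(.SLOW_INTERCEPT_TAU, .FAST_INTERCEPT_TAU)
  }
  xi
}

validate_covariate_model <- function(cm) {
  ev <- eigen(cm$correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(paste0(
      "covariate_model$correlation is not positive-definite ",
      sprintf("(smallest eigenvalue %.3g).", min(ev))
    ))
  }
  invisible(cm)
}

#' Simulate a baseline covariate table
#'
#' Draws one row per subject: study arm, age, sex, education, APOE e4
#' carriage, plasma p-tau217, amyloid PET (Centiloid), hippocampal-atrophy
#' z-score, and (optionally) a tau-PET composite. Continuous covariates share
#' a latent Gaussian copula with the correlation matrix in
#' `params$covariate_model`; p-tau217 is log-normal; amyloid and p-tau217
#' means depend on the biomarker arm.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per subject.
#' @export
simulate_baseline <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  cm <- validate_covariate_model(params$covariate_model)
  n <- params$n_subjects
  if (n < 1) abort("simulate_baseline(): n_subjects must be >= 1.")
  with_seed(derive_seed(params$seed, 1L), {
    n_neg <- round(n * params$prop_negative)
    arm <- c(
      rep("negative-observational", n_neg),
      sample(rep_len(c("placebo", "active"), n - n_neg))
    )
    positive <- arm != "negative-observational"

    L <- chol(cm$correlation)
    Z <- matrix(rnorm(n * 5), n, 5) %*% L
    colnames(Z) <- colnames(cm$correlation)

    age <- cm$age$mean + cm$age$sd * Z[, "age"]
    education <- cm$education$mean + cm$education$sd * Z[, "education"]
    hipp <- cm$hipp_atrophy$mean + cm$hipp_atrophy$sd * Z[, "hipp_atrophy"]
    mulog <- ifelse(positive, cm$ptau217$meanlog["positive"],
                    cm$ptau217$meanlog["negative"])
    ptau <- exp(mulog + cm$ptau217$sdlog * Z[, "ptau217"])
    amy_mu <- ifelse(positive, cm$amyloid$mean_by_arm["positive"],
                     cm$amyloid$mean_by_arm["negative"])
    amy_sd <- ifelse(positive, cm$amyloid$sd_by_arm["positive"],
                     cm$amyloid$sd_by_arm["negative"])
    amyloid <- amy_mu + amy_sd * Z[, "amyloid"]

    sex <- ifelse(runif(n) < cm$female_prob, "female", "male")
    apoe_p <- ifelse(positive, cm$apoe4_prob["positive"], cm$apoe4_prob["negative"])
    apoe4 <- as.integer(runif(n) < apoe_p)

    out <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      arm = arm, age = age, sex = sex, education = education,
      apoe4 = apoe4, ptau217 = ptau, amyloid = amyloid,
      hipp_atrophy = hipp
    )
    if (isTRUE(params$include_tau_pet)) {
      w <- cm$tau_pet$cor
      zt <- w["ptau217"] * Z[, "ptau217"] + w["amyloid"] * Z[, "amyloid"] +
        w["hipp_atrophy"] * Z[, "hipp_atrophy"]
      resid_sd <- sqrt(max(1e-8, 1 - sum(w^2)))  # approx; copula cross-terms small
      zt <- (zt + resid_sd * rnorm(n)) / stats::sd(zt + resid_sd * rnorm(n))
      out$tau_pet <- cm$tau_pet$mean + cm$tau_pet$sd * zt
    }
    out
  })
}

# Standardized membership/longitudinal design shared by the generator and the
# model code. `scale` supplies (mean, sd) per continuous covariate; when NULL
# the covariates enter untouched.
covariate_design <- function(baseline, covariates, scale = NULL) {
  n <- nrow(baseline)
  cols <- lapply(covariates, function(v) {
    if (v == "arm_active") {
      as.numeric(baseline$arm == "active")
    } else if (v == "sex_female") {
      as.numeric(baseline$sex == "female")
    } else if (v == "apoe4") {
      as.numeric(baseline$apoe4)
    } else {
      if (!v %in% names(baseline)) {
        abort(sprintf(
          "Covariate/coefficient mismatch: '%s' is not a column of the baseline table (missing: %s).",
          v, paste(setdiff(covariates, c(names(baseline), "arm_active", "sex_female", "apoe4")),
                   collapse = ", ")
        ))
      }
      x <- baseline[[v]]
      if (!is.null(scale) && v %in% names(scale)) {
        (x - scale[[v]][["mean"]]) / scale[[v]][["sd"]]
      } else {
        x
      }
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

covariate_scale_from_model <- function(cm) {
  list(
    age = c(mean = cm$age$mean, sd = cm$age$sd),
    education = c(mean = cm$education$mean, sd = cm$education$sd),
    hipp_atrophy = c(mean = cm$hipp_atrophy$mean, sd = cm$hipp_atrophy$sd),
    ptau217 = c(mean = cm$ptau217$mean, sd = cm$ptau217$sd),
    amyloid = c(mean = cm$amyloid$mean, sd = cm$amyloid$sd),
    tau_pet = c(mean = cm$tau_pet$mean, sd = cm$tau_pet$sd)
  )
}

#' Assign latent trajectory classes from baseline covariates
#'
#' Draws one class label per subject from the multinomial-logistic membership
#' model `P(class g | w) = exp(xi_0g + w' xi_g) / sum_l exp(xi_0l + w' xi_l)`,
#' with the reference class (all-zero coefficients) prepended as `stable`.
#'
#' @param baseline Baseline tibble from [simulate_baseline()].
#' @param coefs Coefficient matrix: one row per non-reference class, columns
#'   `(Intercept)` plus covariate names matching the baseline design.
#' @param seed Integer seed for the multinomial draw.
#' @param scale Optional per-covariate `c(mean, sd)` list used to z-score
#'   continuous covariates before applying `coefs`.
#' @return A tibble with `subject_id`, `class_true` (factor
#'   stable/slow/fast, or `class1..` for custom coefficient rows) and the
#'   membership probability columns `p_<class>`.
#' @export
assign_latent_class <- function(baseline, coefs, seed = 1L, scale = NULL) {
  if (!"(Intercept)" %in% colnames(coefs)) {
    abort("assign_latent_class(): coefs must contain an '(Intercept)' column.")
  }
  covs <- setdiff(colnames(coefs), "(Intercept)")
  W <- cbind(`(Intercept)` = 1, covariate_design(baseline, covs, scale))
  eta <- cbind(0, W %*% t(coefs[, colnames(W), drop = FALSE]))
  classes <- c("stable", rownames(coefs))
  if (is.null(rownames(coefs))) classes <- paste0("class", seq_len(ncol(eta)))
  colnames(eta) <- classes
  pi <- softmax_rows(eta)
  lab <- with_seed(derive_seed(seed, 2L), {
    u <- runif(nrow(pi))
    cp <- t(apply(pi, 1, cumsum))
    classes[1L + rowSums(u > cp + 1e-15)]
  })
  out <- tibble::tibble(
    subject_id = baseline$subject_id,
    class_true = factor(lab, levels = classes)
  )
  colnames(pi) <- paste0("p_", classes)
  dplyr::bind_cols(out, tibble::as_tibble(pi))
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Simulate longitudinal composite trajectories
#'
#' Generates visit-level outcomes. On the transformed scale, subject `i` of
#' class `g` at time `t` has mean `beta_g0 + B(t) beta_g + x' gamma + b_i`
#' with `b_i ~ N(0, sigma_b^2)` and residual `N(0, sigma_e^2)` noise; the
#' reported outcome is the inverse Box-Cox transform minus the shift. Visits
#' occur at multiples of the visit interval up to the follow-up horizon;
#' retention between successive visits is geometric with per-year loss
#' `annual_dropout_prob`; the test-version covariate alternates with visit
#' parity. Records whose inverse transform is undefined are dropped with a
#' counted warning.
#'
#' @param baseline Baseline tibble.
#' @param classes Tibble from [assign_latent_class()] (or any tibble with
#'   `subject_id` and `class_true` matching rows of `baseline`).
#' @param params A [sim_params()] object.
#' @return A visit-level tibble (`subject_id`, `time`, `outcome`,
#'   `test_version`, `cdr_global`).
#' @export
simulate_trajectories <- function(baseline, classes, params) {
  stopifnot(inherits(params, "sim_params"))
  lab <- classes$class_true[match(baseline$subject_id, classes$subject_id)]
  if (anyNA(lab)) abort("simulate_trajectories(): classes must cover every subject.")
  n <- nrow(baseline)
  times <- seq(0, params$max_followup_years, by = params$visit_interval_years)
  K <- length(times)

  beta <- trajectory_beta(params)
  gnames <- rownames(beta)
  with_seed(derive_seed(params$seed, 3L), {
    # retention: probability of making each next visit
    r <- (1 - params$annual_dropout_prob)^params$visit_interval_years
    n_vis <- if (params$annual_dropout_prob <= 0) {
      rep(K, n)
    } else {
      pmin(1L + stats::rgeom(n, prob = 1 - r), K)
    }
    b <- rnorm(n, 0, params$sigma_b)

    idx <- rep(seq_len(n), n_vis)
    vk <- unlist(lapply(n_vis, seq_len)) - 1L  # visit index 0-based
    t_ij <- times[vk + 1L]

    B <- natural_spline_basis(
      t_ij, df = params$spline_df,
      boundary_knots = c(0, params$max_followup_years),
      interior_knots = params$interior_knots
    )
    gi <- match(as.character(lab), gnames)[idx]
    mu_class <- beta[gi, 1L] + rowSums(B * beta[gi, -1L, drop = FALSE])

    scale <- covariate_scale_from_model(params$covariate_model)
    gamma <- params$shared_covariate_coefs
    long_covs <- setdiff(names(gamma), "test_version_b")
    X <- covariate_design(baseline, long_covs, scale)[idx, , drop = FALSE]
    tv_b <- as.numeric(vk %% 2L == 1L)
    xg <- drop(X %*% gamma[long_covs]) + tv_b * gamma[["test_version_b"]]

    ystar <- mu_class + xg + b[idx] + rnorm(length(idx), 0, params$sigma_e)
    outcome <- boxcox_inverse(ystar, params$boxcox_lambda, params$boxcox_shift)
    dropped <- is.na(outcome)
    if (any(dropped)) {
      warn(sprintf(
        "simulate_trajectories(): %d record(s) dropped (inverse transform undefined).",
        sum(dropped)
      ))
    }

    # crude CDR-global process: monotone-in-class hazard of a score > 0
    eta_cdr <- c(stable = -3.1, slow = -1.2, fast = 0.1)[as.character(lab)][idx]
    cdr <- ifelse(runif(length(idx)) < stats::plogis(eta_cdr + 0.25 * t_ij), 0.5, 0)

    tibble::tibble(
      subject_id = baseline$subject_id[idx],
      time = t_ij,
      outcome = outcome,
      test_version = ifelse(tv_b == 1, "B", "A"),
      cdr_global = cdr
    )[!dropped, ]
  })
}

# Class-specific spline coefficients implied by the target curve values:
# solve [1, B(curve_times)] beta = boxcox(curve + shift).
trajectory_beta <- function(params) {
  tt <- params$curve_times
  B <- natural_spline_basis(
    tt, df = params$spline_df,
    boundary_knots = c(0, params$max_followup_years),
    interior_knots = params$interior_knots
  )
  D <- cbind(1, B)
  if (nrow(D) != ncol(D)) {
    abort("sim_params(): curve_times must pin exactly spline_df + 1 points per class.")
  }
  tr <- t(apply(params$class_trajectory_curves, 1, function(y) {
    solve(D, boxcox(y, params$boxcox_lambda, params$boxcox_shift))
  }))
  colnames(tr) <- c("(Intercept)", colnames(B))
  tr
}

#' Simulate a complete synthetic cohort
#'
#' Chains [simulate_baseline()], [assign_latent_class()] and
#' [simulate_trajectories()] under sub-seeds derived from `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `cohort_sim` with elements `baseline` (tibble),
#'   `visits` (tibble), `classes` (tibble of true labels and membership
#'   probabilities) and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  baseline <- simulate_baseline(params)
  classes <- assign_latent_class(
    baseline, params$class_membership_coefs,
    seed = params$seed,
    scale = covariate_scale_from_model(params$covariate_model)
  )
  visits <- simulate_trajectories(baseline, classes, params)
  structure(
    list(baseline = baseline, visits = visits, classes = classes, params = params),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d subjects, %d visits, classes: %s (seed %d)\n",
    nrow(x$baseline), nrow(x$visits),
    paste(sprintf("%s %.1f%%", levels(x$classes$class_true),
                  100 * prop.table(table(x$classes$class_true))),
          collapse = ", "),
    x$params$seed
  ))
  invisible(x)
}

#' Read/write simulation parameters as YAML
#'
#' @param params A [sim_params()] object.
#' @param path File path.
#' @return `write_sim_params()` returns `path` invisibly; `read_sim_params()`
#'   returns a [sim_params()] object.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  ser <- unclass(params)
  ser$class_membership_coefs <- mat_to_list(params$class_membership_coefs)
  ser$class_trajectory_curves <- mat_to_list(params$class_trajectory_curves)
  ser$covariate_model$correlation <- mat_to_list(params$covariate_model$correlation)
  # named vectors must serialise as YAML maps, not bare sequences
  ser <- rapply(ser, function(x) {
    if (!is.null(names(x)) && length(x) > 1L) as.list(x) else x
  }, classes = c("numeric", "integer", "character"), how = "replace")
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$class_membership_coefs <- list_to_mat(raw$class_membership_coefs)
  raw$class_trajectory_curves <- list_to_mat(raw$class_trajectory_curves)
  raw$covariate_model$correlation <- list_to_mat(raw$covariate_model$correlation)
  for (nm in c("female_prob")) raw$covariate_model[[nm]] <- unlist(raw$covariate_model[[nm]])
  raw$covariate_model$apoe4_prob <- unlist(raw$covariate_model$apoe4_prob)
  for (nm in c("ptau217", "amyloid", "tau_pet")) {
    raw$covariate_model[[nm]] <- lapply(raw$covariate_model[[nm]], unlist)
  }
  raw$shared_covariate_coefs <- unlist(raw$shared_covariate_coefs)
  do.call(sim_params, raw[setdiff(names(raw), character(0))])
}

mat_to_list <- function(m) {
  list(values = as.numeric(t(m)), rownames = rownames(m), colnames = colnames(m))
}

list_to_mat <- function(l) {
  m <- matrix(unlist(l$values), nrow = length(l$rownames), byrow = TRUE)
  dimnames(m) <- list(unlist(l$rownames), unlist(l$colnames))
  m
}
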