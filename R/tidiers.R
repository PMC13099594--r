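# broom-style tidiers ----------------------------------------------------------

#' Tidy a fitted latent-class mixed model
#'
#' Returns a coefficient table. Membership terms are multinomial log-odds
#' against the reference (stable) class; with `scale = "sd"` continuous
#' covariates are per internal-SD (so `exp(estimate)` is an odds ratio per
#' SD), with `scale = "raw"` they are per original covariate unit. Wald
#' standard errors come from the observed information at the optimum.
#'
#' @param x An `lcmm_fit`.
#' @param effects Which submodel: `"membership"`, `"longitudinal"` (shared
#'   covariate effects on the transformed outcome) or `"trajectory"`
#'   (class-specific spline coefficients).
#' @param scale `"sd"` (internally standardised) or `"raw"`.
#' @param conf_level Wald confidence level.
#' @param ... Unused.
#' @return A tibble with `term`, `class` (membership/trajectory), `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, and `odds.ratio` for membership
#'   terms.
#' @method tidy lcmm_fit
#' @export
tidy.lcmm_fit <- function(x, effects = c("membership", "longitudinal", "trajectory"),
                          scale = c("sd", "raw"), conf_level = 0.95, ...) {
  effects <- match.arg(effects)
  scale <- match.arg(scale)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_of <- function(names) {
    if (is.null(x$vcov)) return(rep(NA_real_, length(names)))
    i <- match(names, colnames(x$vcov))
    out <- rep(NA_real_, length(names))
    ok <- !is.na(i)
    out[ok] <- sqrt(pmax(diag(x$vcov)[i[ok]], 0))
    out
  }
  rescale <- function(term, est, se) {
    if (scale == "sd") return(list(est = est, se = se))
    s <- vapply(term, function(tm) {
      if (tm %in% names(x$scaling)) x$scaling[[tm]][["sd"]] else 1
    }, numeric(1))
    list(est = est / s, se = se / s)
  }
  if (effects == "membership") {
    xi <- x$params$xi
    if (!nrow(xi)) return(tibble::tibble())
    out <- purrr::map_dfr(rownames(xi), function(cl) {
      tibble::tibble(class = cl, term = colnames(xi), estimate = xi[cl, ])
    })
    vnames <- paste0("xi[", out$class, ",", out$term, "]")
    se <- if (x$params$reference == 1L) se_of(vnames) else rep(NA_real_, nrow(out))
    rs <- rescale(out$term, out$estimate, se)
    out$estimate <- rs$est; out$std.error <- rs$se
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
    out$odds.ratio <- exp(out$estimate)
    out
  } else if (effects == "longitudinal") {
    gm <- x$params$gamma
    if (!length(gm)) return(tibble::tibble())
    se <- se_of(paste0("gamma[", names(gm), "]"))
    rs <- rescale(names(gm), unname(gm), se)
    tibble::tibble(
      term = names(gm), estimate = rs$est, std.error = rs$se,
      conf.low = rs$est - z * rs$se, conf.high = rs$est + z * rs$se
    )
  } else {
    beta <- x$params$beta
    purrr::map_dfr(rownames(beta), function(cl) {
      tibble::tibble(class = cl, term = colnames(beta), estimate = beta[cl, ],
                     std.error = se_of(paste0("beta[", cl, ",", colnames(beta), "]")))
    })
  }
}

#' Glance at a fitted latent-class mixed model
#'
#' @param x An `lcmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit summaries.
#' @method glance lcmm_fit
#' @export
glance.lcmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, bic = x$bic, icl = x$icl,
    n_params = x$n_params, n_subjects = x$n_subjects, n_obs = x$n_obs,
    n_classes = x$spec$n_classes, spline_df = x$spec$spline_df,
    lambda = x$params$lambda, sigma_b = x$params$sigma_b,
    sigma_e = x$params$sigma_e,
    mean_max_posterior = mean(x$assignment$max_posterior),
    converged = x$convergence$code == 0
  )
}

#' @method tidy pr_curve
#' @export
tidy.pr_curve <- function(x, ...) x$points

#' @method glance pr_curve
#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(auprc = x$auprc, prevalence = x$prevalence,
                 n_thresholds = nrow(x$points))
}

#' @method tidy lcmm_selection
#' @export
tidy.lcmm_selection <- function(x, ...) x$table

#' @method tidy tree_tuning
#' @export
tidy.tree_tuning <- function(x, ...) x$table

#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics, names_from = "metric",
                             values_from = "value")
  dplyr::bind_cols(wide, tibble::tibble(
    accuracy_ci_low = x$accuracy_ci[1], accuracy_ci_high = x$accuracy_ci[2],
    k = x$k, n_failed_folds = length(x$failed_folds)
  ))
}

# -- plotting -----------------------------------------------------------------

#' Model-implied mean class trajectories
#'
#' Plots each latent class's model-implied mean outcome trajectory on the raw
#' composite scale (covariate effects at the sample mean, random intercept at
#' zero).
#'
#' @param object An `lcmm_fit`.
#' @param times Time grid; default 100 points over the boundary span.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcmm_fit
#' @export
autoplot.lcmm_fit <- function(object, times = NULL, ...) {
  bk <- object$boundary_knots
  times <- times %||% seq(bk[1], bk[2], length.out = 100)
  B <- natural_spline_basis(times, object$spec$spline_df, bk,
                            interior_knots = object$interior_knots)
  beta <- object$params$beta
  df <- purrr::map_dfr(rownames(beta), function(cl) {
    ystar <- beta[cl, 1L] + drop(B %*% beta[cl, -1L])
    tibble::tibble(class = cl, time = times,
                   outcome = boxcox_inverse(ystar, object$params$lambda,
                                            object$params$shift))
  })
  df$class <- factor(df$class, levels = rownames(beta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$outcome,
                                   colour = .data$class)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Years since baseline", y = "Cognitive composite",
                  colour = "Latent class") +
    ggplot2::theme_minimal()
}

#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = object$prevalence, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Precision-recall curve (AUPRC %.3f)", object$auprc),
      x = "Recall", y = "Precision"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- purrr::imap_dfr(object$curves, function(cv, nm) {
    dplyr::mutate(cv$points, curve = sprintf("%s (AUPRC %.2f)", nm, cv$auprc))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::facet_wrap(~curve) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of simulated trajectories by class
#'
#' @param cohort A `cohort_sim`.
#' @param max_subjects Subsample size for legibility.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort, max_subjects = 300) {
  cl <- cohort$classes
  ids <- cl$subject_id
  if (length(ids) > max_subjects) {
    ids <- with_seed(1L, sample(ids, max_subjects))
  }
  df <- cohort$visits[cohort$visits$subject_id %in% ids, ]
  df$class <- cl$class_true[match(df$subject_id, cl$subject_id)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$outcome,
                                   group = .data$subject_id,
                                   colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "Years since baseline", y = "Cognitive composite",
                  colour = "Latent class") +
    ggplot2::theme_minimal()
}
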