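# Latent-class mixed-effects model --------------------------------------------
#
# Two linked submodels. The longitudinal submodel gives each latent class its
# own mean trajectory of the Box-Cox-transformed composite: a class intercept
# plus class-specific natural-cubic-spline time effects, shared baseline
# covariate effects, a subject-level random intercept and Gaussian residuals.
# Marginalising the random intercept gives a compound-symmetry multivariate
# normal per subject and class. The membership submodel is a multinomial
# logistic model of baseline covariates. The observed-data log-likelihood is
#
#   sum_i log sum_g pi_ig N(y*_i; mu_ig, sigma_e^2 I + sigma_b^2 J)
#     + sum_ij (lambda - 1) log(y_ij + shift)
#
# maximised by multi-start BFGS with an analytic gradient on the unconstrained
# scale (log sigma_b, log sigma_e).

.LONG_COVARIATES <- c("arm_active", "ptau217", "amyloid", "apoe4", "sex_female",
                      "age", "education", "hipp_atrophy", "test_version_b")
.MEMB_COVARIATES <- setdiff(.LONG_COVARIATES, "test_version_b")
.CONTINUOUS_COVARIATES <- c("ptau217", "amyloid", "age", "education",
                            "hipp_atrophy", "tau_pet")

#' Specify a latent-class mixed-effects model
#'
#' @param n_classes Number of latent classes G (1, 2 or 3).
#' @param spline_df Degrees of freedom of the natural cubic spline time basis
#'   (1, 2 or 3); interior knots at the median (df = 2) or tertiles (df = 3)
#'   of the observation times, boundary knots at baseline and the maximum
#'   observed time unless overridden.
#' @param longitudinal_covariates Covariates with effects on the transformed
#'   outcome, shared across classes.
#' @param membership_covariates Covariates of the multinomial membership
#'   submodel (the longitudinal set minus the test-version indicator by
#'   default).
#' @param lambda Box-Cox exponent: a number (default 1, i.e. no
#'   transformation beyond the shift), or `"profile"` to select it from the
#'   pooled outcomes by [select_lambda()] before fitting. Automatic
#'   pre-selection is not the default because on strongly mixed cohorts the
#'   pooled-marginal normality criterion is boundary-attracted: the skew it
#'   removes reflects the class structure itself, and fitting on such an
#'   aggressively convex scale can collapse the class solution (see the
#'   methods vignette).
#' @param shift Box-Cox offset; `NULL` uses `1 - min(outcome)` so the smallest
#'   shifted outcome is exactly 1.
#' @param boundary_knots,interior_knots Optional explicit spline knots.
#' @param include_tau_pet Add a tau-PET composite to both covariate lists.
#' @param standardize Z-score continuous covariates internally (coefficients
#'   are then per SD; raw-scale coefficients are reported by [tidy()]).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(n_classes = 3, spline_df = 2)
model_spec <- function(n_classes = 3,
                       spline_df = 2,
                       longitudinal_covariates = .LONG_COVARIATES,
                       membership_covariates = .MEMB_COVARIATES,
                       lambda = 1,
                       shift = NULL,
                       boundary_knots = NULL,
                       interior_knots = NULL,
                       include_tau_pet = FALSE,
                       standardize = TRUE) {
  if (!n_classes %in% 1:3) abort("model_spec(): n_classes must be 1, 2 or 3.")
  if (!spline_df %in% 1:3) abort("model_spec(): spline_df must be 1, 2 or 3.")
  if (isTRUE(include_tau_pet)) {
    longitudinal_covariates <- union(longitudinal_covariates, "tau_pet")
    membership_covariates <- union(membership_covariates, "tau_pet")
  }
  extra <- setdiff(membership_covariates, union(longitudinal_covariates, character(0)))
  if (length(extra)) {
    abort(sprintf("model_spec(): membership covariates not in longitudinal set: %s",
                  paste(extra, collapse = ", ")))
  }
  structure(list(
    n_classes = as.integer(n_classes),
    spline_df = as.integer(spline_df),
    longitudinal_covariates = longitudinal_covariates,
    membership_covariates = membership_covariates,
    lambda = lambda,
    shift = shift,
    boundary_knots = boundary_knots,
    interior_knots = interior_knots,
    include_tau_pet = isTRUE(include_tau_pet),
    standardize = isTRUE(standardize)
  ), class = "model_spec")
}

class_labels_for <- function(G) {
  switch(as.character(G),
    "1" = "all",
    "2" = c("stable", "decliner"),
    "3" = c("stable", "slow", "fast"),
    paste0("class", seq_len(G))
  )
}

# Assemble design matrices, transform the outcome, and record scaling/knots.
lcmm_prepare <- function(visits, baseline = NULL, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  visits <- dplyr::arrange(tibble::as_tibble(visits), .data$subject_id, .data$time)
  if (any(!is.finite(visits$outcome)) || any(!is.finite(visits$time))) {
    bad <- which(!is.finite(visits$outcome) | !is.finite(visits$time))
    abort(sprintf("Non-finite outcome/time at visit row(s) %s.",
                  paste(head(bad, 5L), collapse = ", ")))
  }

  covs_l <- spec$longitudinal_covariates
  covs_m <- spec$membership_covariates
  base_covs <- setdiff(union(covs_l, covs_m), "test_version_b")

  n_excluded <- 0L
  if (length(base_covs)) {
    if (is.null(baseline)) abort("lcmm_prepare(): baseline table required for the requested covariates.")
    baseline <- tibble::as_tibble(baseline)
    need <- intersect(c("age", "education", "ptau217", "amyloid", "hipp_atrophy",
                        "tau_pet", "arm", "sex", "apoe4"), names(baseline))
    used <- unique(c(
      intersect(base_covs, names(baseline)),
      if ("arm_active" %in% base_covs) "arm",
      if ("sex_female" %in% base_covs) "sex",
      if ("apoe4" %in% base_covs) "apoe4"
    ))
    cc <- stats::complete.cases(baseline[, intersect(used, names(baseline)), drop = FALSE])
    n_excluded <- sum(!cc)
    baseline <- baseline[cc, ]
    visits <- visits[visits$subject_id %in% baseline$subject_id, ]
  } else if (is.null(baseline)) {
    baseline <- tibble::tibble(subject_id = unique(visits$subject_id))
  }
  baseline <- baseline[baseline$subject_id %in% visits$subject_id, ]
  baseline <- dplyr::arrange(baseline, .data$subject_id)

  subj <- baseline$subject_id
  si <- match(visits$subject_id, subj)
  if (anyNA(si)) abort("lcmm_prepare(): visits contain subjects missing from the baseline table.")
  ord <- order(si, visits$time)
  visits <- visits[ord, ]
  si <- si[ord]
  ni <- tabulate(si, nbins = length(subj))
  if (any(ni == 0L)) {
    keep <- ni > 0L
    baseline <- baseline[keep, ]
    subj <- baseline$subject_id
    si <- match(visits$subject_id, subj)
    ni <- tabulate(si, nbins = length(subj))
  }

  y <- visits$outcome
  shift <- if (is.null(spec$shift)) 1 - min(y) else spec$shift
  lambda <- spec$lambda
  lambda_profile <- NULL
  if (identical(lambda, "profile")) {
    sel <- select_lambda(y, shift = shift)
    lambda <- sel$lambda
    lambda_profile <- sel$profile
  }
  ystar <- boxcox(y, lambda, shift)
  log_jac <- sum(boxcox_log_jacobian(y, lambda, shift))

  bk <- spec$boundary_knots %||% c(min(0, min(visits$time)), max(visits$time))
  B <- natural_spline_basis(visits$time, spec$spline_df, bk,
                            interior_knots = spec$interior_knots,
                            knot_times = visits$time)

  scaling <- list()
  if (spec$standardize) {
    for (v in intersect(.CONTINUOUS_COVARIATES, base_covs)) {
      scaling[[v]] <- c(mean = mean(baseline[[v]]), sd = stats::sd(baseline[[v]]))
    }
  }
  X <- if (length(covs_l)) {
    bl_part <- covariate_design(baseline, setdiff(covs_l, "test_version_b"), scaling)
    Xm <- bl_part[si, , drop = FALSE]
    if ("test_version_b" %in% covs_l) {
      tv <- as.numeric(visits$test_version == "B")
      Xm <- cbind(Xm, test_version_b = tv)[, covs_l, drop = FALSE]
    }
    Xm
  } else {
    matrix(0, nrow(visits), 0)
  }
  W <- cbind(`(Intercept)` = 1,
             if (length(covs_m)) covariate_design(baseline, covs_m, scaling))
  colnames(W) <- c("(Intercept)", covs_m)

  list(
    visits = visits, baseline = baseline, subjects = subj,
    si = si, ni = ni, y = y, ystar = ystar,
    lambda = lambda, shift = shift, log_jac = log_jac,
    lambda_profile = lambda_profile,
    B = B, X = X, W = W, scaling = scaling,
    boundary_knots = attr(B, "boundary_knots"),
    interior_knots = attr(B, "interior_knots"),
    n_excluded = n_excluded, spec = spec
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- parameter vector packing -------------------------------------------------

pack_theta <- function(beta, gamma, xi, sigma_b, sigma_e) {
  c(as.vector(beta), gamma, as.vector(xi),
    log(max(sigma_b, 1e-8)), log(sigma_e))
}

unpack_theta <- function(theta, G, nb, p, qm) {
  i <- 0L
  beta <- matrix(theta[seq_len(G * nb)], G, nb); i <- G * nb
  gamma <- theta[i + seq_len(p)]; i <- i + p
  xi <- matrix(theta[i + seq_len((G - 1L) * qm)], max(G - 1L, 0L), qm)
  i <- i + (G - 1L) * qm
  list(beta = beta, gamma = gamma, xi = xi,
       log_sb = theta[i + 1L], log_se = theta[i + 2L])
}

# Core: mixture log-likelihood, per-subject posteriors, analytic gradient.
lcmm_core_eval <- function(theta, dat, G, want_grad = FALSE, want_tau = FALSE) {
  nb <- ncol(dat$B) + 1L
  p <- ncol(dat$X)
  qm <- ncol(dat$W)
  pr <- unpack_theta(theta, G, nb, p, qm)
  sb <- exp(min(max(pr$log_sb, -12), 12))
  se <- exp(min(max(pr$log_se, -12), 12))
  a <- se^2; b2 <- sb^2
  ni <- dat$ni
  nsub <- length(ni)

  f <- if (p) drop(dat$X %*% pr$gamma) else 0
  Bm <- dat$B
  R <- matrix(0, length(dat$ystar), G)
  for (g in seq_len(G)) {
    R[, g] <- dat$ystar - (pr$beta[g, 1L] +
      (if (nb > 1L) drop(Bm %*% pr$beta[g, -1L]) else 0) + f)
  }
  S <- rowsum(R, dat$si)
  Q <- rowsum(R * R, dat$si)
  den <- a + ni * b2
  ci <- b2 / (a * den)
  quad <- Q / a - ci * S^2
  logdet <- (ni - 1) * log(a) + log(den)
  logphi <- -0.5 * (ni * log(2 * pi) + logdet + quad)

  eta <- matrix(0, nsub, G)
  if (G > 1L) eta[, -1L] <- dat$W %*% t(pr$xi)
  mx <- do.call(pmax, c(as.data.frame(eta), list(0)))
  logpi <- eta - (mx + log(rowSums(exp(eta - mx))))

  lw <- logpi + logphi
  m <- do.call(pmax, as.data.frame(lw))
  lse <- m + log(rowSums(exp(lw - m)))
  ll <- sum(lse) + dat$log_jac

  out <- list(loglik = ll, sigma_b = sb, sigma_e = se)
  if (!(want_grad || want_tau)) return(out)

  tau <- exp(lw - lse)
  if (want_tau) {
    out$tau <- tau
    out$pi <- exp(logpi)
    out$logphi <- logphi
  }
  if (want_grad) {
    tau_obs <- tau[dat$si, , drop = FALSE]
    cS <- (ci * S)[dat$si, , drop = FALSE]
    Wobs <- tau_obs * (R / a - cS)           # tau_ig * (Sigma^-1 r)_j
    gbeta <- matrix(0, G, nb)
    gbeta[, 1L] <- colSums(Wobs)
    if (nb > 1L) gbeta[, -1L] <- t(Wobs) %*% Bm
    ggamma <- if (p) colSums(dat$X * rowSums(Wobs)) else numeric(0)
    gxi <- if (G > 1L) {
      pi_full <- exp(logpi)
      t(tau[, -1L, drop = FALSE] - pi_full[, -1L, drop = FALSE]) %*% dat$W
    } else {
      matrix(0, 0L, qm)
    }
    # variance components
    sumU2 <- Q / a^2 - 2 * ci * S^2 / a + ni * ci^2 * S^2
    trSinv <- ni / a - ni * ci
    dlda <- 0.5 * (sumU2 - trSinv)           # d logphi / d sigma_e^2
    dldb <- 0.5 * (S^2 / den^2 - ni / den)   # d logphi / d sigma_b^2
    g_lse <- sum(tau * dlda) * 2 * a
    g_lsb <- sum(tau * dldb) * 2 * b2
    out$grad <- c(as.vector(gbeta), ggamma, as.vector(gxi), g_lsb, g_lse)
  }
  out
}

#' Observed-data log-likelihood of a latent-class mixed model
#'
#' Evaluates the mixture log-likelihood (including the Box-Cox Jacobian
#' correction) at user-supplied parameter values.
#'
#' @param params An `lcmm_params` list with elements `beta` (G x (df + 1)
#'   matrix: class intercept then spline coefficients), `gamma` (shared
#'   covariate effects, may be empty), `xi` ((G - 1) x (1 + q) membership
#'   coefficients relative to the reference class), `sigma_b`, `sigma_e`, and
#'   optionally `lambda`/`shift` overriding the spec.
#' @param visits Visit-level data (`subject_id`, `time`, `outcome`,
#'   `test_version` when used as a covariate).
#' @param baseline Baseline covariate table, or `NULL` when the spec uses no
#'   covariates.
#' @param spec A [model_spec()].
#' @return The scalar log-likelihood.
#' @export
lcmm_loglik <- function(params, visits, baseline = NULL, spec = model_spec()) {
  if (!is.null(params$lambda)) spec$lambda <- params$lambda
  if (!is.null(params$shift)) spec$shift <- params$shift
  dat <- lcmm_prepare(visits, baseline, spec)
  G <- spec$n_classes
  if (params$sigma_e <= 0) abort("lcmm_loglik(): sigma_e must be > 0.")
  theta <- pack_theta(params$beta, params$gamma %||% numeric(ncol(dat$X)),
                      params$xi %||% matrix(0, G - 1L, ncol(dat$W)),
                      params$sigma_b, params$sigma_e)
  lcmm_core_eval(theta, dat, G)$loglik
}

# -- initialisation -----------------------------------------------------------

fit_single_class <- function(dat) {
  nb <- ncol(dat$B) + 1L
  D <- cbind(1, dat$B, dat$X)
  ols <- stats::lm.fit(D, dat$ystar)
  res <- ols$residuals
  mres <- rowsum(res, dat$si) / dat$ni
  sb0 <- max(stats::sd(mres), 0.05)
  se0 <- max(sqrt(max(mean(res^2) - sb0^2, 0.01)), 0.05)
  beta <- matrix(ols$coefficients[seq_len(nb)], 1L, nb)
  gamma <- if (ncol(dat$X)) ols$coefficients[-seq_len(nb)] else numeric(0)
  theta0 <- pack_theta(beta, gamma, matrix(0, 0L, ncol(dat$W)), sb0, se0)
  opt <- optim(theta0,
    fn = function(th) -lcmm_core_eval(th, dat, 1L)$loglik,
    gr = function(th) -lcmm_core_eval(th, dat, 1L, want_grad = TRUE)$grad,
    method = "BFGS", control = list(maxit = 300, reltol = 1e-12)
  )
  pr <- unpack_theta(opt$par, 1L, nb, ncol(dat$X), ncol(dat$W))
  list(theta = opt$par, loglik = -opt$value, beta = pr$beta, gamma = pr$gamma,
       sigma_b = exp(pr$log_sb), sigma_e = exp(pr$log_se))
}

# Start 1: split subjects by OLS outcome-slope quantiles; class means refit
# within groups around the single-class covariate fit.
initial_theta <- function(dat, G, base1) {
  nb <- ncol(dat$B) + 1L
  if (G == 1L) return(base1$theta)
  t_c <- dat$visits$time - mean(dat$visits$time)
  num <- rowsum(t_c * dat$ystar, dat$si) -
    rowsum(t_c, dat$si) * rowsum(dat$ystar, dat$si) / dat$ni
  den <- rowsum(t_c * t_c, dat$si) - rowsum(t_c, dat$si)^2 / dat$ni
  slope <- ifelse(den > 1e-10, num / den, 0)
  qs <- stats::quantile(slope, probs = seq(0, 1, length.out = G + 1L),
                        names = FALSE, type = 7)
  qs[1] <- -Inf; qs[G + 1L] <- Inf
  grp <- cut(slope, breaks = qs, labels = FALSE, include.lowest = TRUE)
  grp <- (G + 1L) - grp  # steepest decline last
  resid_cov <- dat$ystar - (if (ncol(dat$X)) drop(dat$X %*% base1$gamma) else 0)
  beta <- matrix(0, G, nb)
  D <- cbind(1, dat$B)
  for (g in seq_len(G)) {
    rows <- grp[dat$si] == g
    beta[g, ] <- if (sum(rows) > nb) {
      stats::lm.fit(D[rows, , drop = FALSE], resid_cov[rows])$coefficients
    } else {
      c(mean(resid_cov), rep(0, nb - 1L))
    }
  }
  shares <- pmax(tabulate(grp, G) / length(grp), 1e-3)
  xi <- matrix(0, G - 1L, ncol(dat$W))
  xi[, 1L] <- log(shares[-1L] / shares[1L])
  pack_theta(beta, base1$gamma, xi, max(base1$sigma_b, 0.05),
             max(0.8 * base1$sigma_e, 0.05))
}

perturb_theta <- function(theta, G, nb, p, qm, seed) {
  with_seed(seed, {
    pr <- unpack_theta(theta, G, nb, p, qm)
    pr$beta <- pr$beta + matrix(rnorm(length(pr$beta), 0, 0.5), nrow(pr$beta))
    if (G > 1L) pr$xi[, 1L] <- pr$xi[, 1L] + rnorm(G - 1L, 0, 0.5)
    pack_theta(pr$beta, pr$gamma, pr$xi, exp(pr$log_sb) * exp(rnorm(1, 0, 0.2)),
               exp(pr$log_se) * exp(rnorm(1, 0, 0.2)))
  })
}

# -- fitting ------------------------------------------------------------------

#' Fit a latent-class mixed-effects model
#'
#' Maximises the observed-data log-likelihood by quasi-Newton (BFGS with an
#' analytic gradient) on an unconstrained parameterisation, with a multi-start
#' strategy: the first start splits subjects by outcome-slope quantiles around
#' a single-class fit; the remaining starts perturb it with seed-derived
#' noise. After fitting, classes are relabelled by descending model-implied
#' mean trajectory at the last boundary knot (the stable class first), and
#' membership coefficients are re-expressed against the class with the
#' largest fitted share as reference.
#'
#' @param visits Visit-level tibble (`subject_id`, `time`, `outcome`,
#'   `test_version`).
#' @param baseline Baseline covariate tibble (one row per subject), or `NULL`
#'   for covariate-free specs.
#' @param spec A [model_spec()].
#' @param n_starts Number of optimisation starts.
#' @param seed Integer seed controlling start perturbations.
#' @param init Optional `lcmm_params` used as the first start (e.g. a
#'   full-data fit when refitting on cross-validation folds); remaining
#'   starts perturb it.
#' @return An object of class `lcmm_fit` with the fitted `params`
#'   (`lambda`, `shift`, `beta`, `gamma`, `xi`, `sigma_b`, `sigma_e`),
#'   `loglik`, `n_params`, `bic`, `icl`, the posterior probability matrix,
#'   MAP `assignment` tibble, and convergence diagnostics.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(n_subjects = 150, seed = 7))
#' fit <- fit_lcmm(cohort$visits, cohort$baseline,
#'                 model_spec(n_classes = 2, spline_df = 1), n_starts = 1)
#' glance(fit)
fit_lcmm <- function(visits, baseline = NULL, spec = model_spec(),
                     n_starts = 3, seed = 1L, init = NULL) {
  dat <- lcmm_prepare(visits, baseline, spec)
  G <- spec$n_classes
  nb <- ncol(dat$B) + 1L
  p <- ncol(dat$X)
  qm <- ncol(dat$W)
  n_par <- G * nb + p + (G - 1L) * qm + 2L
  if (sum(dat$ni) < n_par) {
    abort(sprintf("fit_lcmm(): %d observations cannot identify %d parameters.",
                  sum(dat$ni), n_par))
  }

  if (G == 1L) n_starts <- 1L  # single-class deviance has no label modes
  th0 <- if (!is.null(init)) {
    ref <- init$reference %||% 1L
    eta_full <- matrix(0, G, qm)
    if (G > 1L) eta_full[setdiff(seq_len(G), ref), ] <- init$xi
    eta_rel <- sweep(eta_full, 2L, eta_full[1L, ])
    pack_theta(init$beta, init$gamma %||% numeric(p),
               eta_rel[-1L, , drop = FALSE], init$sigma_b, init$sigma_e)
  } else {
    initial_theta(dat, G, fit_single_class(dat))
  }
  starts <- vector("list", n_starts)
  starts[[1L]] <- th0
  if (n_starts > 1L) {
    for (s in 2:n_starts) {
      starts[[s]] <- perturb_theta(th0, G, nb, p, qm, derive_seed(seed, 100L + s))
    }
  }

  runs <- lapply(seq_along(starts), function(s) {
    tryCatch({
      opt <- optim(starts[[s]],
        fn = function(th) -lcmm_core_eval(th, dat, G)$loglik,
        gr = function(th) -lcmm_core_eval(th, dat, G, want_grad = TRUE)$grad,
        method = "BFGS", control = list(maxit = 500, reltol = 1e-10)
      )
      gnorm <- max(abs(lcmm_core_eval(opt$par, dat, G, want_grad = TRUE)$grad))
      if (gnorm > 1e-4 && opt$convergence == 0) {
        opt2 <- optim(opt$par,
          fn = function(th) -lcmm_core_eval(th, dat, G)$loglik,
          gr = function(th) -lcmm_core_eval(th, dat, G, want_grad = TRUE)$grad,
          method = "BFGS", control = list(maxit = 500, reltol = 1e-12)
        )
        if (opt2$value <= opt$value) opt <- opt2
        gnorm <- max(abs(lcmm_core_eval(opt$par, dat, G, want_grad = TRUE)$grad))
      }
      list(par = opt$par, loglik = -opt$value, counts = opt$counts,
           code = opt$convergence, gnorm = gnorm, error = NA_character_)
    }, error = function(e) list(par = NULL, loglik = -Inf, counts = c(0, 0),
                                code = 99L, gnorm = NA_real_,
                                error = conditionMessage(e)))
  })
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) {
    abort(paste0("fit_lcmm(): no start converged. Per-start diagnostics: ",
                 paste(vapply(runs, function(r) r$error %||% "ok", character(1)),
                       collapse = " | ")))
  }
  best_i <- which.max(lls)
  best <- runs[[best_i]]
  pr <- unpack_theta(best$par, G, nb, p, qm)
  sb <- exp(pr$log_sb); se <- exp(pr$log_se)

  # relabel classes by trajectory value at the last boundary knot, descending
  Bend <- natural_spline_basis(dat$boundary_knots[2], spec$spline_df,
                               dat$boundary_knots,
                               interior_knots = dat$interior_knots)
  v_end <- pr$beta[, 1L] + if (nb > 1L) drop(pr$beta[, -1L, drop = FALSE] %*% t(Bend)) else 0
  perm <- order(v_end, decreasing = TRUE)
  beta <- pr$beta[perm, , drop = FALSE]
  eta_full <- rbind(0, pr$xi)[perm, , drop = FALSE]

  theta_perm <- pack_theta(beta, pr$gamma,
                           sweep(eta_full[-1L, , drop = FALSE], 2L, eta_full[1L, ]),
                           sb, se)
  ev <- lcmm_core_eval(theta_perm, dat, G, want_tau = TRUE)
  tau <- ev$tau
  shares <- colMeans(tau)
  ref <- which.max(shares)
  eta_ref <- sweep(eta_full, 2L, eta_full[ref, ])
  labels <- class_labels_for(G)
  xi <- eta_ref[-ref, , drop = FALSE]
  dimnames(xi) <- list(labels[-ref], colnames(dat$W))
  dimnames(beta) <- list(labels, c("(Intercept)", colnames(dat$B)))
  gamma <- setNames(pr$gamma, colnames(dat$X))

  colnames(tau) <- labels
  map <- max.col(tau, ties.method = "first")
  entropy <- -sum(tau[tau > 0] * log(tau[tau > 0]))
  loglik <- ev$loglik
  nsub <- length(dat$subjects)
  bic <- -2 * loglik + n_par * log(nsub)
  icl <- bic + 2 * entropy

  # observed-information covariance (in the class-1-reference packing)
  vcov <- tryCatch({
    H <- optimHess(theta_perm,
      fn = function(th) -lcmm_core_eval(th, dat, G)$loglik,
      gr = function(th) -lcmm_core_eval(th, dat, G, want_grad = TRUE)$grad)
    V <- solve(H)
    nb_names <- c("(Intercept)", colnames(dat$B))
    theta_names <- c(
      as.vector(outer(labels, nb_names, function(a, b) paste0("beta[", a, ",", b, "]"))),
      if (p) paste0("gamma[", colnames(dat$X), "]"),
      if (G > 1L) as.vector(outer(labels[-1L], colnames(dat$W),
                                  function(a, b) paste0("xi[", a, ",", b, "]"))),
      "log_sigma_b", "log_sigma_e"
    )
    dimnames(V) <- list(theta_names, theta_names)
    V
  }, error = function(e) NULL)

  params <- structure(list(
    lambda = dat$lambda, shift = dat$shift,
    beta = beta, gamma = gamma, xi = xi,
    reference = ref, class_labels = labels,
    sigma_b = sb, sigma_e = se
  ), class = "lcmm_params")

  structure(list(
    params = params,
    loglik = loglik, n_params = n_par, bic = bic, icl = icl,
    posterior = tau,
    assignment = tibble::tibble(
      subject_id = dat$subjects,
      class = factor(labels[map], levels = labels),
      max_posterior = tau[cbind(seq_len(nsub), map)]
    ),
    convergence = list(
      n_starts = n_starts, best_start = best_i,
      start_logliks = lls, iterations = unname(best$counts[1L]),
      gradient_norm = best$gnorm, code = best$code,
      sigma_b_boundary = sb < 1e-3 * se,
      seed = seed
    ),
    vcov = vcov,
    scaling = dat$scaling,
    boundary_knots = dat$boundary_knots,
    interior_knots = dat$interior_knots,
    lambda_profile = dat$lambda_profile,
    n_subjects = nsub, n_obs = sum(dat$ni), n_excluded = dat$n_excluded,
    spec = spec
  ), class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lcmm_fit> G=%d, spline df=%d, n=%d subjects (%d visits)\n  loglik %.2f | BIC %.1f | ICL %.1f | lambda %.2f (shift %.2f)\n  sigma_b %.3f, sigma_e %.3f | classes: %s\n",
    x$spec$n_classes, x$spec$spline_df, x$n_subjects, x$n_obs,
    x$loglik, x$bic, x$icl, x$params$lambda, x$params$shift,
    x$params$sigma_b, x$params$sigma_e,
    paste(sprintf("%s %.1f%%", levels(x$assignment$class),
                  100 * prop.table(table(x$assignment$class))), collapse = ", ")
  ))
  invisible(x)
}

#' Posterior class probabilities and MAP assignment
#'
#' Computes `tau_ig = pi_ig phi_ig / sum_l pi_il phi_il` for each subject.
#' Ties in the MAP assignment break toward the lower class index.
#'
#' @param object An `lcmm_fit` (uses its stored data scaling), or an
#'   `lcmm_params` list together with `visits`/`baseline`/`spec`.
#' @param visits,baseline,spec Data and spec when `object` is a parameter
#'   list; ignored for a fitted object unless new data are supplied.
#' @return A list with `tau` (matrix), `assignment` (tibble) and `pi`
#'   (membership-only probabilities).
#' @export
posterior_probs <- function(object, visits = NULL, baseline = NULL, spec = NULL) {
  if (inherits(object, "lcmm_fit") && is.null(visits)) {
    labels <- object$params$class_labels
    tau <- object$posterior
    return(list(tau = tau, assignment = object$assignment, pi = NULL))
  }
  params <- if (inherits(object, "lcmm_fit")) object$params else object
  spec <- spec %||% (if (inherits(object, "lcmm_fit")) object$spec else model_spec())
  spec$lambda <- params$lambda
  spec$shift <- params$shift
  dat <- lcmm_prepare(visits, baseline, spec)
  G <- spec$n_classes
  ref <- params$reference %||% 1L
  eta_full <- matrix(0, G, ncol(dat$W))
  if (G > 1L) eta_full[-ref, ] <- params$xi
  eta_rel <- sweep(eta_full, 2L, eta_full[1L, ])  # pack relative to class 1
  theta <- pack_theta(params$beta, params$gamma %||% numeric(ncol(dat$X)),
                      eta_rel[-1L, , drop = FALSE], params$sigma_b, params$sigma_e)
  ev <- lcmm_core_eval(theta, dat, G, want_tau = TRUE)
  labels <- params$class_labels %||% class_labels_for(G)
  tau <- ev$tau
  colnames(tau) <- labels
  map <- max.col(tau, ties.method = "first")
  list(
    tau = tau,
    assignment = tibble::tibble(
      subject_id = dat$subjects,
      class = factor(labels[map], levels = labels),
      max_posterior = tau[cbind(seq_len(nrow(tau)), map)]
    ),
    pi = ev$pi
  )
}

#' Information criteria of a fitted latent-class model
#'
#' `BIC = -2 loglik + p log(n_subjects)`; `ICL` adds twice the total posterior
#' classification entropy, so `ICL >= BIC` with equality for hard
#' assignments.
#'
#' @param fit An `lcmm_fit`.
#' @return A named list with `bic` and `icl`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "lcmm_fit"))
  list(bic = fit$bic, icl = fit$icl)
}

#' Select the number of classes and spline flexibility
#'
#' Fits every combination of a grid of class counts and spline degrees of
#' freedom and ranks the fits by BIC (ICL reported alongside). The chosen
#' model minimises BIC; the gap to the runner-up is reported.
#'
#' @inheritParams fit_lcmm
#' @param n_classes_grid,spline_df_grid Grid values (defaults 1:3 each).
#' @param keep_fits Keep every fitted model (memory-heavy) rather than only
#'   the best.
#' @return An object of class `lcmm_selection`: a ranked tibble `table`, the
#'   winning `best_fit`, and `delta_bic`/`delta_icl` to the runner-up.
#' @export
model_selection <- function(visits, baseline = NULL, spec = model_spec(),
                            n_classes_grid = 1:3, spline_df_grid = 1:3,
                            n_starts = 2, seed = 1L, keep_fits = FALSE) {
  grid <- expand.grid(n_classes = n_classes_grid, spline_df = spline_df_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- purrr::pmap(grid, function(n_classes, spline_df) {
    sp <- spec
    sp$n_classes <- as.integer(n_classes)
    sp$spline_df <- as.integer(spline_df)
    f <- tryCatch(
      fit_lcmm(visits, baseline, sp, n_starts = n_starts,
               seed = derive_seed(seed, 10L * n_classes + spline_df)),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      tibble::tibble(n_classes = n_classes, spline_df = spline_df,
                     loglik = NA_real_, n_params = NA_integer_,
                     bic = NA_real_, icl = NA_real_, converged = FALSE,
                     message = conditionMessage(f))
    } else {
      fits[[which(grid$n_classes == n_classes & grid$spline_df == spline_df)]] <<- f
      tibble::tibble(n_classes = n_classes, spline_df = spline_df,
                     loglik = f$loglik, n_params = f$n_params,
                     bic = f$bic, icl = f$icl, converged = TRUE,
                     message = NA_character_)
    }
  })
  tab <- dplyr::bind_rows(rows)
  if (all(!tab$converged)) abort("model_selection(): every grid cell failed to fit.")
  ranked <- dplyr::arrange(tab, .data$bic)
  best_row <- ranked[1L, ]
  best_idx <- which(grid$n_classes == best_row$n_classes &
                      grid$spline_df == best_row$spline_df)
  delta_bic <- if (sum(tab$converged) > 1L) ranked$bic[2L] - ranked$bic[1L] else NA_real_
  delta_icl <- if (sum(tab$converged) > 1L) ranked$icl[2L] - ranked$icl[1L] else NA_real_
  structure(list(
    table = tab,
    best = list(n_classes = best_row$n_classes, spline_df = best_row$spline_df),
    best_fit = fits[[best_idx]],
    fits = if (keep_fits) fits else NULL,
    delta_bic = delta_bic, delta_icl = delta_icl
  ), class = "lcmm_selection")
}

#' @export
print.lcmm_selection <- function(x, ...) {
  cat(sprintf("<lcmm_selection> chosen G=%d, df=%d (delta BIC to runner-up %.1f)\n",
              x$best$n_classes, x$best$spline_df, x$delta_bic))
  print(dplyr::arrange(x$table, .data$bic), n = nrow(x$table))
  invisible(x)
}
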