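test_that("single-class likelihood matches the bivariate normal density", {
  visits <- tibble::tibble(subject_id = "a", time = c(0, 1),
                           outcome = c(0, 1), test_version = c("A", "B"))
  spec <- model_spec(n_classes = 1, spline_df = 1,
                     longitudinal_covariates = character(0),
                     membership_covariates = character(0),
                     lambda = 1, shift = 1)
  params <- list(beta = matrix(c(0, 0), 1, 2), gamma = numeric(0),
                 xi = matrix(0, 0, 1), sigma_b = 1, sigma_e = 1)
  # y* = (0, 1), Sigma = [[2, 1], [1, 2]]
  expect_equal(lcmm_loglik(params, visits, NULL, spec),
               -log(2 * pi) - 0.5 * log(3) - 1 / 3, tolerance = 1e-10)
})

test_that("mixture likelihood matches Gauss-Hermite integration", {
  toy <- toy_mixture()
  ll <- lcmm_loglik(toy$params, toy$visits, NULL, toy$spec)

  B <- natural_spline_basis(c(0, 1), 1, c(0, 1))
  ystar <- boxcox(toy$visits$outcome, 1, 5)
  beta <- toy$params$beta
  mu <- lapply(1:2, function(g) beta[g, 1] + drop(B %*% beta[g, 2]))
  pi_g <- c(1, exp(toy$params$xi[1, 1]))
  pi_g <- pi_g / sum(pi_g)
  oracle <- oracle_mixture_loglik(
    y_list = list(ystar[1:2], ystar[3:4]),
    mu_list = list(list(mu[[1]], mu[[2]]), list(mu[[1]], mu[[2]])),
    pi_g = pi_g, sigma_b = 0.8, sigma_e = 0.6
  )
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("likelihood is invariant to label permutation and additive shifts", {
  toy <- toy_mixture()
  ll <- lcmm_loglik(toy$params, toy$visits, NULL, toy$spec)

  # permute the two classes together in (beta, xi)
  perm <- toy$params
  perm$beta <- toy$params$beta[2:1, ]
  perm$xi <- -toy$params$xi
  expect_equal(lcmm_loglik(perm, toy$visits, NULL, toy$spec), ll,
               tolerance = 1e-10)

  # G = 2 with identical class means collapses to the single-class value
  same <- toy$params
  same$beta <- toy$params$beta[c(1, 1), ]
  spec1 <- toy$spec
  spec1$n_classes <- 1L
  p1 <- list(beta = toy$params$beta[1, , drop = FALSE], gamma = numeric(0),
             xi = matrix(0, 0, 1), sigma_b = 0.8, sigma_e = 0.6)
  for (xi_try in c(-2, 0, 1.3)) {
    same$xi <- matrix(xi_try, 1, 1)
    expect_equal(lcmm_loglik(same, toy$visits, NULL, toy$spec),
                 lcmm_loglik(p1, toy$visits, NULL, spec1), tolerance = 1e-10)
  }

  # adding c to the outcomes while raising intercepts by c leaves it unchanged
  shifted <- toy$params
  shifted$beta[, 1] <- shifted$beta[, 1] + 2.5
  v2 <- toy$visits
  v2$outcome <- v2$outcome + 2.5
  expect_equal(lcmm_loglik(shifted, v2, NULL, toy$spec), ll, tolerance = 1e-10)
})

test_that("likelihood is additive over subjects", {
  toy <- toy_mixture()
  v <- toy$visits
  ll_all <- lcmm_loglik(toy$params, v, NULL, toy$spec)
  ll_each <- sum(vapply(unique(v$subject_id), function(id) {
    lcmm_loglik(toy$params, v[v$subject_id == id, ], NULL, toy$spec)
  }, numeric(1)))
  expect_equal(ll_all, ll_each, tolerance = 1e-10)
})

test_that("invalid inputs are rejected with informative errors", {
  toy <- toy_mixture()
  bad <- toy$params
  bad$sigma_e <- 0
  expect_error(lcmm_loglik(bad, toy$visits, NULL, toy$spec), "sigma_e")
  v <- toy$visits
  v$outcome[2] <- NA
  expect_error(lcmm_loglik(toy$params, v, NULL, toy$spec), "row")
})

test_that("G = 1 fit agrees with a mixed-model oracle", {
  skip_if_not_installed("nlme")
  co <- small_cohort(n = 150, seed = 21)
  spec <- model_spec(n_classes = 1, spline_df = 2,
                     longitudinal_covariates = c("sex_female", "education"),
                     membership_covariates = character(0),
                     lambda = 1)
  fit <- fit_lcmm(co$visits, co$baseline, spec, n_starts = 1, seed = 1)

  dat <- cogtraj:::lcmm_prepare(co$visits, co$baseline, spec)
  df <- data.frame(y = dat$ystar, dat$B, dat$X, id = dat$visits$subject_id)
  lme_fit <- nlme::lme(y ~ ns1 + ns2 + sex_female + education,
                       random = ~ 1 | id, data = df, method = "ML")
  expect_equal(fit$loglik, as.numeric(stats::logLik(lme_fit)), tolerance = 1e-4)
})

test_that("fitting recovers a known three-class structure", {
  co <- small_cohort(n = 500, seed = 31)
  fit <- fit_lcmm(co$visits, co$baseline, model_spec(), n_starts = 2, seed = 31)
  truth <- co$classes$class_true[match(fit$assignment$subject_id,
                                       co$classes$subject_id)]
  expect_gt(mean(as.character(fit$assignment$class) == as.character(truth)), 0.85)
  # class mean curves near truth on a grid (transformed scale)
  beta_true <- cogtraj:::trajectory_beta(co$params)
  tt <- seq(0, 7, 0.5)
  Bt <- natural_spline_basis(tt, 2, c(0, 7), interior_knots = 3)
  Bf <- natural_spline_basis(tt, 2, fit$boundary_knots,
                             interior_knots = fit$interior_knots)
  # covariate effects shift the fitted intercepts; compare after centring
  for (g in 1:3) {
    mu_true <- beta_true[g, 1] + drop(Bt %*% beta_true[g, -1])
    mu_fit <- fit$params$beta[g, 1] + drop(Bf %*% fit$params$beta[g, -1])
    shape_err <- (mu_fit - mean(mu_fit)) - (mu_true - mean(mu_true))
    expect_lt(max(abs(shape_err)), 0.45)
  }
  # refit under the same seed reproduces the likelihood exactly
  fit2 <- fit_lcmm(co$visits, co$baseline, model_spec(), n_starts = 2, seed = 31)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("posterior probabilities normalise, collapse and saturate correctly", {
  toy <- toy_mixture()
  po <- posterior_probs(toy$params, toy$visits, NULL, toy$spec)
  expect_equal(unname(rowSums(po$tau)), rep(1, 2), tolerance = 1e-8)

  # identical class densities: tau reduces to the membership prior
  same <- toy$params
  same$beta <- toy$params$beta[c(1, 1), ]
  same$reference <- 1L
  po2 <- posterior_probs(same, toy$visits, NULL, toy$spec)
  expect_equal(unname(po2$tau), unname(po2$pi), tolerance = 1e-10)

  # an outcome far from all but one class mean is assigned with certainty
  far <- toy$params
  far$beta <- matrix(c(4, 24, 0, 0), 2, 2)   # class means 10 residual SDs apart
  far$sigma_b <- 0.1
  v <- tibble::tibble(subject_id = "z", time = c(0, 1),
                      outcome = c(4 - 5, 4 - 5) + c(0.1, -0.1),
                      test_version = "A")
  po3 <- posterior_probs(far, v, NULL, toy$spec)
  expect_gt(po3$tau[1, 1], 0.999)
})

test_that("information criteria satisfy their defining identities", {
  co <- small_cohort(n = 200, seed = 41)
  fit <- fit_lcmm(co$visits, co$baseline,
                  model_spec(n_classes = 2, spline_df = 1), n_starts = 1,
                  seed = 41)
  ic <- information_criteria(fit)
  expect_equal(ic$bic, -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  expect_gte(ic$icl, ic$bic)
  ent <- -sum(fit$posterior[fit$posterior > 0] * log(fit$posterior[fit$posterior > 0]))
  expect_equal(ic$icl, ic$bic + 2 * ent)

  # G = 1: no classification uncertainty, ICL equals BIC
  fit1 <- fit_lcmm(co$visits, co$baseline,
                   model_spec(n_classes = 1, spline_df = 1), seed = 1)
  ic1 <- information_criteria(fit1)
  expect_equal(ic1$icl, ic1$bic)
})

test_that("model selection reports the full grid and ranks by BIC", {
  co <- small_cohort(n = 220, seed = 51)
  sel <- model_selection(co$visits, co$baseline, model_spec(),
                         n_classes_grid = 1:2, spline_df_grid = 1:2,
                         n_starts = 1, seed = 51)
  expect_identical(nrow(sel$table), 4L)
  expect_true(all(c("loglik", "bic", "icl", "converged") %in% names(sel$table)))
  best_bic <- min(sel$table$bic, na.rm = TRUE)
  expect_equal(sel$best_fit$bic, best_bic)
  expect_gte(sel$delta_bic, 0)
})

test_that("mean posterior confidence is high on the calibrated preset", {
  co <- small_cohort(n = 600, seed = 61)
  fit <- fit_lcmm(co$visits, co$baseline, model_spec(), n_starts = 2, seed = 61)
  expect_gte(mean(fit$assignment$max_posterior), 0.9)
})

test_that("selection prefers a single class when the data have no mixture", {
  hits <- vapply(1:5, function(s) {
    xi <- sim_params()$class_membership_coefs
    xi[] <- 0
    xi[, "(Intercept)"] <- -30  # everyone in the stable class
    co <- simulate_cohort(sim_params(n_subjects = 250, seed = 910 + s,
                                     class_membership_coefs = xi))
    sel <- model_selection(co$visits, co$baseline, model_spec(),
                           n_classes_grid = 1:3, spline_df_grid = 1:2,
                           n_starts = 1, seed = s)
    sel$best$n_classes == 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
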