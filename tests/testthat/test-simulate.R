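test_that("baseline covariate moments match the configured model", {
  p <- sim_params(n_subjects = 10000, seed = 1)
  bl <- simulate_baseline(p)
  cm <- p$covariate_model
  se_age <- cm$age$sd / sqrt(nrow(bl))
  expect_lt(abs(mean(bl$age) - cm$age$mean), 3 * se_age)
  se_edu <- cm$education$sd / sqrt(nrow(bl))
  expect_lt(abs(mean(bl$education) - cm$education$mean), 3 * se_edu)
  expect_lt(abs(mean(bl$sex == "female") - cm$female_prob), 3 * 0.005)
  # arm structure
  expect_equal(sum(bl$arm == "negative-observational"),
               round(10000 * p$prop_negative))
})

test_that("boundary arms and determinism contracts hold", {
  p0 <- sim_params(n_subjects = 200, prop_negative = 0, seed = 3)
  expect_false(any(simulate_baseline(p0)$arm == "negative-observational"))

  p <- sim_params(n_subjects = 300, seed = 9)
  expect_identical(simulate_cohort(p)$visits, simulate_cohort(p)$visits)
  expect_identical(simulate_baseline(p), simulate_baseline(p))
})

test_that("non-positive-definite covariate correlation is rejected", {
  cm <- sim_params()$covariate_model
  cm$correlation[1, 2] <- cm$correlation[2, 1] <- 1.2
  expect_error(sim_params(covariate_model = cm), "positive-definite")
})

test_that("class assignment follows the multinomial softmax", {
  p <- sim_params(n_subjects = 6000, seed = 2)
  bl <- simulate_baseline(p)
  # all coefficients zero: uniform thirds
  xi0 <- p$class_membership_coefs
  xi0[] <- 0
  cl <- assign_latent_class(bl, xi0, seed = 5)
  props <- prop.table(table(cl$class_true))
  expect_true(all(abs(props - 1 / 3) < 3 * sqrt(2 / 9 / 6000) + 0.02))

  # saturated intercept forces one class
  xi_sat <- xi0
  xi_sat["fast", "(Intercept)"] <- 20
  cl2 <- assign_latent_class(bl, xi_sat, seed = 5)
  expect_true(all(cl2$class_true == "fast"))
  expect_true(all(cl2$p_fast > 1 - 1e-6))

  # single subject: probabilities equal a hand-evaluated softmax
  one <- bl[1, ]
  xi <- p$class_membership_coefs
  scale <- cogtraj:::covariate_scale_from_model(p$covariate_model)
  W <- cbind(1, cogtraj:::covariate_design(one, setdiff(colnames(xi), "(Intercept)"), scale))
  eta <- c(0, as.numeric(W %*% t(xi)))
  byhand <- exp(eta) / sum(exp(eta))
  got <- as.numeric(assign_latent_class(one, xi, seed = 1, scale = scale)[, c("p_stable", "p_slow", "p_fast")])
  expect_equal(got, byhand, tolerance = 1e-12)
})

test_that("coefficient/covariate name mismatches raise a schema error", {
  p <- sim_params(n_subjects = 20, seed = 1)
  bl <- simulate_baseline(p)
  xi <- p$class_membership_coefs
  colnames(xi)[3] <- "not_a_covariate"
  expect_error(assign_latent_class(bl, xi, seed = 1), "not_a_covariate")
})

test_that("noise-free trajectories trace the class spline curves exactly", {
  p <- sim_params(
    n_subjects = 30, seed = 4, sigma_b = 0, sigma_e = 1e-12,
    shared_covariate_coefs = c(arm_active = 0, ptau217 = 0, amyloid = 0,
                               apoe4 = 0, sex_female = 0, age = 0,
                               education = 0, hipp_atrophy = 0,
                               test_version_b = 0),
    annual_dropout_prob = 0
  )
  co <- simulate_cohort(p)
  beta <- cogtraj:::trajectory_beta(p)
  B <- natural_spline_basis(co$visits$time, p$spline_df,
                            c(0, p$max_followup_years),
                            interior_knots = p$interior_knots)
  g <- match(co$classes$class_true[match(co$visits$subject_id,
                                         co$classes$subject_id)],
             rownames(beta))
  mu <- beta[g, 1] + rowSums(B * beta[g, -1])
  expected <- boxcox_inverse(mu, p$boxcox_lambda, p$boxcox_shift)
  expect_equal(co$visits$outcome, expected, tolerance = 1e-8)
  # no dropout: every subject observed at every scheduled visit
  n_vis <- table(co$visits$subject_id)
  expect_true(all(n_vis == length(seq(0, 7, 0.5))))
  # test version alternates with visit parity
  expect_true(all(co$visits$test_version ==
                    ifelse((co$visits$time / 0.5) %% 2 == 1, "B", "A")))
})

test_that("class frequencies match the analytically averaged softmax", {
  p <- sim_params(n_subjects = 4000, seed = 6)
  bl <- simulate_baseline(p)
  scale <- cogtraj:::covariate_scale_from_model(p$covariate_model)
  xi <- p$class_membership_coefs
  W <- cbind(1, cogtraj:::covariate_design(bl, setdiff(colnames(xi), "(Intercept)"), scale))
  pi_bar <- colMeans(cogtraj:::softmax_rows(cbind(0, W %*% t(xi))))
  cl <- assign_latent_class(bl, xi, seed = 8, scale = scale)
  emp <- as.numeric(prop.table(table(cl$class_true)))
  mc_se <- sqrt(pi_bar * (1 - pi_bar) / nrow(bl))
  expect_true(all(abs(emp - pi_bar) < 3 * mc_se + 1e-6))
})

test_that("stable-class share averages near 77% across seeds", {
  shares <- vapply(1:50, function(s) {
    p <- sim_params(seed = 100 + s)
    bl <- simulate_baseline(p)
    cl <- assign_latent_class(
      bl, p$class_membership_coefs, seed = p$seed,
      scale = cogtraj:::covariate_scale_from_model(p$covariate_model)
    )
    mean(cl$class_true == "stable")
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.77), 0.02)
})

test_that("transformed-scale residuals about the generative mean are Gaussian", {
  pvals <- vapply(1:20, function(s) {
    p <- sim_params(n_subjects = 500, seed = 300 + s)
    co <- simulate_cohort(p)
    beta <- cogtraj:::trajectory_beta(p)
    bl0 <- co$visits[co$visits$time == 0, ]
    g <- match(co$classes$class_true[match(bl0$subject_id,
                                           co$classes$subject_id)],
               rownames(beta))
    scale <- cogtraj:::covariate_scale_from_model(p$covariate_model)
    gamma <- p$shared_covariate_coefs
    X <- cogtraj:::covariate_design(
      co$baseline[match(bl0$subject_id, co$baseline$subject_id), ],
      setdiff(names(gamma), "test_version_b"), scale
    )
    mu <- beta[g, 1] + drop(X %*% gamma[setdiff(names(gamma), "test_version_b")])
    r <- boxcox(bl0$outcome, p$boxcox_lambda, p$boxcox_shift) - mu
    shapiro.test(r)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("parameters survive a YAML round trip", {
  p <- sim_params(n_subjects = 123, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_params(p, path)
  p2 <- read_sim_params(path)
  expect_equal(p2$class_membership_coefs, p$class_membership_coefs)
  expect_equal(p2$covariate_model$correlation, p$covariate_model$correlation)
  # YAML stores 15 significant digits; draws agree to that precision
  expect_equal(simulate_baseline(p2), simulate_baseline(p), tolerance = 1e-12)
})
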