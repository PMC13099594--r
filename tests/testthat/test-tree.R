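test_that("Gini impurity matches its closed form", {
  gini <- cogtraj:::gini_impurity
  expect_equal(gini(c(2, 2)), 0.5)
  expect_equal(gini(c(4, 0)), 0)
  expect_equal(gini(c(3, 1)), 0.375)
})

test_that("perfectly separable data are fit exactly at cp = 0", {
  d <- data.frame(x = c(1:10, 101:110), z = runif(20))
  y <- rep(c("a", "b"), each = 10)
  tr <- grow_tree(d, y, min_leaf = 1, cp = 0)
  expect_equal(mean(predict(tr, d) == y), 1)
  expect_identical(tr$root$split_var, "x")
})

test_that("the first split matches an exhaustive-search oracle", {
  withr::with_seed(5, {
    for (rep in 1:8) {
      d <- data.frame(
        u = round(runif(20), 2),
        v = sample(1:6, 20, replace = TRUE),
        w = round(rnorm(20), 1)
      )
      y <- sample(c("a", "b", "c"), 20, replace = TRUE)
      if (length(unique(y)) < 2) next
      tr <- grow_tree(d, y, min_leaf = 2, cp = 0)
      if (tr$root$leaf) next
      oracle <- oracle_first_split(d, y, min_leaf = 2)
      expect_identical(tr$root$split_var, oracle$var)
      expect_equal(tr$root$threshold, oracle$threshold, tolerance = 1e-10)
    }
  })
})

test_that("single-class input yields a stump with a warning", {
  d <- data.frame(x = 1:30)
  expect_warning(tr <- grow_tree(d, rep("a", 30)), "single-class")
  expect_true(tr$root$leaf)
  expect_identical(nrow(variable_importance(tr)), 0L)
})

test_that("importance shares normalise to 100 and credit the split variables", {
  d <- data.frame(x = c(1:20, 41:60, 81:100), noise = 0)
  y <- rep(c("a", "b", "c"), each = 20)
  tr <- grow_tree(d, y, min_leaf = 5, cp = 0)
  vi <- variable_importance(tr)
  expect_equal(sum(vi$importance), 100, tolerance = 1e-6)
  expect_identical(vi$variable, "x")
  expect_equal(vi$importance, 100, tolerance = 1e-6)
})

test_that("predictions are invariant to monotone predictor rescaling", {
  withr::with_seed(8, {
    d <- data.frame(a = rnorm(200), b = runif(200))
    y <- ifelse(d$a + rnorm(200, 0, 0.5) > 0, "hi", "lo")
    tr1 <- grow_tree(d, y, min_leaf = 10, cp = 0.01)
    d2 <- d
    d2$a <- exp(d$a)  # strictly increasing transform
    tr2 <- grow_tree(d2, y, min_leaf = 10, cp = 0.01)
    expect_identical(predict(tr1, d), predict(tr2, d2))
  })
})

test_that("training accuracy is non-increasing in the complexity parameter", {
  withr::with_seed(9, {
    d <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
    y <- ifelse(d$a + 0.5 * d$b + rnorm(300) > 0, "x", "y")
    accs <- vapply(c(0, 0.001, 0.005, 0.01, 0.02, 0.05, 0.2), function(cp) {
      mean(predict(grow_tree(d, y, min_leaf = 5, cp = cp), d) == y)
    }, numeric(1))
    expect_true(all(diff(accs) <= 1e-12))
  })
})

test_that("tuning reports the grid and collapses pure noise to a stump", {
  withr::with_seed(10, {
    stumps <- vapply(1:10, function(s) {
      d <- data.frame(a = rnorm(300), b = rnorm(300))
      y <- sample(c("u", "v", "w"), 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      tt <- tune_tree(d, y, k = 5, min_leaf = 20, seed = s)
      tt$tree$root$leaf
    }, logical(1))
    expect_gte(mean(stumps), 0.8)
  })
  d <- data.frame(a = rnorm(100))
  y <- rep(c("p", "q"), 50)
  tt <- tune_tree(d, y, cp_grid = c(0, 0.01, 0.05), k = 5, seed = 1)
  expect_identical(nrow(tt$table), 3L)

  # a stump on three classes has balanced accuracy one third
  stump_pred <- factor(rep("u", 90), levels = c("u", "v", "w"))
  truth <- factor(rep(c("u", "v", "w"), each = 30))
  expect_equal(cogtraj:::balanced_accuracy(truth, stump_pred), 1 / 3)
})

test_that("a dominant membership covariate earns the top importance rank", {
  hits <- vapply(1:10, function(s) {
    xi <- sim_params()$class_membership_coefs
    xi[, c("amyloid", "hipp_atrophy", "apoe4", "sex_female", "age",
           "education")] <- xi[, c("amyloid", "hipp_atrophy", "apoe4",
                                   "sex_female", "age", "education")] / 4
    xi[, "ptau217"] <- 2 * max(abs(xi[, c("amyloid", "hipp_atrophy")]))
    p <- sim_params(n_subjects = 800, class_membership_coefs = xi,
                    seed = 700 + s)
    bl <- simulate_baseline(p)
    cl <- assign_latent_class(
      bl, xi, seed = s,
      scale = cogtraj:::covariate_scale_from_model(p$covariate_model)
    )
    d <- as.data.frame(bl[, c("ptau217", "amyloid", "hipp_atrophy", "age",
                              "education")])
    tr <- grow_tree(d, cl$class_true, min_leaf = 20, cp = 0.005)
    vi <- variable_importance(tr)
    nrow(vi) > 0 && vi$variable[1] == "ptau217"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("tree JSON export reproduces the node structure", {
  d <- data.frame(x = c(1:10, 51:60))
  y <- rep(c("a", "b"), each = 10)
  tr <- grow_tree(d, y, min_leaf = 2, cp = 0)
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = FALSE)
  expect_identical(js$split_var, "x")
  expect_false(js$leaf)
  expect_true(js$left$leaf)
  expect_equal(js$n, 20)
})

test_that("grown trees agree with rpart on accuracy for a clean problem", {
  skip_if_not_installed("rpart")
  withr::with_seed(12, {
    d <- data.frame(a = rnorm(400), b = rnorm(400))
    y <- factor(ifelse(d$a > 0.3, "x", ifelse(d$b > 0, "y", "z")))
    ours <- grow_tree(d, y, min_leaf = 20, cp = 0.01)
    rp <- rpart::rpart(y ~ ., data = cbind(d, y = y),
                       control = rpart::rpart.control(minbucket = 20, cp = 0.01))
    acc_ours <- mean(predict(ours, d) == y)
    acc_rp <- mean(predict(rp, d, type = "class") == y)
    expect_lt(abs(acc_ours - acc_rp), 0.05)
  })
})

test_that("cohort-level balanced accuracy sits in the expected band and tau PET adds signal", {
  res <- vapply(1:3, function(s) {
    co <- simulate_cohort(sim_params(seed = 800 + s))
    fit <- fit_lcmm(co$visits, co$baseline, model_spec(), n_starts = 2,
                    seed = 800 + s)
    bl0 <- co$visits[co$visits$time == 0, c("subject_id", "outcome")]
    td <- dplyr::mutate(
      co$baseline,
      pacc_baseline = bl0$outcome[match(.data$subject_id, bl0$subject_id)],
      arm_active = as.numeric(.data$arm == "active"),
      sex_female = as.numeric(.data$sex == "female")
    )[, c("arm_active", "ptau217", "amyloid", "apoe4", "sex_female", "age",
          "education", "hipp_atrophy", "pacc_baseline")]
    labels <- fit$assignment$class[match(co$baseline$subject_id,
                                         fit$assignment$subject_id)]
    tune_tree(td, labels, seed = 800 + s)$cv_balanced_accuracy
  }, numeric(1))
  expect_gte(mean(res), 0.55)
  expect_lte(mean(res), 0.71)

  # a tau-PET covariate that genuinely drives membership raises the tree's
  # balanced accuracy when offered as a predictor
  gain <- vapply(1:3, function(s) {
    co <- simulate_cohort(sim_params(include_tau_pet = TRUE, seed = 900 + s))
    cl <- co$classes$class_true
    base_cols <- c("ptau217", "amyloid", "apoe4", "age", "education",
                   "hipp_atrophy")
    d0 <- as.data.frame(co$baseline[, base_cols])
    d1 <- as.data.frame(co$baseline[, c(base_cols, "tau_pet")])
    tune_tree(d1, cl, seed = s)$cv_balanced_accuracy -
      tune_tree(d0, cl, seed = s)$cv_balanced_accuracy
  }, numeric(1))
  expect_gt(mean(gain), 0)
})
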