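# Independent oracles used across the suite. Each is implemented from first
# principles, separately from the package code paths it checks.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigendecomposition of the
# Jacobi matrix for Hermite polynomials, weight exp(-x^2)).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Mixture log-likelihood for a random-intercept latent-class model by direct
# numerical integration over the random intercept, per subject.
oracle_mixture_loglik <- function(y_list, mu_list, pi_g, sigma_b, sigma_e,
                                  n_nodes = 50) {
  gh <- gauss_hermite(n_nodes)
  b <- sqrt(2) * sigma_b * gh$nodes
  w <- gh$weights / sqrt(pi)
  G <- length(pi_g)
  total <- 0
  for (i in seq_along(y_list)) {
    y <- y_list[[i]]
    lik_g <- vapply(seq_len(G), function(g) {
      mu <- mu_list[[i]][[g]]
      sum(w * vapply(b, function(bb) prod(dnorm(y, mu + bb, sigma_e)),
                     numeric(1)))
    }, numeric(1))
    total <- total + log(sum(pi_g * lik_g))
  }
  total
}

# Naive average precision: for every distinct threshold, recount TP/FP by a
# full scan of the data (O(n^2)).
oracle_average_precision <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Natural cubic spline via the textbook truncated-power construction
# (intercept and linear column included; the natural basis drops to K
# functions for K knots including boundaries).
oracle_natural_spline <- function(x, knots) {
  K <- length(knots)
  d <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  cols <- list(rep(1, length(x)), x)
  for (k in seq_len(K - 2)) cols[[k + 2]] <- d(k) - d(K - 1)
  do.call(cbind, cols)
}

# Exhaustive first-split search: every (variable, midpoint threshold) pair,
# weighted Gini, same tie rule as the tree grower (smaller threshold, then
# earlier predictor).
oracle_first_split <- function(data, labels, min_leaf = 1) {
  y <- factor(labels)
  K <- nlevels(y)
  gini <- function(idx) {
    if (!length(idx)) return(0)
    p <- tabulate(y[idx], K) / length(idx)
    1 - sum(p^2)
  }
  n <- length(y)
  best <- list(gain = -Inf, var = NA, threshold = Inf)
  parent <- gini(seq_len(n))
  for (j in seq_along(data)) {
    x <- data[[j]]
    for (t in sort(unique(x))[-1]) {
      cut_vals <- sort(unique(x))
      mid <- (max(cut_vals[cut_vals < t]) + t) / 2
      left <- which(x < mid)
      right <- which(x >= mid)
      if (length(left) < min_leaf || length(right) < min_leaf) next
      g <- parent - (length(left) * gini(left) + length(right) * gini(right)) / n
      if (g > best$gain + 1e-12 ||
          (abs(g - best$gain) <= 1e-12 && mid < best$threshold - 1e-12)) {
        best <- list(gain = g, var = names(data)[j], threshold = mid)
      }
    }
  }
  best
}

# Small covariate-free two-class visit set with known parameters, used by
# several likelihood tests.
toy_mixture <- function() {
  visits <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    time = rep(c(0, 1), 2),
    outcome = c(0.3, 1.1, -0.4, 0.2),
    test_version = "A"
  )
  spec <- model_spec(
    n_classes = 2, spline_df = 1,
    longitudinal_covariates = character(0),
    membership_covariates = character(0),
    lambda = 1, shift = 5, boundary_knots = c(0, 1)
  )
  params <- list(
    beta = matrix(c(4.1, 3.6, 0.8, -0.9), 2, 2),  # intercepts; slope coefs
    gamma = numeric(0),
    xi = matrix(0.7, 1, 1),  # logit of class-2 odds
    sigma_b = 0.8, sigma_e = 0.6,
    lambda = 1, shift = 5
  )
  list(visits = visits, spec = spec, params = params)
}

# Convenience: small calibrated cohort for fast fitting tests.
small_cohort <- function(n = 250, seed = 11) {
  simulate_cohort(sim_params(n_subjects = n, seed = seed))
}
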