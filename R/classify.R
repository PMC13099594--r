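# Baseline-only class prediction, stratified folds, precision-recall ----------

#' Predict latent class membership from baseline data only
#'
#' Two prediction modes for a subject never seen by the fit. `"prior"` uses
#' the membership submodel alone: `pi_ig` from the multinomial softmax of the
#' baseline covariates. `"baseline-visit"` (default) additionally conditions
#' on the single baseline outcome observation, multiplying the prior by the
#' normal density of the transformed baseline outcome under each class
#' (variance `sigma_b^2 + sigma_e^2`) and renormalising.
#'
#' @param fit An `lcmm_fit`.
#' @param baseline Baseline covariate tibble for the subjects to score;
#'   standardised with the training scaling stored in `fit`.
#' @param outcome0 Baseline (time 0) outcome per subject, required for mode
#'   `"baseline-visit"`. Either a numeric vector aligned with `baseline` rows
#'   or a visit tibble from which the `time == 0` record is taken.
#' @param mode `"baseline-visit"` or `"prior"`.
#' @return A tibble with `subject_id`, one probability column per class
#'   (`p_<class>`), and the modal `class`.
#' @export
predict_class_from_baseline <- function(fit, baseline, outcome0 = NULL,
                                        mode = c("baseline-visit", "prior")) {
  stopifnot(inherits(fit, "lcmm_fit"))
  mode <- match.arg(mode)
  params <- fit$params
  G <- fit$spec$n_classes
  labels <- params$class_labels
  covs_m <- fit$spec$membership_covariates
  W <- cbind(`(Intercept)` = 1,
             if (length(covs_m)) covariate_design(baseline, covs_m, fit$scaling))
  eta_full <- matrix(0, G, ncol(W))
  if (G > 1L) eta_full[-params$reference, ] <- params$xi
  pi <- softmax_rows(W %*% t(eta_full))
  colnames(pi) <- labels

  if (mode == "baseline-visit") {
    if (is.null(outcome0)) {
      abort("predict_class_from_baseline(): outcome0 is required for mode 'baseline-visit'.")
    }
    if (is.data.frame(outcome0)) {
      bl0 <- outcome0[outcome0$time == 0, c("subject_id", "outcome")]
      outcome0 <- bl0$outcome[match(baseline$subject_id, bl0$subject_id)]
    }
    if (anyNA(outcome0)) {
      abort("predict_class_from_baseline(): missing baseline outcome for some subjects.")
    }
    y0 <- boxcox(outcome0, params$lambda, params$shift)
    covs_l <- fit$spec$longitudinal_covariates
    xg <- if (length(covs_l)) {
      Xb <- covariate_design(baseline, setdiff(covs_l, "test_version_b"), fit$scaling)
      gm <- params$gamma[setdiff(covs_l, "test_version_b")]
      drop(Xb %*% gm)  # baseline visit uses test version A (indicator 0)
    } else 0
    B0 <- natural_spline_basis(0, fit$spec$spline_df, fit$boundary_knots,
                               interior_knots = fit$interior_knots)
    mu0 <- params$beta[, 1L] + drop(params$beta[, -1L, drop = FALSE] %*% t(B0))
    s0 <- sqrt(params$sigma_b^2 + params$sigma_e^2)
    loglik0 <- vapply(seq_len(G), function(g) {
      dnorm(y0, mu0[g] + xg, s0, log = TRUE)
    }, numeric(length(y0)))
    if (length(y0) == 1L) loglik0 <- matrix(loglik0, 1L)
    lw <- log(pmax(pi, 1e-300)) + loglik0
    pi <- softmax_rows(lw)
    colnames(pi) <- labels
  }
  map <- max.col(pi, ties.method = "first")
  out <- tibble::tibble(subject_id = baseline$subject_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(`colnames<-`(pi, paste0("p_", labels))))
  out$class <- factor(labels[map], levels = labels)
  out
}

#' Stratified k-fold assignment
#'
#' Builds folds stratified by latent class crossed with p-tau217 tertile (or
#' any class/bin pair supplied). Within each stratum, subjects are shuffled
#' by the seed and dealt round-robin to folds; strata with fewer members than
#' folds are merged into the neighbouring bin within the same class.
#'
#' @param class Vector of stratum class labels (one per subject).
#' @param bin Vector of within-class bins (e.g. biomarker tertile, integer).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: a tibble with `fold` (1..k) and
#'   the merged `stratum` label per subject, in input order.
#' @export
make_folds <- function(class, bin, k = 10, seed = 1L) {
  if (k < 2) abort("make_folds(): k must be >= 2.")
  n <- length(class)
  stopifnot(length(bin) == n)
  class <- as.character(class)
  bin <- as.integer(factor(bin))
  # merge bins with < k members into the nearest bin of the same class
  repeat {
    key <- paste(class, bin, sep = "|")
    cnt <- table(key)
    small <- names(cnt)[cnt < k]
    merged <- FALSE
    for (s in small) {
      parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
      cl <- parts[1L]; b <- as.integer(parts[2L])
      other <- sort(unique(bin[class == cl & bin != b]))
      if (!length(other)) next
      tgt <- other[which.min(abs(other - b))]
      bin[class == cl & bin == b] <- tgt
      merged <- TRUE
    }
    if (!merged) break
  }
  stratum <- paste(class, bin, sep = "|")
  fold <- integer(n)
  with_seed(derive_seed(seed, 4L), {
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1L)
      fold[idx] <- as.integer(((start - 1L + seq_along(idx) - 1L) %% k) + 1L)
    }
  })
  structure(tibble::tibble(fold = fold, stratum = stratum), class = c("fold_plan", "tbl_df", "tbl", "data.frame"))
}

#' Precision-recall curve and average precision
#'
#' Computes the precision-recall curve at every distinct score threshold
#' (descending, tied scores grouped into one step) and the area under it as
#' average precision `sum_k (R_k - R_{k-1}) P_k`.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical, or 0/1).
#' @return An object of class `pr_curve`: a list with `points` (tibble of
#'   `threshold`, `recall`, `precision`), `auprc`, and `prevalence`.
#' @export
#' @examples
#' pr <- precision_recall(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))
#' pr$auprc  # 1
precision_recall <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    abort("precision_recall(): need at least one positive and one negative label.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1L - l)[grp_end]
  recall <- tp / P
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(
    points = tibble::tibble(threshold = s[grp_end], recall = recall,
                            precision = precision),
    auprc = ap,
    prevalence = P / (P + N)
  ), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> AUPRC %.4f (prevalence %.3f, %d thresholds)\n",
              x$auprc, x$prevalence, nrow(x$points)))
  invisible(x)
}

#' Stratified cross-validated baseline prediction of latent classes
#'
#' Evaluates how well baseline data alone predict the latent classes defined
#' by the full-data model. The full-data MAP assignment is the evaluation
#' truth. Folds are stratified by that class crossed with p-tau217 tertile.
#' Per fold the model is refit on the training 90%, held-out subjects are
#' scored with [predict_class_from_baseline()], and scores are pooled across
#' folds into one precision-recall curve per class (one-vs-rest) plus a
#' combined decliner-vs-stable curve (score = sum of non-stable class
#' probabilities), along with overall MAP accuracy and its exact binomial
#' 95% CI.
#'
#' @param visits,baseline Cohort tables.
#' @param spec A [model_spec()].
#' @param k Number of folds.
#' @param seed Integer seed (folds, refit starts).
#' @param mode Prediction mode passed to [predict_class_from_baseline()].
#' @param n_starts Starts per fold refit.
#' @param reference_fit Optional pre-computed full-data `lcmm_fit` (avoids
#'   refitting when already available).
#' @return An object of class `cv_report`: `metrics` tibble (one row per
#'   curve plus accuracy), `curves` (named list of `pr_curve`), `accuracy`,
#'   `accuracy_ci`, `folds`, `failed_folds`, and `truth` ("full-data MAP
#'   assignment").
#' @export
cross_validate <- function(visits, baseline, spec = model_spec(), k = 10,
                           seed = 1L, mode = c("baseline-visit", "prior"),
                           n_starts = 1, reference_fit = NULL) {
  mode <- match.arg(mode)
  full <- reference_fit %||% fit_lcmm(visits, baseline, spec,
                                      n_starts = max(2, n_starts), seed = seed)
  labels <- full$params$class_labels
  truth_tbl <- full$assignment
  bl <- baseline[match(truth_tbl$subject_id, baseline$subject_id), ]
  tert <- cut(bl$ptau217,
              breaks = stats::quantile(bl$ptau217, c(0, 1 / 3, 2 / 3, 1)),
              labels = FALSE, include.lowest = TRUE)
  plan <- make_folds(as.character(truth_tbl$class), tert, k = k, seed = seed)

  # hold transform and knots fixed at the full-data values across folds
  fold_spec <- spec
  fold_spec$lambda <- full$params$lambda
  fold_spec$shift <- full$params$shift
  fold_spec$boundary_knots <- full$boundary_knots
  fold_spec$interior_knots <- full$interior_knots

  preds <- vector("list", k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    test_ids <- truth_tbl$subject_id[plan$fold == f]
    train_ids <- setdiff(truth_tbl$subject_id, test_ids)
    res <- tryCatch({
      fit_f <- fit_lcmm(
        visits[visits$subject_id %in% train_ids, ],
        bl[bl$subject_id %in% train_ids, ],
        fold_spec, n_starts = n_starts, seed = derive_seed(seed, 200L + f),
        init = full$params
      )
      predict_class_from_baseline(
        fit_f, bl[bl$subject_id %in% test_ids, ],
        outcome0 = visits[visits$subject_id %in% test_ids, ],
        mode = mode
      )
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, f) else preds[[f]] <- res
  }
  if (length(failed) > 2L) {
    abort(sprintf("cross_validate(): %d folds failed to refit (folds %s).",
                  length(failed), paste(failed, collapse = ", ")))
  }
  pred <- dplyr::bind_rows(preds)
  truth <- truth_tbl$class[match(pred$subject_id, truth_tbl$subject_id)]

  curves <- list()
  for (cl in labels) {
    curves[[paste0(cl, "_vs_rest")]] <-
      precision_recall(pred[[paste0("p_", cl)]], truth == cl)
  }
  stable_lab <- labels[1L]
  dec_score <- rowSums(as.matrix(pred[paste0("p_", setdiff(labels, stable_lab))]))
  curves[["decliner_vs_stable"]] <- precision_recall(dec_score, truth != stable_lab)

  acc_n <- sum(as.character(pred$class) == as.character(truth))
  bt <- stats::binom.test(acc_n, nrow(pred))
  metrics <- dplyr::bind_rows(
    purrr::imap(curves, ~ tibble::tibble(metric = paste0("auprc_", .y),
                                         value = .x$auprc)),
    tibble::tibble(metric = "accuracy", value = acc_n / nrow(pred))
  )
  structure(list(
    metrics = metrics, curves = curves,
    accuracy = acc_n / nrow(pred),
    accuracy_ci = unname(bt$conf.int),
    predictions = pred,
    folds = plan, failed_folds = failed, k = k, mode = mode,
    truth = "full-data model MAP assignment"
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV (mode %s; truth: %s)\n  accuracy %.3f (95%% CI %.3f-%.3f)\n",
    x$k, x$mode, x$truth, x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]
  ))
  for (nm in names(x$curves)) {
    cat(sprintf("  AUPRC %-22s %.3f\n", nm, x$curves[[nm]]$auprc))
  }
  if (length(x$failed_folds)) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}
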