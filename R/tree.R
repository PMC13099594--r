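# Classification-tree profile of latent classes -------------------------------
#
# Greedy binary recursive partitioning with Gini impurity. A split is kept iff
# its n-weighted impurity reduction is at least cp times the root impurity and
# both children hold at least min_leaf records. Ties break deterministically:
# smaller threshold first, then the earlier predictor in column order.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best (variable, threshold/set) for one node; exhaustive over predictors.
# Equal-gain ties resolve to the smaller threshold, then the earlier
# predictor in column order (categorical splits rank after numeric ties).
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  K <- nlevels(y)
  parent_counts <- tabulate(y, K)
  parent_imp <- gini_impurity(parent_counts)
  tol <- 1e-12
  best <- list(gain = -Inf, threshold = Inf, var = Inf)
  consider <- function(gain, j, thr, set) {
    if (gain > best$gain + tol ||
        (abs(gain - best$gain) <= tol &&
           (thr < best$threshold - tol ||
              (abs(thr - best$threshold) <= tol && j < best$var)))) {
      best <<- list(gain = gain, var = j, threshold = thr, set = set)
    }
  }
  for (j in seq_along(X)) {
    x <- X[[j]]
    if (is.factor(x) || is.character(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2L) next
      xc <- as.character(x)
      for (s in seq_len(2^(length(lev) - 1L) - 1L)) {
        left_lev <- lev[as.logical(bitwAnd(s, 2^(seq_along(lev) - 1L)))]
        left <- xc %in% left_lev
        nl <- sum(left)
        if (nl < min_leaf || n - nl < min_leaf) next
        cl <- tabulate(y[left], K)
        imp <- (nl * gini_impurity(cl) +
                  (n - nl) * gini_impurity(parent_counts - cl)) / n
        consider(parent_imp - imp, j, Inf, left_lev)
      }
    } else {
      ord <- order(x)
      xs <- x[ord]; ys <- y[ord]
      cand <- which(c(diff(xs) != 0, FALSE))
      cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
      if (!length(cand)) next
      cum <- vapply(seq_len(K), function(k) cumsum(ys == levels(y)[k]),
                    numeric(n))
      CL <- cum[cand, , drop = FALSE]
      nl <- cand; nr <- n - cand
      CR <- matrix(parent_counts, length(cand), K, byrow = TRUE) - CL
      imp <- (nl * (1 - rowSums((CL / nl)^2)) +
                nr * (1 - rowSums((CR / nr)^2))) / n
      gains <- parent_imp - imp
      gmax <- max(gains)
      if (gmax <= best$gain - tol) {
        # still might tie; fall through only when close
        if (gmax < best$gain - tol) next
      }
      ties <- which(gains >= gmax - tol)
      thrs <- (xs[cand[ties]] + xs[cand[ties] + 1L]) / 2
      pick <- ties[which.min(thrs)]
      consider(gains[pick], j, (xs[cand[pick]] + xs[cand[pick] + 1L]) / 2, NULL)
    }
  }
  if (!is.finite(best$gain)) return(NULL)
  if (is.infinite(best$threshold)) best$threshold <- NA_real_
  best
}

grow_node <- function(X, y, min_leaf, cp, root_imp, n_total, depth = 0L) {
  K <- nlevels(y)
  counts <- tabulate(y, K)
  names(counts) <- levels(y)
  pred <- which.max(counts)  # ties to lower class index
  imp <- gini_impurity(counts)
  node <- list(
    n = length(y), counts = counts, predicted = levels(y)[pred],
    impurity = imp, leaf = TRUE
  )
  if (imp <= 1e-12 || length(y) < 2L * min_leaf || depth >= 30L) return(node)
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp)) return(node)
  weighted_gain <- (length(y) / n_total) * sp$gain
  if (weighted_gain < cp * root_imp - 1e-12) return(node)
  vname <- names(X)[sp$var]
  left <- if (is.null(sp$set)) {
    X[[sp$var]] < sp$threshold
  } else {
    as.character(X[[sp$var]]) %in% sp$set
  }
  node$leaf <- FALSE
  node$split_var <- vname
  node$threshold <- sp$threshold
  node$set <- sp$set
  node$gain <- weighted_gain          # n-weighted impurity reduction
  node$left <- grow_node(X[left, , drop = FALSE], y[left], min_leaf, cp,
                         root_imp, n_total, depth + 1L)
  node$right <- grow_node(X[!left, , drop = FALSE], y[!left], min_leaf, cp,
                          root_imp, n_total, depth + 1L)
  node
}

#' Grow a classification tree over baseline predictors
#'
#' @param data Data frame of predictors (numeric or factor/character
#'   columns); column order breaks ties between equally good splits.
#' @param labels Class label per row (factor or coercible).
#' @param min_leaf Minimum records in each child.
#' @param cp Complexity parameter: a split must reduce the n-weighted Gini
#'   impurity by at least `cp` times the root impurity.
#' @return An object of class `tree_model` with the nested `root` node, the
#'   settings used, and the class levels.
#' @export
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 10, 11, 12))
#' grow_tree(d, rep(c("a", "b"), each = 3), min_leaf = 1, cp = 0)
grow_tree <- function(data, labels, min_leaf = 20, cp = 0.01) {
  data <- as.data.frame(data)
  y <- factor(labels)
  stopifnot(nrow(data) == length(y))
  if (nlevels(droplevels(y)) < 2L) {
    warn("grow_tree(): single-class input; returning a stump.")
  }
  root_imp <- gini_impurity(tabulate(y, nlevels(y)))
  root <- grow_node(data, y, min_leaf, cp, max(root_imp, 1e-12), nrow(data))
  structure(list(
    root = root, cp = cp, min_leaf = min_leaf,
    classes = levels(y), predictors = names(data), n = nrow(data)
  ), class = "tree_model")
}

predict_node <- function(node, data) {
  n <- nrow(data)
  out <- character(n)
  if (node$leaf || n == 0L) {
    out[] <- node$predicted
    return(out)
  }
  left <- if (is.null(node$set)) {
    data[[node$split_var]] < node$threshold
  } else {
    as.character(data[[node$split_var]]) %in% node$set
  }
  out[left] <- predict_node(node$left, data[left, , drop = FALSE])
  out[!left] <- predict_node(node$right, data[!left, , drop = FALSE])
  out
}

#' @export
predict.tree_model <- function(object, newdata, ...) {
  factor(predict_node(object$root, as.data.frame(newdata)),
         levels = object$classes)
}

#' Impurity-based variable importance
#'
#' Sums each predictor's n-weighted Gini impurity reductions over all its
#' splits and normalises the shares to 100%.
#'
#' @param tree A `tree_model`.
#' @return A tibble (`variable`, `importance` in percent, descending); empty
#'   for a stump.
#' @export
variable_importance <- function(tree) {
  acc <- new.env()
  walk <- function(node) {
    if (node$leaf) return(invisible())
    cur <- mget(node$split_var, envir = acc, ifnotfound = 0)[[1L]]
    assign(node$split_var, cur + node$gain, envir = acc)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  vals <- unlist(as.list(acc))
  if (!length(vals)) {
    return(tibble::tibble(variable = character(0), importance = numeric(0)))
  }
  tibble::tibble(
    variable = names(vals),
    importance = unname(100 * vals / sum(vals))
  ) |> dplyr::arrange(dplyr::desc(.data$importance))
}

balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth)
  lv <- levels(droplevels(truth))
  mean(vapply(lv, function(l) mean(pred[truth == l] == l), numeric(1)))
}

#' Tune the tree complexity parameter by cross-validation
#'
#' Grows a tree per fold at each candidate `cp`, scoring held-out accuracy
#' and balanced accuracy (mean per-class recall). The chosen `cp` maximises
#' mean CV accuracy; ties break toward the larger `cp` (simpler tree).
#'
#' @inheritParams grow_tree
#' @param cp_grid Candidate complexity parameters.
#' @param k Number of folds (stratified by class).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `tree_tuning`: per-cp `table` (mean accuracy,
#'   balanced accuracy, SEs), `best_cp`, and the final `tree` grown on all
#'   data at `best_cp`.
#' @export
tune_tree <- function(data, labels, cp_grid = c(0, 0.001, 0.005, 0.01, 0.02, 0.05),
                      k = 10, min_leaf = 20, seed = 1L) {
  if (!length(cp_grid)) abort("tune_tree(): cp grid is empty.")
  data <- as.data.frame(data)
  y <- factor(labels)
  plan <- make_folds(as.character(y), rep(1L, length(y)), k = k, seed = seed)
  res <- purrr::map_dfr(sort(cp_grid), function(cp) {
    per_fold <- purrr::map_dfr(seq_len(k), function(f) {
      tr <- plan$fold != f
      tree <- grow_tree(data[tr, , drop = FALSE], y[tr], min_leaf = min_leaf, cp = cp)
      pred <- predict(tree, data[!tr, , drop = FALSE])
      tibble::tibble(
        accuracy = mean(pred == y[!tr]),
        balanced_accuracy = balanced_accuracy(y[!tr], pred)
      )
    })
    tibble::tibble(
      cp = cp,
      accuracy = mean(per_fold$accuracy),
      accuracy_se = stats::sd(per_fold$accuracy) / sqrt(k),
      balanced_accuracy = mean(per_fold$balanced_accuracy),
      balanced_accuracy_se = stats::sd(per_fold$balanced_accuracy) / sqrt(k)
    )
  })
  best <- res[res$accuracy >= max(res$accuracy) - 1e-12, ]
  best_cp <- max(best$cp)
  structure(list(
    table = res, best_cp = best_cp, k = k,
    cv_accuracy = res$accuracy[res$cp == best_cp],
    cv_balanced_accuracy = res$balanced_accuracy[res$cp == best_cp],
    tree = grow_tree(data, y, min_leaf = min_leaf, cp = best_cp)
  ), class = "tree_tuning")
}

#' @export
print.tree_tuning <- function(x, ...) {
  cat(sprintf("<tree_tuning> chosen cp = %g (CV accuracy %.3f, balanced %.3f)\n",
              x$best_cp, x$cv_accuracy, x$cv_balanced_accuracy))
  print(x$table)
  invisible(x)
}

format_node <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  lab <- sprintf("%s[n=%d, pred=%s, gini=%.3f]", pad, node$n, node$predicted,
                 node$impurity)
  if (node$leaf) return(lab)
  rule <- if (is.null(node$set)) {
    sprintf("%s < %.4g", node$split_var, node$threshold)
  } else {
    sprintf("%s in {%s}", node$split_var, paste(node$set, collapse = ","))
  }
  c(sprintf("%s (split: %s)", lab, rule),
    format_node(node$left, indent + 1L),
    format_node(node$right, indent + 1L))
}

#' @export
format.tree_model <- function(x, ...) paste(format_node(x$root), collapse = "\n")

#' @export
print.tree_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

node_to_list <- function(node) {
  out <- list(n = node$n, counts = as.list(node$counts),
              predicted = node$predicted, impurity = node$impurity,
              leaf = node$leaf)
  if (!node$leaf) {
    out$split_var <- node$split_var
    out$threshold <- node$threshold
    out$set <- node$set
    out$gain <- node$gain
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
  }
  out
}

#' Export a tree as nested JSON
#'
#' @param tree A `tree_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(node_to_list(tree$root), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
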