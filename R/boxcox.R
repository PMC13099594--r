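#' Box-Cox transformation of a shifted outcome
#'
#' Transforms a cognitive composite score (which may be negative) after adding
#' a positive shift, so that heavier-than-Gaussian tails can be symmetrised
#' before mixture modelling. For exponent `lambda != 0` the transform is
#' `((y + shift)^lambda - 1) / lambda`; at `lambda = 0` it is
#' `log(y + shift)`.
#'
#' @param y Numeric vector of raw outcome values.
#' @param lambda Box-Cox exponent.
#' @param shift Offset added to `y` before transforming; every shifted value
#'   must be strictly positive.
#' @return Numeric vector of transformed values.
#' @seealso [boxcox_inverse()], [boxcox_log_jacobian()], [select_lambda()]
#' @export
#' @examples
#' boxcox(5, lambda = 1)           # 4
#' boxcox(exp(1), lambda = 0)      # 1
boxcox <- function(y, lambda, shift = 0) {
  ys <- y + shift
  bad <- which(!is.na(ys) & ys <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Box-Cox transform undefined: shifted outcome <= 0 at record(s) %s (first value %.4g).",
      paste(head(bad, 5L), collapse = ", "), ys[bad[1L]]
    ))
  }
  if (abs(lambda) < .Machine$double.eps^0.5) log(ys) else (ys^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps a transformed value back to the raw outcome scale, undoing the shift.
#' Values for which the inverse is undefined (`lambda * z + 1 <= 0` when
#' `lambda != 0`) return `NA`.
#'
#' @param z Numeric vector on the transformed scale.
#' @inheritParams boxcox
#' @return Numeric vector on the raw outcome scale.
#' @export
boxcox_inverse <- function(z, lambda, shift = 0) {
  if (abs(lambda) < .Machine$double.eps^0.5) {
    return(exp(z) - shift)
  }
  base <- lambda * z + 1
  out <- rep(NA_real_, length(z))
  ok <- !is.na(base) & base > 0
  out[ok] <- base[ok]^(1 / lambda) - shift
  out
}

#' Log-Jacobian of the Box-Cox transformation
#'
#' Per-observation contribution `(lambda - 1) * log(y + shift)` that corrects
#' a Gaussian log-likelihood on the transformed scale back to the raw scale.
#'
#' @inheritParams boxcox
#' @return Numeric vector of per-observation log-Jacobian terms.
#' @export
boxcox_log_jacobian <- function(y, lambda, shift = 0) {
  ys <- y + shift
  bad <- which(!is.na(ys) & ys <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Box-Cox Jacobian undefined: shifted outcome <= 0 at record(s) %s.",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  (lambda - 1) * log(ys)
}

#' Select the Box-Cox exponent by profile likelihood
#'
#' Chooses the exponent that makes the pooled transformed outcomes closest to
#' Gaussian, by maximising the Jacobian-corrected normal log-likelihood over a
#' grid of candidate exponents. Ties (within numerical tolerance) are broken
#' toward `lambda = 1`, i.e. toward no transformation.
#'
#' @param y Numeric vector of raw outcomes (visit-level, pooled over subjects),
#'   or a data frame containing an `outcome` column.
#' @param shift Offset added before transforming. The default `NULL` uses
#'   `1 - min(y)`, which makes the smallest shifted value exactly 1.
#' @param grid Candidate exponents; default `seq(-2, 2, by = 0.1)`.
#' @return A list with elements `lambda` (the selected exponent), `shift`, and
#'   `profile`, a tibble of the grid with the profile log-likelihood per
#'   candidate.
#' @export
#' @examples
#' y <- rnorm(500)
#' select_lambda(y)$lambda
select_lambda <- function(y, shift = NULL, grid = seq(-2, 2, by = 0.1)) {
  if (is.data.frame(y)) y <- y$outcome
  y <- y[!is.na(y)]
  if (!length(y)) abort("select_lambda(): empty outcome vector.")
  if (isTRUE(all.equal(stats::var(y), 0))) {
    abort("select_lambda(): outcome vector is constant; the exponent is not identifiable.")
  }
  if (is.null(shift)) shift <- 1 - min(y)
  n <- length(y)
  ll <- vapply(grid, function(lam) {
    z <- boxcox(y, lam, shift)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * (log(2 * pi * s2) + 1) + sum(boxcox_log_jacobian(y, lam, shift))
  }, numeric(1))
  best <- max(ll)
  cand <- which(ll >= best - 1e-8)
  pick <- cand[which.min(abs(grid[cand] - 1))]
  list(
    lambda = grid[pick],
    shift = shift,
    profile = tibble::tibble(lambda = grid, loglik = ll)
  )
}
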