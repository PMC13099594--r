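#' Natural cubic spline basis for follow-up time
#'
#' Builds the spline design used for class-specific time effects: a natural
#' cubic spline (linear beyond the boundary knots, zero second derivative at
#' them) without an intercept column. Interior knots follow the study
#' convention: none for one degree of freedom, the median observation time for
#' two, and the tertiles for three.
#'
#' @param t Numeric vector of times (years since baseline).
#' @param df Degrees of freedom (number of basis columns), 1, 2 or 3.
#' @param boundary_knots Length-2 numeric: baseline and maximum follow-up time.
#' @param interior_knots Optional explicit interior knots. The default `NULL`
#'   places them at quantiles of `knot_times` per the `df` rule.
#' @param knot_times Times whose quantiles define interior knots; defaults to
#'   `t` itself. Pass the full set of observation times when evaluating the
#'   basis on a prediction grid so the knots match the fitted model.
#' @return Matrix with `length(t)` rows and `df` columns; the knots are
#'   attached as attributes `boundary_knots` and `interior_knots`.
#' @export
#' @examples
#' B <- natural_spline_basis(seq(0, 7, 0.5), df = 2, boundary_knots = c(0, 7))
#' dim(B)
natural_spline_basis <- function(t, df, boundary_knots,
                                 interior_knots = NULL, knot_times = t) {
  stopifnot(length(boundary_knots) == 2L)
  if (!(boundary_knots[1] < boundary_knots[2])) {
    abort("natural_spline_basis(): boundary knots must be increasing.")
  }
  if (!df %in% 1:3) abort("natural_spline_basis(): df must be 1, 2 or 3.")
  if (is.null(interior_knots)) {
    interior_knots <- switch(df,
      numeric(0),
      stats::median(knot_times),
      stats::quantile(knot_times, c(1 / 3, 2 / 3), names = FALSE)
    )
  }
  if (length(interior_knots) &&
      (min(interior_knots) <= boundary_knots[1] ||
       max(interior_knots) >= boundary_knots[2])) {
    abort(sprintf(
      "natural_spline_basis(): interior knot(s) [%s] outside boundary span (%g, %g).",
      paste(signif(interior_knots, 4), collapse = ", "),
      boundary_knots[1], boundary_knots[2]
    ))
  }
  if (length(interior_knots) != df - 1L) {
    abort("natural_spline_basis(): need df - 1 interior knots.")
  }
  B <- splines::ns(t,
    knots = if (length(interior_knots)) interior_knots else NULL,
    Boundary.knots = boundary_knots, intercept = FALSE
  )
  B <- unclass(B)[, , drop = FALSE]
  attributes(B)[c("knots", "Boundary.knots", "intercept")] <- NULL
  dimnames(B) <- list(NULL, paste0("ns", seq_len(ncol(B))))
  attr(B, "boundary_knots") <- as.numeric(boundary_knots)
  attr(B, "interior_knots") <- as.numeric(interior_knots)
  B
}
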