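# Polynomial shape models for kernels: OLS fits on a normalized time axis,
# nested F-tests, the sequential selection ladder, and shape parameters
# (y-intercept, tangent slope at the midpoint).

#' Fit a polynomial to kernel values
#'
#' Ordinary least squares of kernel values on powers of time. The default
#' time grid is the normalized breakpoint grid `t_k = (k-1)/(K-1)` on
#' `[0, 1]`.
#'
#' @param y Kernel values (cents). A `"kernel"` object is accepted.
#' @param degree Polynomial degree, 1 (linear) to 4 (quartic).
#' @param t Optional time grid; defaults to the normalized grid.
#' @return An object of class `"shape_fit"`: `degree`, `coefficients`
#'   (ascending powers, `b0` first), `sse`, `r_squared`, `n_points`, plus the
#'   data (`t`, `y`, `fitted`).
#' @export
fit_polynomial <- function(y, degree, t = NULL) {
  if (inherits(y, "kernel")) y <- y$values
  y <- as.numeric(y)
  n <- length(y)
  degree <- as.integer(degree)
  if (degree < 1L || degree > 4L)
    stop("degree must be between 1 and 4", call. = FALSE)
  if (degree >= n)
    stop("degree must be smaller than the number of points", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1) / (n - 1)
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > .Machine$double.eps) max(0, min(1, 1 - sse / sst)) else 1
  structure(list(degree = degree, coefficients = coefs, sse = sse,
                 r_squared = r2, n_points = n, t = t, y = y,
                 fitted = unname(stats::fitted(fit))),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("shape_fit: degree %d, n = %d, SSE = %.4g, R^2 = %.3f\n",
              x$degree, x$n_points, x$sse, x$r_squared))
  cat("  coefficients (b0..):", signif(x$coefficients, 4), "\n")
  invisible(x)
}

#' Nested F-test between two polynomial fits
#'
#' Compares a lower-degree fit against a higher-degree fit of the same data:
#' `F = ((SSE_s - SSE_b)/df_num) / (SSE_b/df_den)` with `df_num` the degree
#' difference and `df_den = n - (degree_big + 1)`. For Gaussian OLS this is
#' the likelihood-ratio-equivalent test.
#'
#' @param fit_small,fit_big `"shape_fit"` objects on the same data with
#'   `fit_big$degree > fit_small$degree`.
#' @param alpha Significance level for declaring the bigger model the winner.
#' @return An object of class `"nested_test"`: `df_num`, `df_den`, `f_stat`,
#'   `p_value`, `winner` (`"small"`/`"big"`), and the two degrees.
#' @export
nested_f_test <- function(fit_small, fit_big, alpha = 0.05) {
  if (fit_big$degree <= fit_small$degree)
    stop("fit_big must have the higher degree", call. = FALSE)
  if (fit_big$n_points != fit_small$n_points ||
      !isTRUE(all.equal(fit_small$y, fit_big$y)))
    stop("fits must be on the same data", call. = FALSE)
  if (fit_big$sse <= .Machine$double.eps)
    stop("degenerate test: the larger model fits perfectly (SSE = 0)",
         call. = FALSE)
  df_num <- fit_big$degree - fit_small$degree
  df_den <- fit_big$n_points - (fit_big$degree + 1L)
  if (df_den < 1L)
    stop("no residual degrees of freedom for the larger model", call. = FALSE)
  f <- max(0, (fit_small$sse - fit_big$sse) / df_num /
             (fit_big$sse / df_den))
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  structure(list(df_num = df_num, df_den = df_den, f_stat = f, p_value = p,
                 degree_small = fit_small$degree, degree_big = fit_big$degree,
                 winner = if (p < alpha) "big" else "small"),
            class = "nested_test")
}

degree_label <- function(d) c("linear", "quadratic", "cubic", "quartic")[d]

#' Sequential shape selection ladder
#'
#' Replicates the sequential nested-comparison procedure used to pick the
#' best-fitting kernel shape: linear vs quadratic first; if that is not
#' significant, linear vs cubic; a significant cubic is then challenged by
#' quartic; if linear vs cubic is also not significant, linear vs quartic
#' decides. (If linear vs quadratic is significant the winner steps up the
#' same way: quadratic vs cubic, then vs quartic.)
#'
#' @param y Kernel values (or a `"kernel"`); needs at least 6 points so the
#'   quartic retains residual degrees of freedom (melody kernels, with 3
#'   points, are excluded from the ladder).
#' @param t Optional time grid (normalized grid by default).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"shape_selection"`: `best_degree`,
#'   `best_label`, `ladder` (data.frame of comparisons with df, F, p and the
#'   better-fitting model), `fits` (list of the four fits).
#' @export
select_shape <- function(y, t = NULL, alpha = 0.05) {
  if (inherits(y, "kernel")) y <- y$values
  if (length(y) < 6L)
    stop("shape selection needs >= 6 points (quartic residual df)",
         call. = FALSE)
  fits <- lapply(1:4, function(d) fit_polynomial(y, d, t = t))
  rows <- list()
  run <- function(small, big) {
    tst <- nested_f_test(fits[[small]], fits[[big]], alpha = alpha)
    better <- if (tst$winner == "big") big else small
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = sprintf("%s and %s", degree_label(small),
                           degree_label(big)),
      df_num = tst$df_num, df_den = tst$df_den, f = tst$f_stat,
      p = tst$p_value, better = degree_label(better),
      stringsAsFactors = FALSE)
    tst$winner == "big"
  }
  current <- 1L
  if (run(1L, 2L)) {                     # quadratic beats linear
    current <- 2L
    if (run(2L, 3L)) {
      current <- 3L
      if (run(3L, 4L)) current <- 4L
    } else if (run(2L, 4L)) current <- 4L
  } else if (run(1L, 3L)) {              # cubic beats linear
    current <- 3L
    if (run(3L, 4L)) current <- 4L
  } else if (run(1L, 4L)) {              # last rung: quartic vs linear
    current <- 4L
  }
  structure(list(best_degree = current,
                 best_label = degree_label(current),
                 ladder = do.call(rbind, rows), fits = fits),
            class = "shape_selection")
}

#' @export
print.shape_selection <- function(x, ...) {
  cat(sprintf("shape_selection: best-fitting model = %s\n", x$best_label))
  print(transform(x$ladder, f = round(f, 2), p = signif(p, 3)))
  invisible(x)
}

#' Shape parameters of a fitted polynomial
#'
#' Extracts the y-intercept `b0 = p(0)` and the slope of the tangent at the
#' midpoint of the normalized time axis, `p'(0.5)`, computed from the
#' analytic derivative of the fitted polynomial.
#'
#' @param fit A `"shape_fit"`.
#' @param midpoint Evaluation point for the tangent slope (default 0.5).
#' @return List with `b0` (cents), `midpoint_slope` (cents per normalized
#'   time unit) and `midpoint`.
#' @export
shape_params <- function(fit, midpoint = 0.5) {
  co <- fit$coefficients
  powers <- seq_along(co) - 1L
  slope <- sum(powers[-1L] * co[-1L] * midpoint^(powers[-1L] - 1L))
  list(b0 = co[1L], midpoint_slope = slope, midpoint = midpoint)
}
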