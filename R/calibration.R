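#' Fit a linear CI-to-ground-truth calibration
#'
#' Ordinary least squares fit `y = m * x + q` with the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x Canopy Index values (0-1000); at least 3 points, not all equal.
#' @param y Ground-truth values (gap fraction, LLN, interior-leaf fraction,
#'   cluster or berry weight, light-interception fraction, ...).
#' @return An object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`. `r_squared` is `NA` (flagged) when `y` has zero
#'   variance.
#' @export
fit_linear <- function(x, y) {
  check_paired(x, y)
  if (stats::var(x) == 0) stop("degenerate x: all CI values equal",
                               call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  co <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, n = length(x)),
            class = "linear_fit")
}

#' Construct a linear calibration from known coefficients
#'
#' Wraps published calibration coefficients (e.g. a pooled per-vine gap
#' line) into a `linear_fit` so it can be evaluated with [predict()].
#'
#' @param slope,intercept Line coefficients.
#' @param r_squared Optional reported goodness of fit.
#' @param n Optional number of points behind the fit.
#' @return A `linear_fit`.
#' @export
linear_calibration <- function(slope, intercept, r_squared = NA_real_,
                               n = NA_integer_) {
  stop_if_not_scalar_number(slope, "slope")
  stop_if_not_scalar_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n = n),
            class = "linear_fit")
}

#' Fit an exponential CI-to-ground-truth calibration
#'
#' Fits `y = a * exp(b * x)` by least squares on `log(y)` (deterministic
#' log-linear fit); `R^2` is reported on the original scale,
#' `1 - SS_res / SS_tot` with residuals `y - a * exp(b * x)`.
#'
#' @inheritParams fit_linear
#' @return An object of class `exponential_fit`: `a` (> 0), `b`,
#'   `r_squared`, `n`.
#' @export
fit_exponential <- function(x, y) {
  check_paired(x, y)
  if (any(y <= 0)) {
    stop("exponential model requires all y > 0; use the linear model instead",
         call. = FALSE)
  }
  if (stats::var(x) == 0) stop("degenerate x: all CI values equal",
                               call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), log(y))
  a <- exp(unname(fit$coefficients[1L]))
  b <- unname(fit$coefficients[2L])
  res <- y - a * exp(b * x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(a = a, b = b, r_squared = r2, n = length(x)),
            class = "exponential_fit")
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("paired observations must not contain NA",
                                 call. = FALSE)
  invisible(TRUE)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.6g x + %.6g  (R2 = %.4g, n = %s)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> y = %.6g exp(%.6g x)  (R2 = %.4g, n = %s)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Evaluate a calibration at given CI values
#'
#' @param object A `linear_fit` or `exponential_fit`.
#' @param ci CI value(s) at which to evaluate the model.
#' @param percent If `TRUE`, multiply the (fractional) prediction by 100.
#' @param ... Unused.
#' @return Predicted ground-truth value(s).
#' @examples
#' cg_line <- linear_calibration(slope = -0.001, intercept = 0.761)
#' predict(cg_line, ci = 250, percent = TRUE)  # 51.1
#' @export
predict.linear_fit <- function(object, ci, percent = FALSE, ...) {
  out <- object$slope * ci + object$intercept
  if (percent) out <- 100 * out
  out
}

#' @rdname predict.linear_fit
#' @export
predict.exponential_fit <- function(object, ci, percent = FALSE, ...) {
  out <- object$a * exp(object$b * ci)
  if (percent) out <- 100 * out
  out
}

#' Calibration report across scopes
#'
#' Fits the linear (and, where all responses are positive, the exponential)
#' calibration of one ground-truth variable against CI within each scope
#' group, reporting coefficients, `R^2` and Pearson `r`. With
#' `pool = "date"` the data are first averaged per measuring date (each
#' point = one date mean over vines) before a single pooled fit, the
#' standard per-vine pooled presentation.
#'
#' @param data A data frame holding at least the `x`, `y` and scope columns.
#' @param x,y Column names of the CI predictor and the ground-truth response.
#' @param scope Optional column name to group by (e.g. `"vine_id"`,
#'   `"date"`, `"sector"`); `NULL` fits once on all rows.
#' @param pool `"none"` or `"date"`; `"date"` averages over the `date`
#'   column first.
#' @param min_n Groups with fewer points are skipped with a warning.
#' @return A data frame with one row per group: `scope`, `n`, `slope`,
#'   `intercept`, `r_squared`, `pearson_r`, `exp_a`, `exp_b`,
#'   `exp_r_squared` (exponential columns `NA` where invalid).
#' @export
calibration_report <- function(data, x = "ci", y, scope = NULL,
                               pool = c("none", "date"), min_n = 3L) {
  pool <- match.arg(pool)
  for (col in c(x, y, scope)) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  if (pool == "date") {
    if (!"date" %in% names(data)) stop("pool = 'date' needs a date column",
                                       call. = FALSE)
    agg <- stats::aggregate(data[, c(x, y)], by = list(date = data$date), mean)
    data <- agg
    scope <- NULL
  }
  key <- if (is.null(scope)) rep("pooled", nrow(data)) else
    as.character(data[[scope]])
  groups <- split(seq_len(nrow(data)), key)
  rows <- lapply(names(groups), function(k) {
    i <- groups[[k]]
    if (length(i) < min_n) {
      warning("scope '", k, "' has fewer than ", min_n, " points; skipped")
      return(NULL)
    }
    xi <- data[[x]][i]
    yi <- data[[y]][i]
    if (stats::var(yi) == 0) {
      warning("scope '", k, "' has constant response; R2 undefined")
    }
    lin <- fit_linear(xi, yi)
    r <- if (stats::var(yi) > 0) stats::cor(xi, yi) else NA_real_
    ex <- if (all(yi > 0)) fit_exponential(xi, yi) else NULL
    data.frame(scope = k, n = length(i),
               slope = lin$slope, intercept = lin$intercept,
               r_squared = lin$r_squared, pearson_r = r,
               exp_a = if (is.null(ex)) NA_real_ else ex$a,
               exp_b = if (is.null(ex)) NA_real_ else ex$b,
               exp_r_squared = if (is.null(ex)) NA_real_ else ex$r_squared,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no scope had enough points", call. = FALSE)
  do.call(rbind, rows)
}
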