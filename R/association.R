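#' Bivariate regression screen (linear or quadratic)
#'
#' Fits `y ~ x` or `y ~ x + x^2` by least squares, the screen used to relate
#' each diversity or soil predictor to multifunctionality (quadratic fits
#' capture unimodal, "single peak" responses).
#'
#' @param data `data.frame` holding both variables.
#' @param response,predictor Column names.
#' @param form `"linear"` or `"quadratic"`.
#' @return List of class `"regfit"`: `response`, `predictor`, `form`,
#'   `coefficients`, `r2`, `p` (overall F-test), `n`, and the underlying
#'   `lm` fit.
#' @export
ols_screen <- function(data, response, predictor, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  stopifnot(response %in% names(data), predictor %in% names(data))
  d <- data.frame(y = data[[response]], x = data[[predictor]])
  d <- d[stats::complete.cases(d), ]
  n_par <- if (form == "linear") 2L else 3L
  if (nrow(d) <= n_par + 1L) stop("too few observations for the requested form")
  if (stats::sd(d$x) == 0) stop("constant predictor: ", predictor)
  fit <- if (form == "linear") stats::lm(y ~ x, data = d)
         else stats::lm(y ~ x + I(x^2), data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_
       else unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(response = response, predictor = predictor, form = form,
                 coefficients = stats::coef(fit), r2 = sm$r.squared, p = p,
                 n = nrow(d), fit = fit),
            class = "regfit")
}

#' @export
print.regfit <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s]  R2 = %.3f, p = %.3g, n = %d\n",
              x$response, x$predictor, x$form, x$r2, x$p, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Run a battery of bivariate screens
#'
#' Fits both linear and quadratic forms of `response` against each predictor
#' and collects the results in a table.
#'
#' @param data `data.frame`.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @return `data.frame`: predictor, form, coefficients (intercept, b1, b2),
#'   r2, p, n.
#' @export
screen_table <- function(data, response, predictors) {
  rows <- list()
  for (pred in predictors) {
    for (form in c("linear", "quadratic")) {
      f <- ols_screen(data, response, pred, form)
      co <- f$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        response = response, predictor = pred, form = form,
        intercept = unname(co[1]), b1 = unname(co[2]),
        b2 = if (form == "quadratic") unname(co[3]) else NA_real_,
        r2 = f$r2, p = f$p, n = f$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
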