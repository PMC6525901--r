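# The eight single-predictor curve-estimation families, fitted the way the
# classic statistical-package "curve estimation" procedure fits them:
# additive families by OLS on the stated regressors, multiplicative families
# by OLS after log-linearization, with R^2/F/Sig reported on the fitting
# (possibly transformed) scale.

curve_forms <- c("linear", "logarithm", "quadratic", "composite",
                 "power", "growth", "exponential", "logistic")

# per-family description: regressor builder, response transform,
# coefficient back-transform, prediction function
curve_family <- function(form, u = Inf) {
  switch(form,
    linear = list(
      k = 2, x_ok = function(x) TRUE, y_ok = function(y) TRUE,
      fit = function(x, y) stats::lm(y ~ x),
      coefs = function(b) c(b0 = b[[1]], b1 = b[[2]]),
      predict = function(b, x) b[["b0"]] + b[["b1"]] * x),
    logarithm = list(
      k = 2, x_ok = function(x) all(x > 0), y_ok = function(y) TRUE,
      fit = function(x, y) stats::lm(y ~ log(x)),
      coefs = function(b) c(b0 = b[[1]], b1 = b[[2]]),
      predict = function(b, x) b[["b0"]] + b[["b1"]] * log(x)),
    quadratic = list(
      k = 3, x_ok = function(x) TRUE, y_ok = function(y) TRUE,
      fit = function(x, y) stats::lm(y ~ x + I(x^2)),
      coefs = function(b) c(b0 = b[[1]], b1 = b[[2]], b2 = b[[3]]),
      predict = function(b, x) b[["b0"]] + b[["b1"]] * x + b[["b2"]] * x^2),
    composite = list(
      k = 2, x_ok = function(x) TRUE, y_ok = function(y) all(y > 0),
      fit = function(x, y) stats::lm(log(y) ~ x),
      coefs = function(b) c(b0 = exp(b[[1]]), b1 = exp(b[[2]])),
      predict = function(b, x) b[["b0"]] * b[["b1"]]^x),
    power = list(
      k = 2, x_ok = function(x) all(x > 0), y_ok = function(y) all(y > 0),
      fit = function(x, y) stats::lm(log(y) ~ log(x)),
      coefs = function(b) c(b0 = exp(b[[1]]), b1 = b[[2]]),
      predict = function(b, x) b[["b0"]] * x^b[["b1"]]),
    growth = list(
      k = 2, x_ok = function(x) TRUE, y_ok = function(y) all(y > 0),
      fit = function(x, y) stats::lm(log(y) ~ x),
      coefs = function(b) c(b0 = b[[1]], b1 = b[[2]]),
      predict = function(b, x) exp(b[["b0"]] + b[["b1"]] * x)),
    exponential = list(
      k = 2, x_ok = function(x) TRUE, y_ok = function(y) all(y > 0),
      fit = function(x, y) stats::lm(log(y) ~ x),
      coefs = function(b) c(b0 = exp(b[[1]]), b1 = b[[2]]),
      predict = function(b, x) b[["b0"]] * exp(b[["b1"]] * x)),
    logistic = list(
      k = 2, x_ok = function(x) TRUE,
      y_ok = function(y) all(y > 0) && all(y < u),
      fit = function(x, y) stats::lm(log(1 / y - 1 / u) ~ x),
      coefs = function(b) c(b0 = exp(b[[1]]), b1 = exp(b[[2]])),
      predict = function(b, x) 1 / (1 / u + b[["b0"]] * b[["b1"]]^x)),
    stop_bad("unknown curve form: ", form))
}

#' Fit one curve-estimation family to a beds-to-BOR table
#'
#' Fits a single regression family of the classic curve-estimation set
#' (`linear`, `logarithm`, `quadratic`, `composite`, `power`, `growth`,
#' `exponential`, `logistic`) by ordinary least squares; the multiplicative
#' families are log-linearized first, and their fit statistics (R squared,
#' F, degrees of freedom, p-value) are reported on the transformed scale, as
#' the classic procedure does. An original-scale R squared is also recorded
#' for diagnostics.
#'
#' The logistic family is `y = 1 / (1/u + b0 * b1^x)` with a fixed upper
#' bound `u`; the default `u = Inf` corresponds to leaving the bound
#' unspecified, reducing to `1/y = b0 * b1^x`.
#'
#' @param beds numeric predictor vector (bed counts), or a data frame with
#'   columns `beds` and `bor`.
#' @param bor numeric response (BOR fractions); ignored when `beds` is a
#'   data frame.
#' @param form one of the eight family names.
#' @param logistic_u upper bound `u` of the logistic family.
#' @return Object of class `bor_fit`: list with `form`, `coefficients`
#'   (named `b0`, `b1`, and `b2` for the quadratic), `r_squared`, `f_stat`,
#'   `df1`, `df2`, `sig`, `r_squared_original`, `n`.
#' @examples
#' sweeps <- case_study_sweeps()
#' fit_curve(sweeps$W9, form = "quadratic")
#' @seealso [fit_bor_curves()] to fit and rank all families.
#' @export
fit_curve <- function(beds, bor = NULL, form = "quadratic",
                      logistic_u = Inf) {
  if (is.data.frame(beds)) { bor <- beds$bor; beds <- beds$beds }
  form <- match.arg(form, curve_forms)
  fam <- curve_family(form, u = logistic_u)
  x <- as.numeric(beds); y <- as.numeric(bor)
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (length(x) < fam$k + 1)
    stop_bad(form, ": needs at least ", fam$k + 1, " points")
  if (!fam$x_ok(x)) stop_bad(form, ": predictor outside the family's domain")
  if (!fam$y_ok(y)) stop_bad(form, ": response outside the family's domain")
  m <- fam$fit(x, y)
  s <- summary(m)
  b <- fam$coefs(stats::coef(m))
  fstat <- s$fstatistic
  yhat <- fam$predict(b, x)
  r2_orig <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(list(
    form = form,
    coefficients = b,
    r_squared = s$r.squared,
    f_stat = unname(fstat[1]),
    df1 = as.integer(fstat[2]), df2 = as.integer(fstat[3]),
    sig = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared_original = r2_orig,
    logistic_u = if (form == "logistic") logistic_u else NULL,
    n = length(x)), class = "bor_fit")
}

#' @export
print.bor_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<%s fit: R2 = %.3f, F(%d,%d) = %.3f, p = %.3g>\n",
              x$form, x$r_squared, x$df1, x$df2, x$f_stat, x$sig))
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.bor_fit <- function(object, ...) object$coefficients

#' @export
predict.bor_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$beds else newdata
  fam <- curve_family(object$form, u = object$logistic_u %||% Inf)
  fam$predict(object$coefficients, as.numeric(x))
}

#' Fit all curve families and select the best by R squared
#'
#' Fits every family whose domain constraints hold on the data (families
#' violating them, e.g. a multiplicative family with non-positive responses,
#' are skipped with a message), ranks the fits by R squared on the fitting
#' scale, breaking ties in favour of fewer coefficients, and returns the
#' winner together with the full ranking table.
#'
#' @inheritParams fit_curve
#' @param forms families to try (default all eight).
#' @return Object of class `bor_curvefit`: list with `best` (a `bor_fit`),
#'   `fits` (named list of all `bor_fit`s), `table` (ranking data frame with
#'   columns `form`, `r_squared`, `f_stat`, `df1`, `df2`, `sig`, `b0`, `b1`,
#'   `b2`), `n`.
#' @examples
#' cf <- fit_bor_curves(case_study_sweeps()$W9)
#' cf$best$form   # "quadratic"
#' summary(cf)
#' @export
fit_bor_curves <- function(beds, bor = NULL, forms = curve_forms,
                           logistic_u = Inf) {
  if (is.data.frame(beds)) { bor <- beds$bor; beds <- beds$beds }
  if (length(beds) < 4) stop_bad("need at least 4 points")
  forms <- match.arg(forms, curve_forms, several.ok = TRUE)
  fits <- list()
  for (f in forms) {
    res <- tryCatch(fit_curve(beds, bor, f, logistic_u = logistic_u),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", f, ": ", conditionMessage(res))
    } else fits[[f]] <- res
  }
  if (!length(fits)) stop_bad("no curve family could be fitted")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  ncoef <- vapply(fits, function(f) length(f$coefficients), integer(1))
  ord <- order(-r2, ncoef)
  fits <- fits[ord]
  tab <- do.call(rbind, lapply(fits, function(f) {
    b <- f$coefficients
    data.frame(form = f$form, r_squared = f$r_squared, f_stat = f$f_stat,
               df1 = f$df1, df2 = f$df2, sig = f$sig,
               b0 = b[["b0"]], b1 = b[["b1"]],
               b2 = if ("b2" %in% names(b)) b[["b2"]] else NA_real_)
  }))
  rownames(tab) <- NULL
  structure(list(best = fits[[1]], fits = fits, table = tab,
                 n = length(beds)),
            class = "bor_curvefit")
}

#' @export
print.bor_curvefit <- function(x, ...) {
  cat(sprintf("Curve selection over %d point(s): best = %s (R2 = %.3f)\n",
              x$n, x$best$form, x$best$r_squared))
  invisible(x)
}

#' @export
summary.bor_curvefit <- function(object, digits = 3, ...) {
  cat(sprintf("Curve-estimation ranking (%d points), best fit first:\n",
              object$n))
  tab <- object$table
  tab$r_squared <- round(tab$r_squared, 3)
  tab$f_stat <- round(tab$f_stat, 3)
  tab$sig <- signif(tab$sig, 3)
  for (cc in c("b0", "b1", "b2")) tab[[cc]] <- signif(tab[[cc]], digits)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.bor_curvefit <- function(object, ...) object$best$coefficients

#' @export
predict.bor_curvefit <- function(object, newdata, ...)
  predict(object$best, newdata, ...)

#' Quadratic BOR response function
#'
#' The allocation stage models each department's bed occupancy rate as a
#' quadratic in its bed count, `BOR(C) = beta + a C + b C^2`.
#'
#' @param beta,a,b constant, linear and quadratic coefficients.
#' @return Object of class `bor_function`.
#' @examples
#' f <- bor_function(0.895, 0.003, -2.854e-5)
#' evaluate_bor(f, 121)  # 0.8401
#' @export
bor_function <- function(beta, a, b) {
  stopifnot(is.finite(beta), is.finite(a), is.finite(b))
  structure(list(beta = beta, a = a, b = b), class = "bor_function")
}

#' @export
print.bor_function <- function(x, ...) {
  cat(sprintf("BOR(C) = %.6g %+.6g C %+.6g C^2\n", x$beta, x$a, x$b))
  invisible(x)
}

#' Convert a quadratic curve fit to a BOR response function
#'
#' The allocation model assumes a quadratic beds-to-BOR relationship, so
#' only quadratic fits can be exported; other families raise an error.
#'
#' @param fit a `bor_fit` or `bor_curvefit` whose (best) form is
#'   `"quadratic"`.
#' @return A [bor_function()] with unrounded coefficients.
#' @export
as_bor_function <- function(fit) {
  if (inherits(fit, "bor_curvefit")) fit <- fit$best
  stopifnot(inherits(fit, "bor_fit"))
  if (fit$form != "quadratic")
    stop_bad("allocation requires a quadratic BOR function; best fit is '",
             fit$form, "'")
  b <- fit$coefficients
  bor_function(b[["b0"]], b[["b1"]], b[["b2"]])
}

#' Evaluate a quadratic BOR response function
#'
#' Returns `beta + a * beds + b * beds^2`, unclamped: values outside
#' `[0, 1]` are legal (occupancy above 1 means corridor beds) and are
#' reported with a message when encountered.
#'
#' @param fn a [bor_function()].
#' @param beds positive bed count(s).
#' @param warn report values outside `[0, 1]` (default `FALSE`).
#' @return Numeric vector of BOR values.
#' @export
evaluate_bor <- function(fn, beds, warn = FALSE) {
  stopifnot(inherits(fn, "bor_function"))
  if (any(beds < 1)) stop_bad("beds must be >= 1")
  v <- fn$beta + fn$a * beds + fn$b * beds^2
  if (warn && any(v < 0 | v > 1))
    message("BOR value(s) outside [0, 1]: ",
            paste(signif(v[v < 0 | v > 1], 4), collapse = ", "))
  v
}
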