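# Environmental driver regressions: the functional forms relating monthly or
# annual fluxes to water table, WFPS, temperature, soil respiration and
# mineral-N covariates, including class-binned fitting.

# Offset (g N ha-1 day-1) added before log-transforming N2O fluxes so that
# the small uptakes observed in the field (down to -4) stay in the domain.
LN_FLUX_OFFSET <- 4

#' Construct a driver model from known coefficients
#'
#' Builds a `driver_model` directly from published or assumed coefficients,
#' for prediction and as a generative truth in simulations. [fit_driver_model()]
#' returns the same class with fitted values.
#'
#' @param coefficients Named vector of slopes; names are covariate columns
#'   (for `form = "quadratic"` the two names are the covariate and
#'   `"<covariate>^2"`).
#' @param intercept Intercept.
#' @param form `"linear"` (multiple linear), `"quadratic"` (single covariate
#'   plus its square), `"exponential"` (log response, fitted log-linear and
#'   back-transformed by `exp`), or `"logarithmic"` (response vs
#'   `log(x + log_shift)`).
#' @param transform `"identity"` or `"ln_offset"` — the response is
#'   `log(flux + offset)` and predictions back-transform as
#'   `exp(eta) - offset`.
#' @param offset Offset of the `ln_offset` transform, default
#'   `LN_FLUX_OFFSET` (4).
#' @param log_shift Shift inside the logarithm of the `"logarithmic"` form.
#' @param coef_se,intercept_se,r2,p_values,n Optional fit statistics.
#' @return Object of class `driver_model`.
#' @export
driver_model <- function(coefficients, intercept,
                         form = c("linear", "quadratic", "exponential",
                                  "logarithmic"),
                         transform = c("identity", "ln_offset"),
                         offset = LN_FLUX_OFFSET, log_shift = 0,
                         coef_se = NULL, intercept_se = NULL, r2 = NA_real_,
                         p_values = NULL, n = NA_integer_) {
  form <- match.arg(form)
  transform <- match.arg(transform)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            is.numeric(intercept), length(intercept) == 1L)
  structure(list(coefficients = coefficients, intercept = intercept,
                 form = form, transform = transform, offset = offset,
                 log_shift = log_shift, coef_se = coef_se,
                 intercept_se = intercept_se, r2 = r2, p_values = p_values,
                 n = n),
            class = "driver_model")
}

# Covariate columns entering the linear predictor, in model-term order.
.dm_terms <- function(object) {
  if (object$form == "quadratic")
    unique(sub("\\^2$", "", names(object$coefficients)))
  else names(object$coefficients)
}

#' Fit a driver model by ordinary least squares
#'
#' Fits one of the supported functional forms to a merged covariate + flux
#' table. The `ln_offset` response transform regresses `log(flux + offset)`;
#' the `exponential` form regresses `log(response)` on the covariates and
#' back-transforms predictions with `exp`. Rows with missing values in the
#' response or any term are dropped (complete-case).
#'
#' @param data Data frame holding the response and covariate columns.
#' @param response Name of the response (flux) column.
#' @param terms Character vector of covariate columns (a single covariate
#'   for the quadratic and logarithmic forms).
#' @param weights Optional observation weights (e.g. bin counts).
#' @inheritParams driver_model
#' @return A `driver_model` with coefficients, SEs, R^2, two-sided p-values
#'   and n.
#' @export
fit_driver_model <- function(data, response, terms,
                             form = c("linear", "quadratic", "exponential",
                                      "logarithmic"),
                             transform = c("identity", "ln_offset"),
                             offset = LN_FLUX_OFFSET, log_shift = 0,
                             weights = NULL) {
  form <- match.arg(form)
  transform <- match.arg(transform)
  stopifnot(response %in% names(data), all(terms %in% names(data)))
  if (form %in% c("quadratic", "logarithmic") && length(terms) != 1L)
    stop(form, " form takes exactly one covariate")

  keep <- stats::complete.cases(data[c(response, terms)])
  d <- data[keep, , drop = FALSE]
  y <- d[[response]]

  if (transform == "ln_offset") {
    bad <- which(y <= -offset)
    if (length(bad))
      stop("ln(flux + ", offset, ") undefined for rows: ",
           paste(utils::head(which(keep)[bad], 10), collapse = ", "))
    y <- log(y + offset)
  }
  if (form == "exponential") {
    if (any(y <= 0))
      stop("exponential form requires a positive response after transform")
    y <- log(y)
  }

  X <- switch(form,
    linear = ,
    exponential = as.matrix(d[terms]),
    quadratic = {
      x <- d[[terms]]
      m <- cbind(x, x^2)
      colnames(m) <- c(terms, paste0(terms, "^2"))
      m
    },
    logarithmic = {
      x <- d[[terms]] + log_shift
      if (any(x <= 0)) stop("logarithmic form needs covariate + log_shift > 0")
      m <- cbind(log(x))
      colnames(m) <- paste0("log(", terms, ")")
      m
    })

  df_fit <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  fit <- if (is.null(weights)) stats::lm(fml, data = df_fit)
         else stats::lm(fml, data = df_fit, weights = weights)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient fit; collinear terms: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))

  sm <- summary(fit)
  ct <- sm$coefficients
  slopes <- ct[-1, 1]
  names(slopes) <- colnames(X)
  r2 <- if (stats::var(y) > 0) sm$r.squared else 0

  driver_model(coefficients = slopes, intercept = ct[1, 1], form = form,
               transform = transform, offset = offset, log_shift = log_shift,
               coef_se = stats::setNames(ct[-1, 2], colnames(X)),
               intercept_se = ct[1, 2], r2 = r2,
               p_values = stats::setNames(ct[, 4],
                                          c("(Intercept)", colnames(X))),
               n = length(y))
}

#' Predict fluxes from a driver model
#'
#' Evaluates the model's linear predictor on new covariates and applies the
#' back-transform of its form and response spec (`exp` for the exponential
#' form, `exp(eta) - offset` for the `ln_offset` response).
#'
#' @param object A `driver_model`.
#' @param newdata Data frame (or named list) providing every model term.
#' @param ... Unused.
#' @return Numeric vector of predicted fluxes.
#' @export
predict.driver_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  need <- .dm_terms(object)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("missing covariates: ", paste(miss, collapse = ", "))
  eta <- object$intercept + switch(object$form,
    linear = ,
    exponential = {
      as.vector(as.matrix(newdata[names(object$coefficients)]) %*%
                  object$coefficients)
    },
    quadratic = {
      x <- newdata[[need]]
      b <- object$coefficients
      b[[need]] * x + b[[paste0(need, "^2")]] * x^2
    },
    logarithmic = {
      x <- newdata[[need]] + object$log_shift
      unname(object$coefficients[1]) * log(x)
    })
  if (object$form == "exponential") eta <- exp(eta)
  if (object$transform == "ln_offset") exp(eta) - object$offset else eta
}

#' @export
coef.driver_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.driver_model <- function(x, ...) {
  resp <- if (x$transform == "ln_offset")
    sprintf("ln(flux + %g)", x$offset) else "flux"
  if (x$form == "exponential") resp <- paste0("ln(", resp, ")")
  rhs <- paste(sprintf("%.4g x %s", x$coefficients, names(x$coefficients)),
               collapse = " + ")
  cat(sprintf("Driver model (%s): %s = %s + %.4g\n", x$form, resp, rhs,
              x$intercept))
  if (!is.na(x$r2)) cat(sprintf("  R2 = %.3f, n = %s\n", x$r2, x$n))
  invisible(x)
}

#' Bin covariates into classes and fit on bin means
#'
#' Reproduces the across-site class-binned fitting procedure: observations
#' are grouped into fixed-width classes of the covariate (e.g. 10% WFPS,
#' 10 cm water-table, 1 degC temperature intervals), per-bin response means
#' are computed first, and the model is fitted to the bin means (unweighted
#' by default; `weighted = TRUE` weights by bin count).
#'
#' @param data Data frame with the response and covariate.
#' @param response,covariate Column names.
#' @param width Bin width in covariate units.
#' @param weighted Weight the fit by bin counts? Default `FALSE`.
#' @inheritParams fit_driver_model
#' @return List with `model` (a `driver_model` fitted to bin means) and
#'   `bins` (data frame: bin_lo, bin_mid, x_mean, y_mean, y_se, n).
#' @export
bin_and_fit <- function(data, response, covariate, width,
                        form = c("linear", "quadratic", "exponential",
                                 "logarithmic"),
                        transform = c("identity", "ln_offset"),
                        offset = LN_FLUX_OFFSET, log_shift = 0,
                        weighted = FALSE) {
  form <- match.arg(form)
  transform <- match.arg(transform)
  keep <- stats::complete.cases(data[c(response, covariate)])
  x <- data[[covariate]][keep]
  y <- data[[response]][keep]
  lo <- floor(x / width) * width
  parts <- split(data.frame(x, y), lo)
  if (length(parts) < 3L)
    stop("need at least 3 non-empty bins, got ", length(parts))
  bins <- do.call(rbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    data.frame(bin_lo = as.numeric(nm), bin_mid = as.numeric(nm) + width / 2,
               x_mean = mean(p$x), y_mean = mean(p$y),
               y_se = if (nrow(p) > 1) stats::sd(p$y) / sqrt(nrow(p))
                      else NA_real_,
               n = nrow(p))
  }))
  fit_df <- stats::setNames(bins[c("x_mean", "y_mean")],
                            c(covariate, response))
  model <- fit_driver_model(fit_df, response, covariate, form = form,
                            transform = transform, offset = offset,
                            log_shift = log_shift,
                            weights = if (weighted) bins$n else NULL)
  list(model = model, bins = bins)
}

#' Published driver-model catalog
#'
#' Loads the bundled catalog of monthly-flux driver regressions (response
#' spec, functional form, covariates, published coefficients, R^2 and n)
#' used as regression-test fixtures and as generative truths for the
#' synthetic campaign.
#'
#' @return Data frame, one row per catalogued equation.
#' @export
driver_catalog <- function() {
  path <- system.file("extdata", "driver_catalog.csv", package = "peatflux",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a driver model from a catalog entry
#'
#' @param eq Equation number in [driver_catalog()].
#' @return A `driver_model` with the published coefficients.
#' @export
catalog_model <- function(eq) {
  cat_df <- driver_catalog()
  row <- cat_df[cat_df$eq == eq, , drop = FALSE]
  if (nrow(row) != 1L) stop("no catalog entry for eq ", eq)
  terms <- strsplit(row$terms, ";")[[1]]
  coefs <- as.numeric(strsplit(row$coefficients, ";")[[1]])
  ses <- as.numeric(strsplit(row$ses, ";")[[1]])
  driver_model(stats::setNames(coefs, terms), row$intercept,
               form = row$form, transform = row$response,
               coef_se = stats::setNames(ses, terms),
               intercept_se = row$intercept_se, r2 = row$r2, n = row$n)
}
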