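#' The four-parameter logistic dose-response model
#'
#' Evaluates the 4PL ("log(inhibitor) vs. response -- variable slope")
#' sigmoid
#' \deqn{y(d) = bottom + \frac{top - bottom}{1 + 10^{\,hillslope\,(\log_{10}
#' ED_{50} - \log_{10} d)}}}{y(d) = bottom + (top - bottom) /
#' (1 + 10^(hillslope * (log10(ED50) - log10(d))))}
#' so that a decreasing (inhibition) curve carries a negative hillslope and
#' the response at dose 0 is the `top` asymptote. At `d = ED50` the response
#' is exactly `(top + bottom) / 2`.
#'
#' @param dose Vector of doses (same units as the ED50, conventionally uM);
#'   dose 0 is evaluated as the model limit.
#' @param bottom,top Lower and upper response asymptotes (% of vehicle
#'   control).
#' @param log10_ed50 Base-10 log of the ED50.
#' @param hillslope Steepness; negative for decreasing curves.
#' @return Numeric vector of responses.
#' @export
#' @examples
#' fourpl(c(0, 10, 1e6), bottom = 0, top = 100, log10_ed50 = 1, hillslope = -1)
fourpl <- function(dose, bottom, top, log10_ed50, hillslope) {
  bottom + (top - bottom) / (1 + 10^(hillslope * (log10_ed50 - log10(dose))))
}

# extract the four parameters from a fit, a fourpl_params object, or a
# named numeric vector
par4 <- function(object) {
  p <- if (inherits(object, c("fourpl_fit", "fourpl_params"))) {
    object$coefficients
  } else if (is.numeric(object) && !is.null(names(object))) {
    object
  } else {
    stop_input("expected a `fourpl_fit`, `fourpl_params`, or named numeric vector")
  }
  need <- c("bottom", "top", "log10_ed50", "hillslope")
  if (!all(need %in% names(p))) {
    stop_input(paste0("missing 4PL parameters: ",
                      paste(setdiff(need, names(p)), collapse = ", ")))
  }
  p[need]
}

#' Bundle known 4PL parameters
#'
#' Builds a lightweight parameter object that [predict_effect()],
#' [inverse_dose()] and the additivity functions accept wherever a fitted
#' curve is accepted. Used for ground-truth curves in simulations.
#'
#' @param bottom,top Response asymptotes (% control); `top` must exceed
#'   `bottom`.
#' @param ed50 Dose giving the half-span response, in uM (> 0).
#' @param hillslope Slope; negative for decreasing curves.
#' @return An object of class `fourpl_params`.
#' @export
#' @examples
#' p <- fourpl_params(bottom = 0, top = 100, ed50 = 63.8, hillslope = -2)
#' predict_effect(p, 63.8)
fourpl_params <- function(bottom, top, ed50, hillslope) {
  if (!is.finite(ed50) || ed50 <= 0) stop_input("`ed50` must be finite and > 0")
  if (!is.finite(bottom) || !is.finite(top) || top <= bottom) {
    stop_input("`top` must exceed `bottom` and both must be finite")
  }
  structure(
    list(coefficients = c(bottom = bottom, top = top,
                          log10_ed50 = log10(ed50), hillslope = hillslope)),
    class = "fourpl_params"
  )
}

validate_dose_response <- function(data) {
  need <- c("dose_um", "response_pct")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_input("`data` must be a data frame with columns `dose_um` and `response_pct`")
  }
  if (nrow(data) < 5) {
    stop_input(sprintf("need at least 5 observations to fit a 4PL; got %d", nrow(data)))
  }
  if (!all(is.finite(data$dose_um)) || any(data$dose_um < 0)) {
    stop_input("all doses must be finite and >= 0")
  }
  if (!all(is.finite(data$response_pct))) {
    stop_input("all responses must be finite")
  }
  if (length(unique(data$dose_um[data$dose_um > 0])) < 4) {
    stop_input("need at least 4 distinct nonzero doses")
  }
  invisible(data)
}

# deterministic derivative-free warm start: asymptotes from the data range,
# log10_ed50 by interpolating the dose at half-span, hillslope from a
# logit-linear regression of the suppressed fraction on log10 dose
init_4pl <- function(dose, response) {
  top0 <- max(response)
  bot0 <- min(response)
  span <- top0 - bot0
  pos <- dose > 0
  x <- log10(dose[pos])
  y <- response[pos]
  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  mid <- bot0 + span / 2
  e0 <- tryCatch(approx(as.numeric(means), xs, xout = mid, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(e0)) e0 <- stats::median(x)
  frac <- pmin(pmax((top0 - y) / span, 0.01), 0.99)
  sl <- coef(lm(log(frac / (1 - frac)) ~ x))[[2]]
  h0 <- -sl / log(10)
  if (!is.finite(h0) || abs(h0) < 1e-3) h0 <- if (sl >= 0) -1 else 1
  c(bottom = bot0, top = top0, log10_ed50 = e0, hillslope = h0)
}

# top > bottom is a class invariant; the 4PL is unchanged under
# (bottom, top, h) -> (top, bottom, -h), so flip a swapped optimum back
canonicalize_4pl <- function(est, vc) {
  if (est[["top"]] >= est[["bottom"]]) return(list(est = est, vcov = vc))
  tr <- diag(4)
  dimnames(tr) <- list(names(est), names(est))
  tr[] <- 0
  tr["bottom", "top"] <- 1
  tr["top", "bottom"] <- 1
  tr["log10_ed50", "log10_ed50"] <- 1
  tr["hillslope", "hillslope"] <- -1
  est2 <- drop(tr %*% est)
  names(est2) <- names(est)
  list(est = est2, vcov = tr %*% vc %*% t(tr))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model ([fourpl()]) to individual replicate
#' observations, via Levenberg-Marquardt ([minpack.lm::nls.lm()]) from a
#' deterministic data-driven warm start. Parameter covariance is taken from
#' the Jacobian at the optimum and 95% confidence intervals are Wald
#' intervals with a Student-t quantile on `n - 4` residual degrees of
#' freedom. Replicates are fit as individual points, not averaged.
#'
#' @param data Data frame with columns `dose_um` and `response_pct`
#'   (additional columns such as `compound` and `replicate` are carried
#'   along). At least 5 observations over at least 4 distinct nonzero doses.
#' @param init Optional named numeric vector of starting values
#'   (`bottom`, `top`, `log10_ed50`, `hillslope`); defaults to the
#'   data-driven warm start.
#' @param level Confidence level for the parameter intervals (default 0.95).
#' @return An object of class `fourpl_fit`: a list with `coefficients`,
#'   `vcov`, `ci` (tibble of per-parameter intervals), `ed50`, `sigma`,
#'   `n_obs`, `residual_df`, `fitted`, `residuals` and the input `data`.
#'   Supports [tidy()], [glance()], [augment()], [predict_effect()],
#'   [inverse_dose()] and [autoplot()].
#' @export
#' @examples
#' d <- simulate_monotherapy(ed50 = 40, hillslope = -2, noise_sd = 0, seed = 1)
#' fit <- fit_4pl(d)
#' glance(fit)$ed50
fit_4pl <- function(data, init = NULL, level = 0.95) {
  validate_dose_response(data)
  dose <- data$dose_um
  response <- data$response_pct
  if (diff(range(response)) <= .Machine$double.eps^0.5 * max(1, abs(response[1]))) {
    stop_fit("responses have zero span; the 4PL is unidentifiable",
             diagnostics = list(range = range(response)))
  }
  start <- if (is.null(init)) init_4pl(dose, response) else par4(init)

  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = function(p) response - fourpl(dose, p[["bottom"]], p[["top"]],
                                         p[["log10_ed50"]], p[["hillslope"]]),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)
    )),
    error = function(e) {
      stop_fit(paste0("4PL fit failed: ", conditionMessage(e)),
               diagnostics = list(start = start, message = conditionMessage(e)))
    }
  )
  if (!res$info %in% 1:4) {
    stop_fit(paste0("4PL fit did not converge: ", res$message),
             diagnostics = list(start = start, info = res$info,
                                niter = res$niter, message = res$message))
  }

  est <- res$par
  n <- length(response)
  rdf <- n - 4L
  sigma2 <- res$deviance / rdf
  # covariance from the Gauss-Newton Hessian (J'J) at the optimum;
  # zero-residual fits (e.g. refitting a noiseless construction) simply
  # collapse the CIs onto the point estimates
  vc <- tryCatch(sigma2 * solve(res$hessian),
                 error = function(e) matrix(NA_real_, 4, 4))
  dimnames(vc) <- list(names(est), names(est))
  can <- canonicalize_4pl(est, vc)
  est <- can$est
  vc <- can$vcov

  fitted <- fourpl(dose, est[["bottom"]], est[["top"]],
                   est[["log10_ed50"]], est[["hillslope"]])
  resid <- response - fitted
  sigma <- sqrt(sigma2)
  se <- sqrt(pmax(diag(vc), 0))
  tq <- qt(1 - (1 - level) / 2, df = rdf)
  ci <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - tq * se),
    conf.high = unname(est + tq * se)
  )

  structure(
    list(
      coefficients = est,
      vcov = vc,
      ci = ci,
      level = level,
      ed50 = 10^est[["log10_ed50"]],
      sigma = sigma,
      rss = sum(resid^2),
      n_obs = n,
      residual_df = rdf,
      fitted = fitted,
      residuals = resid,
      data = as_tibble(data),
      compound = if ("compound" %in% names(data)) data$compound[[1]] else NA_character_
    ),
    class = "fourpl_fit"
  )
}

#' Predict the response of a fitted 4PL at given doses
#'
#' @param fit A `fourpl_fit` or [fourpl_params()] object.
#' @param dose Vector of doses in uM, all >= 0; dose 0 returns the
#'   zero-dose asymptote (`top` for a decreasing curve).
#' @return Numeric vector of responses (% control).
#' @export
predict_effect <- function(fit, dose) {
  p <- par4(fit)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop_input("`dose` must be finite and >= 0")
  }
  fourpl(dose, p[["bottom"]], p[["top"]], p[["log10_ed50"]], p[["hillslope"]])
}

#' Invert a fitted 4PL: dose producing a given percent effect
#'
#' "Percent effect" is the percent of the fitted span (`top - bottom`)
#' suppressed, so `effect_pct = 50` returns the ED50 exactly. The target
#' response is `top - (effect_pct/100) * (top - bottom)` and the closed-form
#' inverse of [fourpl()] is used, so
#' `predict_effect(fit, inverse_dose(fit, e))` round-trips to machine
#' precision.
#'
#' @param fit A `fourpl_fit` or [fourpl_params()] object.
#' @param effect_pct Vector of percent-effect levels, each strictly inside
#'   (0, 100); the asymptotes themselves are unreachable at finite dose.
#' @return Numeric vector of doses in uM.
#' @export
#' @examples
#' p <- fourpl_params(0, 100, ed50 = 10, hillslope = -1)
#' inverse_dose(p, 50)
inverse_dose <- function(fit, effect_pct) {
  p <- par4(fit)
  if (any(!is.finite(effect_pct)) || any(effect_pct <= 0) || any(effect_pct >= 100)) {
    stop_domain(
      "`effect_pct` must lie strictly inside the open interval (0, 100); the asymptotes are reached only in the zero/infinite dose limit"
    )
  }
  remaining <- 1 - effect_pct / 100        # fraction of the span not suppressed
  x <- p[["log10_ed50"]] - log10(1 / remaining - 1) / p[["hillslope"]]
  10^x
}

# methods --------------------------------------------------------------------

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("4PL dose-response fit",
      if (!is.na(x$compound)) paste0(" [", x$compound, "]"), "\n", sep = "")
  cat(sprintf("  n = %d observations, residual df = %d, sigma = %.3g\n",
              x$n_obs, x$residual_df, x$sigma))
  cat(sprintf("  ED50 = %.4g uM, hillslope = %.3g\n",
              x$ed50, x$coefficients[["hillslope"]]))
  print(x$ci)
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) object$coefficients

#' @export
vcov.fourpl_fit <- function(object, ...) object$vcov

#' Tidy a 4PL fit into a per-parameter tibble
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.fourpl_fit <- function(x, ...) x$ci

#' One-row summary of a 4PL fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `ed50`, `hillslope`, `top`, `bottom`,
#'   `sigma`, `rss`, `n_obs`, `df.residual`.
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(
    ed50 = x$ed50,
    hillslope = x$coefficients[["hillslope"]],
    top = x$coefficients[["top"]],
    bottom = x$coefficients[["bottom"]],
    sigma = x$sigma,
    rss = x$rss,
    n_obs = x$n_obs,
    df.residual = x$residual_df
  )
}

#' Augment dose-response data with 4PL fitted values and residuals
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return The fitting data with `.fitted` and `.resid` columns appended.
#' @export
augment.fourpl_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' Plot a fitted 4PL curve over its data
#'
#' @param object A `fourpl_fit`.
#' @param n Number of curve evaluation points (default 200).
#' @param ... Unused.
#' @return A ggplot: observed responses and the fitted curve on a log10
#'   dose axis (zero doses are dropped from the display, not the fit).
#' @export
autoplot.fourpl_fit <- function(object, n = 200, ...) {
  d <- dplyr::filter(object$data, .data$dose_um > 0)
  rng <- range(d$dose_um)
  grid <- tibble(
    dose_um = 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  )
  grid$response_pct <- predict_effect(object, grid$dose_um)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_um, y = .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dose (uM)", y = "response (% of control)",
      title = if (!is.na(object$compound)) object$compound else NULL
    ) +
    ggplot2::theme_minimal()
}
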