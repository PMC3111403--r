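#' Theoretical additive total dose for a fixed-ratio mixture
#'
#' Solves the Loewe additivity relation for a mixture of composition
#' `(fraction_a, fraction_b)` at a given percent effect: the total dose `Z`
#' satisfying
#' \deqn{\frac{f_a Z}{D_{x,a}} + \frac{f_b Z}{D_{x,b}} = 1}
#' where `Dx` are the equi-effective monotherapy doses from
#' [inverse_dose()]. Closed form: `Z = 1 / (f_a/Dx_a + f_b/Dx_b)`. At 50%
#' effect with equal-potency fractions this reduces to the arithmetic mean
#' of the two ED50s.
#'
#' @param effect_pct Percent-effect level(s), strictly inside (0, 100) and
#'   achievable by both curves.
#' @param fit_a,fit_b Monotherapy curves (`fourpl_fit` or [fourpl_params()]).
#' @param fraction_a,fraction_b Mixture dose fractions; must sum to 1.
#' @return Numeric vector of additive total doses (uM).
#' @export
additive_total_dose <- function(effect_pct, fit_a, fit_b,
                                fraction_a, fraction_b = 1 - fraction_a) {
  if (abs(fraction_a + fraction_b - 1) > 1e-12) {
    stop_input("fractions must sum to 1")
  }
  dxa <- inverse_dose(fit_a, effect_pct)
  dxb <- inverse_dose(fit_b, effect_pct)
  1 / (fraction_a / dxa + fraction_b / dxb)
}

#' Build the theoretical additive dose-response curve
#'
#' Constructs the Tallarida theoretical additive curve for a fixed-ratio
#' mixture: over a grid of percent-effect levels, computes the Loewe
#' additive total dose ([additive_total_dose()]), places each grid effect
#' back on a % control response scale, and fits a 4PL to the resulting
#' (dose, response) points by least squares. The additive isobole is not
#' exactly 4PL when the two hillslopes differ, so the fit's maximum
#' absolute residual is reported.
#'
#' The construction is deterministic given the two monotherapy curves, so
#' the refit's regression covariance alone would be degenerate (near-zero
#' residuals). When both inputs are fitted curves carrying a covariance,
#' their parameter uncertainty is propagated into the additive refit by a
#' numerical delta method: the Jacobian of the refit parameters with
#' respect to the eight monotherapy parameters is estimated by finite
#' differences, and the propagated covariance drives the additive curve's
#' confidence intervals, with a Student-t quantile on the summed
#' monotherapy residual degrees of freedom.
#'
#' @inheritParams additive_total_dose
#' @param effect_grid Percent-effect levels (default `1:99`).
#' @param asymptotes How the additive curve's response scale is anchored:
#'   `"average"` (default) uses the mean of the two monotherapy tops and
#'   bottoms, `"a"` or `"b"` adopts one compound's asymptotes.
#' @param propagate_uncertainty Propagate monotherapy-fit covariance into
#'   the additive fit's CIs (default TRUE; skipped automatically when an
#'   input is a bare [fourpl_params()] object with no covariance).
#' @return An `additive_curve`: list with `grid` (tibble `effect_pct`,
#'   `total_dose_um`, `response_pct`), `fit` (the 4PL refit, with
#'   propagated covariance where available), `max_abs_residual`, and the
#'   fractions.
#' @export
build_additive_curve <- function(fit_a, fit_b, fraction_a,
                                 fraction_b = 1 - fraction_a,
                                 effect_grid = 1:99,
                                 asymptotes = c("average", "a", "b"),
                                 propagate_uncertainty = TRUE) {
  asymptotes <- match.arg(asymptotes)
  if (any(effect_grid <= 0) || any(effect_grid >= 100)) {
    stop_domain("`effect_grid` levels must lie strictly inside (0, 100)")
  }

  construct <- function(pa, pb) {
    top <- switch(asymptotes,
                  average = (pa[["top"]] + pb[["top"]]) / 2,
                  a = pa[["top"]], b = pb[["top"]])
    bottom <- switch(asymptotes,
                     average = (pa[["bottom"]] + pb[["bottom"]]) / 2,
                     a = pa[["bottom"]], b = pb[["bottom"]])
    z <- additive_total_dose(effect_grid, pa, pb, fraction_a, fraction_b)
    ok <- is.finite(z) & z > 0
    tibble(
      effect_pct = effect_grid[ok],
      total_dose_um = z[ok],
      response_pct = top - effect_grid[ok] / 100 * (top - bottom)
    )
  }

  pa <- par4(fit_a)
  pb <- par4(fit_b)
  grid <- construct(pa, pb)
  if (nrow(grid) < 5) {
    stop_fit("fewer than 5 valid additive grid points; cannot construct curve")
  }
  fit <- fit_4pl(tibble(compound = "theoretical additive",
                        dose_um = grid$total_dose_um,
                        response_pct = grid$response_pct))

  both_fitted <- inherits(fit_a, "fourpl_fit") && inherits(fit_b, "fourpl_fit")
  if (propagate_uncertainty && both_fitted &&
      all(is.finite(fit_a$vcov)) && all(is.finite(fit_b$vcov))) {
    refit_par <- function(pa, pb) {
      g <- construct(pa, pb)
      coef(fit_4pl(tibble(dose_um = g$total_dose_um,
                          response_pct = g$response_pct),
                   init = fit$coefficients))
    }
    jac <- function(p_this, p_other, this_first, vc) {
      se <- sqrt(pmax(diag(vc), 0))
      h <- pmax(0.05 * se, 1e-4)
      J <- matrix(0, 4, 4)
      for (k in 1:4) {
        pk <- p_this
        pk[k] <- pk[k] + h[k]
        pert <- if (this_first) refit_par(pk, p_other) else refit_par(p_other, pk)
        J[, k] <- (pert - fit$coefficients) / h[k]
      }
      J
    }
    Ja <- jac(pa, pb, TRUE, fit_a$vcov)
    Jb <- jac(pb, pa, FALSE, fit_b$vcov)
    v_prop <- Ja %*% fit_a$vcov %*% t(Ja) + Jb %*% fit_b$vcov %*% t(Jb)
    vc <- fit$vcov + v_prop
    dimnames(vc) <- dimnames(fit$vcov)
    rdf <- fit_a$residual_df + fit_b$residual_df
    se <- sqrt(pmax(diag(vc), 0))
    tq <- qt(1 - (1 - fit$level) / 2, df = rdf)
    est <- fit$coefficients
    fit$vcov <- vc
    fit$residual_df <- rdf
    fit$ci <- tibble(
      term = names(est), estimate = unname(est), std.error = unname(se),
      conf.low = unname(est - tq * se), conf.high = unname(est + tq * se)
    )
  }

  structure(
    list(grid = grid, fit = fit,
         max_abs_residual = max(abs(fit$residuals)),
         fraction_a = fraction_a, fraction_b = fraction_b),
    class = "additive_curve"
  )
}

#' @export
print.additive_curve <- function(x, ...) {
  cat(sprintf(
    "Theoretical additive curve (fractions %.3f:%.3f)\n  %d grid points, refit ED50 = %.4g uM, hillslope = %.3g, max |resid| = %.3g\n",
    x$fraction_a, x$fraction_b, nrow(x$grid), x$fit$ed50,
    x$fit$coefficients[["hillslope"]], x$max_abs_residual
  ))
  invisible(x)
}

#' @export
#' @rdname build_additive_curve
#' @param x An `additive_curve`.
#' @param ... Unused.
tidy.additive_curve <- function(x, ...) x$grid

#' Loewe Combination Index for a combination dose
#'
#' For a combination delivering component doses `(d1, d2)` that achieves
#' percent effect `x`, the Combination Index is
#' \deqn{CI = d_1 / D_{x,1} + d_2 / D_{x,2}}
#' where `Dx` are the monotherapy doses producing the same effect. CI < 1
#' indicates synergy, CI = 1 Loewe additivity, CI > 1 antagonism.
#'
#' @param d1,d2 Component doses in the mixture (uM), >= 0.
#' @param fit_a,fit_b Monotherapy curves (`fourpl_fit` or
#'   [fourpl_params()]); `fit_a` corresponds to `d1`.
#' @param effect_pct Percent effect achieved (may be a vector matching
#'   `d1`/`d2`), strictly inside (0, 100).
#' @return A tibble of class `combination_index` with columns `effect_pct`,
#'   `d1_um`, `d2_um`, `Dx1_um`, `Dx2_um`, `ci`, `call` (synergistic /
#'   additive / antagonistic by the sign of `ci - 1`).
#' @export
combination_index <- function(d1, d2, fit_a, fit_b, effect_pct) {
  if (any(d1 < 0) || any(d2 < 0)) stop_input("component doses must be >= 0")
  dx1 <- inverse_dose(fit_a, effect_pct)
  dx2 <- inverse_dose(fit_b, effect_pct)
  ci <- d1 / dx1 + d2 / dx2
  out <- tibble(
    effect_pct = effect_pct, d1_um = d1, d2_um = d2,
    Dx1_um = dx1, Dx2_um = dx2, ci = ci,
    call = dplyr::case_when(ci < 1 ~ "synergistic",
                            ci > 1 ~ "antagonistic",
                            TRUE ~ "additive")
  )
  class(out) <- c("combination_index", class(out))
  out
}

#' Compare an observed mixture curve with its theoretical additive curve
#'
#' Calls the interaction for a fixed-ratio combination by (i) flagging
#' non-overlap of the 95% confidence intervals for `log10_ed50` and
#' `hillslope` between the actual mixture fit and the additive refit, and
#' (ii) computing the Combination Index at the actual mixture's ED50, with
#' the mixture decomposed by the design's exact fractions. A verdict other
#' than "additive" requires a significant (non-overlapping) parameter
#' shift; its direction is taken from the Combination Index (CI < 1
#' synergistic, CI > 1 subadditive/antagonistic; a CI of exactly 1 falls
#' back on whether the actual curve is shallower than additive, i.e. has a
#' wider effective dose span).
#'
#' @param fit_actual 4PL fit of the observed mixture data.
#' @param fit_additive 4PL fit of the theoretical additive curve (an
#'   `additive_curve` is also accepted).
#' @param design The `fixed_ratio_design` (or fraction pair) used for the
#'   mixture; supplies the decomposition and, at 50% effect, the
#'   monotherapy ED50s.
#' @param fit_a,fit_b Optional monotherapy fits; required when
#'   `effect_for_ci` is not 50 and `design` carries no curves.
#' @param effect_for_ci Percent effect at which the CI is evaluated
#'   (default 50, i.e. at the ED50s).
#' @return A `synergy_report`: list with both fits, the parameter
#'   comparison tibble (`comparison`), `ci_at_ed50`
#'   (a [combination_index()] row) and `verdict` in
#'   {"synergistic", "additive", "subadditive/antagonistic"}.
#' @export
compare_curves <- function(fit_actual, fit_additive, design,
                           fit_a = NULL, fit_b = NULL, effect_for_ci = 50) {
  if (inherits(fit_additive, "additive_curve")) fit_additive <- fit_additive$fit
  if (inherits(design, "fixed_ratio_design")) {
    fa <- design$fraction_a
    fb <- design$fraction_b
    if (is.null(fit_a) && !is.null(design$ed50_a) && effect_for_ci == 50) {
      # at 50% effect the equi-effective monotherapy doses are the ED50s
      fit_a <- fourpl_params(0, 100, design$ed50_a, -1)
      fit_b <- fourpl_params(0, 100, design$ed50_b, -1)
    }
  } else if (is.numeric(design) && length(design) == 2) {
    fa <- design[[1]]
    fb <- design[[2]]
  } else {
    stop_input("`design` must be a fixed_ratio_design or a pair of fractions")
  }
  if (is.null(fit_a) || is.null(fit_b)) {
    stop_input("monotherapy curves are required (pass `fit_a`/`fit_b`, or a design built from ED50s with effect_for_ci = 50)")
  }

  cmp <- dplyr::inner_join(
    dplyr::rename(tidy(fit_actual), actual = "estimate",
                  actual.low = "conf.low", actual.high = "conf.high"),
    dplyr::rename(tidy(fit_additive), additive = "estimate",
                  additive.low = "conf.low", additive.high = "conf.high"),
    by = "term", suffix = c("", ".additive")
  )
  cmp <- dplyr::transmute(
    cmp, .data$term, .data$actual, .data$additive,
    delta = .data$actual - .data$additive,
    .data$actual.low, .data$actual.high, .data$additive.low, .data$additive.high,
    nonoverlap = .data$actual.low > .data$additive.high |
      .data$actual.high < .data$additive.low
  )
  flag <- function(term) cmp$nonoverlap[cmp$term == term]

  zed <- fit_actual$ed50
  comp <- component_doses(c(fa, fb), zed)
  ci_row <- combination_index(comp$dose_a_um, comp$dose_b_um,
                              fit_a, fit_b, effect_for_ci)

  significant <- isTRUE(flag("log10_ed50")) || isTRUE(flag("hillslope"))
  verdict <- if (!significant) {
    "additive"
  } else if (ci_row$ci < 1) {
    "synergistic"
  } else if (ci_row$ci > 1) {
    "subadditive/antagonistic"
  } else if (abs(coef(fit_actual)[["hillslope"]]) <
             abs(coef(fit_additive)[["hillslope"]])) {
    "synergistic"
  } else {
    "subadditive/antagonistic"
  }

  structure(
    list(
      fit_actual = fit_actual, fit_additive = fit_additive,
      comparison = cmp,
      ed50_nonoverlap = isTRUE(flag("log10_ed50")),
      hillslope_nonoverlap = isTRUE(flag("hillslope")),
      ci_at_ed50 = ci_row,
      fraction_a = fa, fraction_b = fb,
      verdict = verdict
    ),
    class = "synergy_report"
  )
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("Synergy report (actual mixture vs theoretical additive)\n")
  cat(sprintf("  ED50: actual %.4g vs additive %.4g uM  [95%% CIs %s]\n",
              x$fit_actual$ed50, x$fit_additive$ed50,
              if (x$ed50_nonoverlap) "do NOT overlap" else "overlap"))
  cat(sprintf("  hillslope: actual %.3g vs additive %.3g  [95%% CIs %s]\n",
              coef(x$fit_actual)[["hillslope"]],
              coef(x$fit_additive)[["hillslope"]],
              if (x$hillslope_nonoverlap) "do NOT overlap" else "overlap"))
  cat(sprintf("  combination index at ED50 (%.3g uM): %.3f\n",
              x$fit_actual$ed50, x$ci_at_ed50$ci))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' @export
#' @rdname compare_curves
#' @param x A `synergy_report`.
#' @param ... Unused.
tidy.synergy_report <- function(x, ...) x$comparison

#' @export
#' @rdname compare_curves
glance.synergy_report <- function(x, ...) {
  tibble(
    ed50_actual = x$fit_actual$ed50,
    ed50_additive = x$fit_additive$ed50,
    hillslope_actual = coef(x$fit_actual)[["hillslope"]],
    hillslope_additive = coef(x$fit_additive)[["hillslope"]],
    ed50_nonoverlap = x$ed50_nonoverlap,
    hillslope_nonoverlap = x$hillslope_nonoverlap,
    ci_at_ed50 = x$ci_at_ed50$ci,
    verdict = x$verdict
  )
}

#' Plot actual-mixture and theoretical-additive curves together
#'
#' @param object A `synergy_report`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot overlaying the two fitted curves and the mixture data.
#' @export
autoplot.synergy_report <- function(object, n = 200, ...) {
  d <- dplyr::filter(object$fit_actual$data, .data$dose_um > 0)
  rng <- range(d$dose_um)
  doses <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  curves <- dplyr::bind_rows(
    tibble(dose_um = doses, curve = "actual mixture",
           response_pct = predict_effect(object$fit_actual, doses)),
    tibble(dose_um = doses, curve = "theoretical additive",
           response_pct = predict_effect(object$fit_additive, doses))
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$dose_um, y = .data$response_pct,
                               colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = dplyr::mutate(d, curve = "actual mixture"),
                        alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c("actual mixture" = "black", "theoretical additive" = "#b2182b")
    ) +
    ggplot2::labs(x = "total dose (uM)", y = "response (% of control)",
                  colour = NULL,
                  subtitle = paste("verdict:", object$verdict)) +
    ggplot2::theme_minimal()
}
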