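#' Derive an equal-potency fixed-ratio combination design from two ED50s
#'
#' In a fixed-ratio (ray) design, the two compounds are mixed so that each
#' contributes 50% of the combination's potency: the dose fractions are
#' proportional to the monotherapy ED50s, `fraction_a =
#' ed50_a / (ed50_a + ed50_b)`. For display the design also carries the
#' "rounded ratio": each ED50 rounded to the nearest multiple of 5 uM
#' (ties to the even multiple). Downstream arithmetic always uses the exact
#' fractions, never the rounded label.
#'
#' @param ed50_a,ed50_b Monotherapy ED50s in uM, both finite and > 0.
#' @param label_a,label_b Optional compound labels for printing.
#' @return A `fixed_ratio_design`: list with `ed50_a`, `ed50_b`,
#'   `fraction_a`, `fraction_b`, `rounded_a`, `rounded_b`, `rounded_ratio`
#'   (a "X:Y" label) and the compound labels.
#' @export
#' @examples
#' design_fixed_ratio(36.7, 34.7)$rounded_ratio # "35:35"
design_fixed_ratio <- function(ed50_a, ed50_b, label_a = "A", label_b = "B") {
  for (v in c(ed50_a, ed50_b)) {
    if (!is.finite(v) || v <= 0) stop_input("ED50s must be finite and > 0")
  }
  fa <- ed50_a / (ed50_a + ed50_b)
  ra <- round_to_5(ed50_a)
  rb <- round_to_5(ed50_b)
  structure(
    list(
      ed50_a = ed50_a, ed50_b = ed50_b,
      fraction_a = fa, fraction_b = 1 - fa,
      rounded_a = ra, rounded_b = rb,
      rounded_ratio = paste0(format(ra), ":", format(rb)),
      label_a = label_a, label_b = label_b
    ),
    class = "fixed_ratio_design"
  )
}

# nearest multiple of 5, half-to-even (base round() is IEC 60559 half-to-even)
round_to_5 <- function(x) 5 * round(x / 5)

#' Split a total mixture dose into its fixed-ratio components
#'
#' @param design A `fixed_ratio_design`, or a numeric pair of fractions
#'   `c(fraction_a, fraction_b)` summing to 1 (within 1e-12).
#' @param total_dose Total mixture dose(s) in uM, >= 0.
#' @return A tibble with columns `total_dose_um`, `dose_a_um`, `dose_b_um`;
#'   the component doses sum to the total exactly.
#' @export
#' @examples
#' component_doses(c(0.4, 0.6), 30) # 12 and 18
component_doses <- function(design, total_dose) {
  if (inherits(design, "fixed_ratio_design")) {
    fa <- design$fraction_a
    fb <- design$fraction_b
  } else if (is.numeric(design) && length(design) == 2) {
    fa <- design[[1]]
    fb <- design[[2]]
  } else {
    stop_input("`design` must be a fixed_ratio_design or a pair of fractions")
  }
  if (abs(fa + fb - 1) > 1e-12) {
    stop_input(sprintf("fractions must sum to 1 (got %.15g)", fa + fb))
  }
  if (any(!is.finite(total_dose)) || any(total_dose < 0)) {
    stop_input("`total_dose` must be finite and >= 0")
  }
  tibble(
    total_dose_um = total_dose,
    dose_a_um = fa * total_dose,
    dose_b_um = total_dose - fa * total_dose
  )
}

#' @export
print.fixed_ratio_design <- function(x, ...) {
  cat("Equal-potency fixed-ratio design\n")
  cat(sprintf("  %s: ED50 %.4g uM, fraction %.4f\n", x$label_a, x$ed50_a, x$fraction_a))
  cat(sprintf("  %s: ED50 %.4g uM, fraction %.4f\n", x$label_b, x$ed50_b, x$fraction_b))
  cat(sprintf("  rounded ratio (%s:%s): %s\n", x$label_a, x$label_b, x$rounded_ratio))
  invisible(x)
}

#' @export
#' @rdname design_fixed_ratio
#' @param x A `fixed_ratio_design`.
#' @param ... Unused.
tidy.fixed_ratio_design <- function(x, ...) {
  tibble(
    compound = c(x$label_a, x$label_b),
    ed50_um = c(x$ed50_a, x$ed50_b),
    fraction = c(x$fraction_a, x$fraction_b),
    rounded_um = c(x$rounded_a, x$rounded_b)
  )
}
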