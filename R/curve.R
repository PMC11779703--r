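# Cq standard-curve fitting and inverse prediction.
#
# Cq here is a detection time in minutes (isothermal reaction); an
# instrument reporting cycles maps to minutes with a minutes-per-cycle
# scalar. Censored reactions (no amplification within the run limit)
# carry NA Cq and are excluded from fitting.

#' Fit a Cq standard curve
#'
#' Ordinary least squares of Cq (minutes) on log10 template copies over a
#' dilution series; censored measurements (NA Cq) are dropped. The fitted
#' object supports [predict_cq()], [predict_copies()], `tidy()` and
#' `glance()`.
#'
#' @param data tibble with columns `copies` and `cq` (minutes; NA =
#'   censored / no amplification).
#' @return object of class `lamp_standard_curve`: list with `slope`
#'   (min per log10 copies), `intercept` (min at 1 copy), `r_squared`,
#'   `range_log10` (fitted range), `n` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(data) {
  d <- as_tibble(data) |>
    filter(!is.na(.data$cq), .data$copies > 0)
  if (length(unique(d$copies)) < 2L) {
    abort("need Cq at >= 2 distinct copy levels to fit a standard curve",
          class = "lampdx_error_fit")
  }
  d <- mutate(d, log10_copies = log10(.data$copies))
  fit <- lm(cq ~ log10_copies, data = d)
  structure(list(
    slope = unname(coef(fit)[["log10_copies"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    # suppressWarnings: summary.lm warns on noiseless (perfect-fit) input
    r_squared = suppressWarnings(summary(fit)$r.squared),
    range_log10 = range(d$log10_copies),
    n = nrow(d),
    fit = fit
  ), class = "lamp_standard_curve")
}

#' @export
print.lamp_standard_curve <- function(x, ...) {
  cat(sprintf(
    "<lamp_standard_curve> Cq = %.3f %+.3f * log10(copies)  (r^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Predicted Cq at given copy numbers
#' @param curve a [fit_standard_curve()] object.
#' @param copies template copies (> 0).
#' @return predicted Cq in minutes.
#' @export
predict_cq <- function(curve, copies) {
  curve$intercept + curve$slope * log10(copies)
}

#' Template copies estimated from an observed Cq (inverse prediction)
#' @param curve a [fit_standard_curve()] object.
#' @param cq observed Cq in minutes.
#' @return estimated copy number.
#' @export
predict_copies <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' @export
tidy.lamp_standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10_copies"),
         estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.lamp_standard_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n = x$n, log10_min = x$range_log10[1], log10_max = x$range_log10[2])
}
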