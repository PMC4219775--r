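#' Forward model of two-population competition
#'
#' GFP+ fraction after `t` days when the GFP+ population grows at per-day log
#' relative fitness `s`:
#' `p_t = p0*exp(s*t) / (p0*exp(s*t) + 1 - p0)`. Exactly linear on the logit
#' scale: `logit(p_t) = logit(p0) + s*t`.
#'
#' @param p0 Day-0 GFP+ fraction in (0, 1).
#' @param s Per-day selection coefficient.
#' @param t Days (vectorized).
#' @return GFP+ fraction(s) in (0, 1).
#' @export
project_gfp <- function(p0, s, t) {
  if (!is.numeric(p0) || any(p0 <= 0) || any(p0 >= 1)) .stopf("p0 must be in (0, 1)")
  .inv_logit(.logit(p0) + s * t)
}

#' Construct a selection fit by hand
#'
#' Mostly useful for feeding externally estimated coefficients to
#' [classify_inhibitory()]; fits from data come from [fit_selection()].
#'
#' @param s Per-day selection coefficient.
#' @param se Standard error of `s`.
#' @param p0_hat Fitted day-0 fraction.
#' @param n_points Number of points behind the estimate.
#' @return A `"selection_fit"` object.
#' @export
selection_fit <- function(s, se = NA_real_, p0_hat = NA_real_, n_points = NA_integer_) {
  if (!is.finite(s)) .stopf("s must be finite")
  structure(list(s = s, se = se, p0_hat = p0_hat, n_points = n_points,
                 lm = NULL, data = NULL, pseudo = NA_real_),
            class = "selection_fit")
}

#' Estimate a per-day selection coefficient from a GFP competition series
#'
#' Ordinary least squares of `logit(p_t)` on day: the slope is the selection
#' coefficient `s` (per day) and the intercept is `logit(p0)`. The
#' two-population exponential competition model is exactly linear in logit
#' space, so a noiseless series is interpolated exactly. Observed fractions
#' are clamped to `[pseudo, 1 - pseudo]` so occasional 0% or 100%
#' measurements remain finite on the logit scale.
#'
#' @param series A [competition_series()], or any data.frame with a `day`
#'   (or `days`) column and a `pct_gfp` column. Values may be fractions in
#'   `[0, 1]` or percentages in `[0, 100]` (auto-detected; `s` is invariant
#'   to the choice).
#' @param pseudo Clamping pseudo-fraction. Default `1/(2 * events)` when the
#'   series records its flow events per measurement, else `5e-5`.
#' @return An object of class `"selection_fit"` with components `s`, `se`,
#'   `p0_hat`, `n_points`, the underlying `lm` fit and the (clamped) data.
#'   Methods: `print`, `summary`, `coef` (returns `c(p0, s)`), `predict`
#'   (fractions at new days), `fitted`, `residuals`, `plot`, `simulate`.
#' @seealso [classify_inhibitory()], [project_gfp()]
#' @examples
#' ev <- competition_series(c(0, 35), c(0.46, 0.10))
#' fit <- fit_selection(ev)
#' coef(fit)  # s close to -0.0582/day
#' @export
fit_selection <- function(series, pseudo = NULL) {
  days <- series[["day"]] %||% series[["days"]]
  if (is.null(days)) .stopf("series must have a 'day' column")
  p <- series[["pct_gfp"]]
  if (is.null(p)) .stopf("series must have a 'pct_gfp' column")
  if (any(p > 1)) p <- p / 100
  if (any(p < 0 | p > 1)) .stopf("fractions must lie in [0, 1] (or [0, 100] as %%)")
  if (length(unique(days)) < 2L) .stopf("at least 2 distinct days are required")

  events <- attr(series, "events_per_measurement")
  pseudo <- pseudo %||% (if (!is.null(events)) 1 / (2 * events) else 5e-5)
  if (pseudo <= 0 || pseudo >= 0.5) .stopf("pseudo must be in (0, 0.5)")
  p_cl <- pmin(pmax(p, pseudo), 1 - pseudo)
  if (all(p_cl == pseudo) || all(p_cl == 1 - pseudo))
    .stopf("degenerate series: all observations at 0 or 1 after clamping")

  d <- data.frame(day = days, logit_p = .logit(p_cl))
  fit <- lm(logit_p ~ day, data = d)
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients["day", "Std. Error"],
                 error = function(e) NA_real_)
  if (!is.finite(se)) se <- NA_real_

  structure(
    list(s = unname(cf["day"]), se = se, p0_hat = unname(.inv_logit(cf["(Intercept)"])),
         n_points = length(p), lm = fit,
         data = data.frame(day = days, pct_gfp = p, pct_gfp_clamped = p_cl),
         pseudo = pseudo),
    class = "selection_fit"
  )
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("Two-population competition fit (logit-linear)\n")
  cat(sprintf("  s     = %+.5f per day%s\n", x$s,
              if (is.finite(x$se)) sprintf(" (SE %.5f)", x$se) else ""))
  cat(sprintf("  p0    = %.4f (fitted day-0 GFP+ fraction)\n", x$p0_hat))
  cat(sprintf("  n     = %s points\n", x$n_points))
  invisible(x)
}

#' @export
coef.selection_fit <- function(object, ...) {
  c(p0 = object$p0_hat, s = object$s)
}

#' @export
summary.selection_fit <- function(object, ...) {
  out <- list(fit = object,
              lm_summary = if (!is.null(object$lm)) summary(object$lm) else NULL)
  class(out) <- "summary.selection_fit"
  out
}

#' @export
print.summary.selection_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$lm_summary)) {
    cat("\nLogit-scale regression:\n")
    print(x$lm_summary$coefficients)
  }
  invisible(x)
}

#' @export
predict.selection_fit <- function(object, days = NULL, ...) {
  days <- days %||% object$data$day
  project_gfp(object$p0_hat, object$s, days)
}

#' @export
fitted.selection_fit <- function(object, ...) predict(object)

#' @export
residuals.selection_fit <- function(object, type = c("logit", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$lm)) .stopf("no data behind this fit")
  if (type == "logit") unname(residuals(object$lm))
  else object$data$pct_gfp - fitted(object)
}

#' @export
plot.selection_fit <- function(x, ...) {
  if (is.null(x$data)) .stopf("no data behind this fit")
  plot(x$data$day, 100 * x$data$pct_gfp, xlab = "Day", ylab = "%GFP+",
       ylim = c(0, 100), pch = 19, ...)
  tt <- seq(min(x$data$day), max(x$data$day), length.out = 200)
  graphics::lines(tt, 100 * predict(x, tt))
  invisible(x)
}

#' @export
simulate.selection_fit <- function(object, nsim = 1, seed = NULL,
                                   days = NULL, events = 1e4, ...) {
  .seed_rng(seed)
  days <- days %||% object$data$day
  p <- project_gfp(object$p0_hat, object$s, days)
  lapply(seq_len(nsim), function(r) {
    competition_series(days, rbinom(length(p), events, p) / events,
                       replicate = r, events_per_measurement = events)
  })
}

#' Classify a construct as growth-inhibitory from its selection fit
#'
#' Inhibitory when the upper `1 - alpha` one-sided confidence bound of `s`
#' lies below `s_threshold`: `s + z_(1-alpha) * SE < s_threshold`. A flat
#' empty-vector-like series is therefore called non-inhibitory, as is an
#' underpowered fit with a large standard error.
#'
#' @param fit A `"selection_fit"`.
#' @param alpha One-sided significance level.
#' @param s_threshold Selection-coefficient threshold (default 0 = neutral).
#' @return A list of class `"inhibition_call"`: `inhibitory` (logical), `s`,
#'   `se`, `ci_upper`, `alpha`, `s_threshold`.
#' @export
classify_inhibitory <- function(fit, alpha = 0.05, s_threshold = 0) {
  if (!is.finite(fit$se)) .stopf("fit has no finite standard error (need >= 3 points)")
  upper <- fit$s + qnorm(1 - alpha) * fit$se
  structure(list(inhibitory = upper < s_threshold, s = fit$s, se = fit$se,
                 ci_upper = upper, alpha = alpha, s_threshold = s_threshold),
            class = "inhibition_call")
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat(sprintf("%s: s = %+.5f/day, one-sided %.0f%% upper bound %+.5f (threshold %+.4f)\n",
              if (x$inhibitory) "growth-inhibitory" else "not inhibitory",
              x$s, 100 * (1 - x$alpha), x$ci_upper, x$s_threshold))
  invisible(x)
}
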