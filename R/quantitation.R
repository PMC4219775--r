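#' Define a qPCR standard curve
#'
#' The log-linear model `Ct = intercept + slope * log10(copies)`. The
#' amplification efficiency implied by the slope is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling, slope -3.3219).
#'
#' @param slope Ct change per log10(copies); must be negative.
#' @param intercept Ct at 1 copy.
#' @param r2 Optional fit quality.
#' @param copies_range Optional range of the calibrated standards (copies);
#'   the lower end is the default below-detection threshold.
#' @return An object of class `"standard_curve"`.
#' @seealso [fit_standard_curve()], [ct_to_copies()]
#' @export
standard_curve <- function(slope, intercept, r2 = NA_real_, copies_range = NULL) {
  if (!is.numeric(slope) || slope >= 0) .stopf("slope must be negative")
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.2)
    .warnf("implied amplification efficiency %.2f outside (0, 1.2]", eff)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency = eff, copies_range = copies_range, lm = NULL),
            class = "standard_curve")
}

#' Fit a standard curve from serial-dilution points
#'
#' Least squares of Ct on log10(copies). Requires at least 3 points spanning
#' at least 2 decades of input copies.
#'
#' @param copies Known input copies per reaction (all > 0), or a data.frame
#'   with `copies` and `ct` columns.
#' @param ct Measured Ct values.
#' @return A `"standard_curve"` with `slope`, `intercept`, `r2`,
#'   `efficiency` and `copies_range` filled in from the fit.
#' @export
fit_standard_curve <- function(copies, ct = NULL) {
  if (is.data.frame(copies)) {
    ct <- copies$ct
    copies <- copies$copies
  }
  if (length(copies) != length(ct)) .stopf("copies and ct lengths differ")
  if (length(copies) < 3L) .stopf("at least 3 standard points are required")
  if (any(copies <= 0)) .stopf("standard points must have copies > 0")
  if (log10(max(copies) / min(copies)) < 2)
    .stopf("standards must span at least 2 decades of input copies")
  if (stats::sd(ct) == 0) .stopf("identical Cts at all dilutions: singular fit")

  d <- data.frame(lc = log10(copies), ct = ct)
  fit <- lm(ct ~ lc, data = d)
  cf <- coef(fit)
  if (cf["lc"] >= 0) .stopf("fitted slope is non-negative: not a dilution series")
  out <- standard_curve(unname(cf["lc"]), unname(cf["(Intercept)"]),
                        r2 = suppressWarnings(summary(fit))$r.squared,
                        copies_range = range(copies))
  out$lm <- fit
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.3f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.3f%s%s\n", x$efficiency,
              if (is.finite(x$r2)) sprintf(", R^2 = %.4f", x$r2) else "",
              if (!is.null(x$copies_range))
                sprintf(", calibrated %g-%g copies", x$copies_range[1], x$copies_range[2])
              else ""))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.standard_curve <- function(object, copies, ...) {
  if (any(copies <= 0)) .stopf("copies must be > 0 to predict a Ct")
  object$intercept + object$slope * log10(copies)
}

#' Convert Ct to copies per reaction
#'
#' Inverts the standard-curve line: `copies = 10^((ct - intercept)/slope)`.
#' Undetermined Cts (`NA`) return `NA` (below detection).
#'
#' @param ct Ct values (`NA` = undetermined).
#' @param curve A [standard_curve()].
#' @return Copies per reaction.
#' @seealso [below_detection()]
#' @export
ct_to_copies <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' Flag below-detection absolute measurements
#'
#' Absolute quantitation is only trusted within the curve's calibrated range:
#' an undetermined Ct, or a Ct implying fewer copies than `lod_copies`
#' (default: the lowest calibrated standard), is below detection.
#'
#' @param ct Ct values.
#' @param curve A [standard_curve()].
#' @param lod_copies Copies at the limit of detection.
#' @return Logical vector.
#' @export
below_detection <- function(ct, curve, lod_copies = NULL) {
  lod_copies <- lod_copies %||%
    (if (!is.null(curve$copies_range)) curve$copies_range[1] else 0)
  copies <- ct_to_copies(ct, curve)
  is.na(ct) | copies < lod_copies
}

#' Cell equivalents of an RNA input
#'
#' Converts an RNA mass input to the number of cells it represents, given the
#' total RNA content per cell (default 12.5 pg/cell, so 10 ng = 800 cells).
#'
#' @param rna_input_ng RNA input per reaction in nanograms.
#' @param rna_per_cell_pg Total RNA per cell in picograms.
#' @return A list of class `"cell_equivalents"` with `rna_input_ng`,
#'   `rna_per_cell_pg` and `cells`.
#' @export
cell_equivalents <- function(rna_input_ng = 10, rna_per_cell_pg = 12.5) {
  if (rna_input_ng <= 0 || rna_per_cell_pg <= 0)
    .stopf("rna_input_ng and rna_per_cell_pg must be positive")
  structure(list(rna_input_ng = rna_input_ng, rna_per_cell_pg = rna_per_cell_pg,
                 cells = rna_input_ng * 1000 / rna_per_cell_pg),
            class = "cell_equivalents")
}

#' @export
print.cell_equivalents <- function(x, ...) {
  cat(sprintf("%g ng RNA at %g pg/cell = %g cell equivalents\n",
              x$rna_input_ng, x$rna_per_cell_pg, x$cells))
  invisible(x)
}

#' Copies per cell from copies per reaction
#'
#' @param copies_per_reaction Absolute copies measured in the reaction.
#' @param cells A [cell_equivalents()] object or a plain cell count.
#' @return Copies per cell (linear in `copies_per_reaction`).
#' @export
copies_per_cell <- function(copies_per_reaction, cells) {
  n <- if (inherits(cells, "cell_equivalents")) cells$cells else cells
  if (!is.numeric(n) || any(n <= 0)) .stopf("cells must be > 0")
  copies_per_reaction / n
}

#' Cap Ct values for relative quantitation
#'
#' Cts above the cap — including undetermined (`NA`) reactions, an extension
#' of the same rule — are assigned the cap before fold-change arithmetic.
#'
#' @param ct Ct values (`NA` = undetermined).
#' @param cap Maximum Ct (default 35).
#' @return Capped Ct values.
#' @export
cap_ct <- function(ct, cap = 35) {
  ct[is.na(ct)] <- cap
  pmin(ct, cap)
}

#' Delta-delta-Ct fold change
#'
#' `2^-((target - control) - (ref_target - ref_control))`: expression of a
#' target gene relative to an endogenous control, normalized to a reference
#' sample. Invariant to any additive shift applied to all four Cts. Cap Cts
#' with [cap_ct()] first.
#'
#' @param target_ct,control_ct Cts of target and endogenous control in the
#'   test sample.
#' @param ref_target_ct,ref_control_ct The same pair in the reference sample.
#' @return Fold change (1 = no change).
#' @export
ddct_fold <- function(target_ct, control_ct, ref_target_ct, ref_control_ct) {
  2^(-((target_ct - control_ct) - (ref_target_ct - ref_control_ct)))
}

#' Expression ratio to an endogenous control
#'
#' `2^-(target - control)` within a single sample. Cap Cts first.
#'
#' @param target_ct,control_ct Capped Ct values.
#' @return Ratio (1 = equal expression).
#' @export
ratio_to_control <- function(target_ct, control_ct) {
  2^(-(target_ct - control_ct))
}

#' Absolute quantitation of a set of reactions
#'
#' Convenience wrapper: converts Cts to copies per reaction via the standard
#' curve, then to copies per cell via the cell equivalents of the RNA input,
#' flagging below-detection reactions.
#'
#' @param ct Ct values (`NA` = undetermined).
#' @param curve A [standard_curve()].
#' @param cells A [cell_equivalents()] or cell count.
#' @param lod_copies Limit of detection in copies (default: lowest standard).
#' @return data.frame with `ct`, `copies_per_reaction`, `copies_per_cell`,
#'   `below_detection`.
#' @export
quant_absolute <- function(ct, curve, cells, lod_copies = NULL) {
  cpr <- ct_to_copies(ct, curve)
  data.frame(ct = ct,
             copies_per_reaction = cpr,
             copies_per_cell = copies_per_cell(cpr, cells),
             below_detection = below_detection(ct, curve, lod_copies))
}
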