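#' Relative luciferase activity of a reporter under a miR mimic
#'
#' Each well's firefly signal is normalized to its renilla signal
#' (transfection-efficiency control); the mimic group's mean firefly/renilla
#' ratio is then divided by that of wells transfected with the reporter
#' construct alone. Well-level ratios are averaged (mean of ratios, not ratio
#' of means).
#'
#' @param wells_with_mimic,wells_construct_only data.frames with numeric
#'   `firefly` and `renilla` columns (renilla must be positive).
#' @return Relative luciferase activity (1 = no repression).
#' @export
relative_luciferase <- function(wells_with_mimic, wells_construct_only) {
  for (w in list(wells_with_mimic, wells_construct_only)) {
    if (!nrow(w)) .stopf("both well groups must be non-empty")
    if (any(w$renilla <= 0)) .stopf("renilla must be > 0 in every well")
  }
  mean(wells_with_mimic$firefly / wells_with_mimic$renilla) /
    mean(wells_construct_only$firefly / wells_construct_only$renilla)
}

#' Fold growth relative to a reference condition
#'
#' Blank-subtracted mean readout of the test condition over that of the
#' reference (e.g. dye-reduction fluorescence of miR-transduced cells
#' normalized to empty vector). Blank subtraction is optional (default 0).
#'
#' @param readings_test,readings_reference Numeric readouts (e.g. RFU).
#' @param blank Instrument blank to subtract from both means.
#' @return Fold growth (1 = equal growth).
#' @export
growth_fold <- function(readings_test, readings_reference, blank = 0) {
  ref <- mean(readings_reference) - blank
  if (ref <= 0) .stopf("reference mean must exceed the blank")
  (mean(readings_test) - blank) / ref
}

#' Quadrant frequencies of a two-channel flow table
#'
#' Fractions of events in the four quadrants defined by fixed thresholds on
#' two channels (e.g. Annexin V vs 7-AAD). Events above a threshold are
#' positive for that channel.
#'
#' @param events data.frame of per-event intensities.
#' @param x_channel,y_channel Column names of the two gated channels.
#' @param x_threshold,y_threshold Gate thresholds.
#' @return Named numeric vector `c(neg_neg, pos_neg, neg_pos, pos_pos)`
#'   summing to 1.
#' @export
quadrant_frequencies <- function(events, x_channel, y_channel,
                                 x_threshold, y_threshold) {
  if (!nrow(events)) .stopf("events table is empty")
  for (ch in c(x_channel, y_channel))
    if (!ch %in% names(events)) .stopf("missing channel column: %s", ch)
  if (!is.finite(x_threshold) || !is.finite(y_threshold))
    .stopf("thresholds must be finite")
  xp <- events[[x_channel]] > x_threshold
  yp <- events[[y_channel]] > y_threshold
  n <- nrow(events)
  c(neg_neg = sum(!xp & !yp), pos_neg = sum(xp & !yp),
    neg_pos = sum(!xp & yp), pos_pos = sum(xp & yp)) / n
}

#' Cell-cycle phase fractions from BrdU / DNA-content flow data
#'
#' Gates: events with DNA content below the 2N window are subG1; of the
#' remainder, BrdU-positive events are S phase; BrdU-negative events within
#' the 2N window are G0/G1 and above it (4N) are G2/M.
#'
#' @param events data.frame of per-event intensities.
#' @param dna_channel,brdu_channel Column names.
#' @param brdu_threshold BrdU positivity threshold.
#' @param g1_window Numeric `c(lo, hi)`: the 2N DNA-content window.
#' @return Named fractions `c(subG1, G0G1, S, G2M)` summing to 1.
#' @export
cell_cycle_fractions <- function(events, dna_channel = "dna",
                                 brdu_channel = "brdu",
                                 brdu_threshold, g1_window) {
  if (!nrow(events)) .stopf("events table is empty")
  for (ch in c(dna_channel, brdu_channel))
    if (!ch %in% names(events)) .stopf("missing channel column: %s", ch)
  dna <- events[[dna_channel]]
  brdu <- events[[brdu_channel]]
  sub_g1 <- dna < g1_window[1]
  s_phase <- !sub_g1 & brdu > brdu_threshold
  g0_g1 <- !sub_g1 & !s_phase & dna <= g1_window[2]
  g2_m <- !sub_g1 & !s_phase & dna > g1_window[2]
  n <- nrow(events)
  c(subG1 = sum(sub_g1), G0G1 = sum(g0_g1), S = sum(s_phase), G2M = sum(g2_m)) / n
}

#' Loading-normalized densitometry relative to a reference lane
#'
#' `(band/loading) / (ref_band/ref_loading)`: a band intensity normalized to
#' its lane's loading control, relative to the same quantity in a reference
#' lane. Invariant to global gain.
#'
#' @param band,loading Band and loading-control intensities of the test lane.
#' @param ref_band,ref_loading The same pair for the reference lane.
#' @return Relative protein level (1 = no change).
#' @export
densitometry_relative <- function(band, loading, ref_band, ref_loading) {
  if (any(c(loading, ref_loading) <= 0)) .stopf("loading intensities must be > 0")
  (band / loading) / (ref_band / ref_loading)
}

#' Rescue of a growth phenotype by co-expressed ORF
#'
#' Quantifies how much co-expressing a candidate target's open reading frame
#' restores growth suppressed by a miR: the percent growth gain of
#' miR + ORF over miR + empty vector, alongside the percent growth deficit of
#' miR + empty vector versus the double-empty-vector baseline.
#'
#' @param growth_mir_plus_ev Fold growth of miR + empty vector (relative to
#'   the baseline condition), must be > 0.
#' @param growth_mir_plus_orf Fold growth of miR + ORF.
#' @param growth_ev_ev Fold growth of the double-empty-vector baseline
#'   (default 1, i.e. the normalization reference itself).
#' @return List with `pct_rescue` (percent greater growth of miR + ORF vs
#'   miR + EV) and `pct_deficit` (percent lower growth of miR + EV vs the
#'   EV + EV baseline).
#' @export
rescue_effect <- function(growth_mir_plus_ev, growth_mir_plus_orf,
                          growth_ev_ev = 1) {
  if (growth_mir_plus_ev <= 0) .stopf("growth_mir_plus_ev must be > 0")
  list(
    pct_rescue = 100 * (growth_mir_plus_orf - growth_mir_plus_ev) / growth_mir_plus_ev,
    pct_deficit = 100 * (growth_ev_ev - growth_mir_plus_ev) / growth_ev_ev
  )
}

#' Two-sample t test convenience wrapper
#'
#' Thin plumbing around [stats::t.test()] for comparing replicate readouts
#' between two conditions; returns just the p-value.
#'
#' @param x,y Numeric replicate values for the two conditions.
#' @param ... Passed to [stats::t.test()].
#' @return p-value.
#' @export
t_test_p <- function(x, y, ...) {
  stats::t.test(x, y, ...)$p.value
}
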