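#' Simulate a pooled miR dropout screen
#'
#' Generates per-replicate detection tables under the generative model the
#' downstream calling rules assume:
#' \enumerate{
#'   \item \strong{Transduction}: each exposed cell receives a Poisson(MOI)
#'     number of integrations; a cell is transduced if it receives at least
#'     one (single-hit model, transduced fraction `1 - exp(-moi)`). Transduced
#'     founders are assigned to constructs multinomially according to the
#'     library representation.
#'   \item \strong{Growth}: each clone grows deterministically and
#'     exponentially, so a construct with per-day fitness `w` contributes
#'     `n0 * w^t` cells at day `t`; untransduced cells grow at `w = 1`.
#'   \item \strong{Sampling}: at each timepoint `cells_sampled_per_tp` cells
#'     are drawn multinomially from the culture; a construct's template copy
#'     number is its sampled cell count (one integration per cell).
#'   \item \strong{Detection}: the probability that qPCR detects a construct
#'     is logistic in `log10(copies)` centered at `dropout_floor` with slope
#'     `detection_slope`, falling from ~1 well above the floor toward 0 below
#'     it (sporadic amplification at low template input, the "Monte Carlo
#'     effect"). With `dropout_floor = 0`, any positive copy number is
#'     detected.
#' }
#'
#' @param scenario A [screen_scenario()].
#' @param rng_seed Optional seed overriding `scenario$rng_seed`.
#'
#' @return An object of class `"screen_dataset"`: a list with
#'   \describe{
#'     \item{replicates}{list of data.frames (`construct`, `timepoint_day`,
#'       `copies`, `detected`, `abundance`), one per replicate screen;
#'       `abundance` is `copies` where detected and `NA` otherwise.}
#'     \item{reference_timepoint}{first timepoint (default day 4).}
#'     \item{truth}{ground-truth fitness map and expected transduced
#'       fraction, retained for recovery tests.}
#'   }
#' @seealso [call_candidates()], [write_screen_dataset()]
#' @export
simulate_screen <- function(scenario, rng_seed = NULL) {
  stopifnot(inherits(scenario, "screen_scenario"))
  .seed_rng(rng_seed %||% scenario$rng_seed)

  constructs <- names(scenario$representation)
  k <- scenario$library_size
  tps <- scenario$timepoints
  p_trans <- scenario$transduced_fraction_expected

  replicates <- vector("list", scenario$n_replicates)
  for (r in seq_len(scenario$n_replicates)) {
    n_trans <- rbinom(1L, size = scenario$n_cells_infected, prob = p_trans)
    founders <- as.numeric(rmultinom(1L, size = n_trans,
                                     prob = scenario$representation))
    n_untrans <- scenario$n_cells_infected - n_trans

    per_tp <- lapply(tps, function(t) {
      clone_sizes <- c(founders * scenario$fitness^t, n_untrans)
      samp <- as.numeric(rmultinom(1L, size = scenario$cells_sampled_per_tp,
                                   prob = clone_sizes / sum(clone_sizes)))
      copies <- samp[seq_len(k)]
      detected <- runif(k) < detection_probability(
        copies, scenario$dropout_floor, scenario$detection_slope)
      data.frame(construct = constructs, timepoint_day = t,
                 copies = copies, detected = detected,
                 abundance = ifelse(detected, copies, NA_real_))
    })
    replicates[[r]] <- do.call(rbind, per_tp)
    rownames(replicates[[r]]) <- NULL
  }

  structure(
    list(
      replicates = replicates,
      constructs = constructs,
      timepoints = tps,
      reference_timepoint = tps[1],
      cell_line_label = "synthetic",
      cross_line_reference = NULL,
      scenario = scenario,
      truth = list(
        fitness = scenario$fitness,
        transduced_fraction_expected = p_trans,
        # the Poisson single-hit fraction; moi itself is the linear
        # approximation often quoted as "~30%" at MOI 0.3
        moi = scenario$moi
      )
    ),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("Pooled screen dataset: %d constructs x %d timepoints x %d replicates (reference day %g)\n",
              length(x$constructs), length(x$timepoints),
              length(x$replicates), x$reference_timepoint))
  invisible(x)
}

#' qPCR detection probability at low template input
#'
#' Logistic in `log10(copies)` centered at `floor_copies`: 0.5 at the floor,
#' approaching 1 above and 0 below it. `floor_copies = 0` means deterministic
#' detection of any positive copy number. Zero copies are never detected.
#'
#' @param copies Template copies per reaction (vector).
#' @param floor_copies Dropout floor in copies.
#' @param slope Logistic slope per log10(copies).
#' @return Vector of detection probabilities.
#' @export
detection_probability <- function(copies, floor_copies, slope = 4) {
  p <- ifelse(copies > 0,
              if (floor_copies <= 0) 1
              else .inv_logit(slope * (log10(pmax(copies, 0.5)) - log10(floor_copies))),
              0)
  as.numeric(p)
}

#' Simulate GFP competition time series
#'
#' For each replicate and day, the true GFP+ fraction is
#' `p_t = p0*exp(s*t) / (p0*exp(s*t) + 1 - p0)` and the observed fraction is
#' `Binomial(events_per_measurement, p_t) / events_per_measurement`.
#'
#' @param scenario A [competition_scenario()].
#' @param rng_seed Optional seed overriding `scenario$rng_seed`.
#' @return A list of [competition_series()] objects, one per replicate.
#' @seealso [fit_selection()], [project_gfp()]
#' @export
simulate_competition <- function(scenario, rng_seed = NULL) {
  stopifnot(inherits(scenario, "competition_scenario"))
  .seed_rng(rng_seed %||% scenario$rng_seed)
  p_true <- project_gfp(scenario$p0, scenario$s, scenario$days)
  lapply(seq_len(scenario$n_replicates), function(r) {
    obs <- rbinom(length(p_true), size = scenario$events_per_measurement,
                  prob = p_true) / scenario$events_per_measurement
    competition_series(scenario$days, obs, replicate = r,
                       label = scenario$label,
                       events_per_measurement = scenario$events_per_measurement)
  })
}

#' Simulate a qPCR plate from known template copies
#'
#' Applies the log-linear standard-curve model
#' `Ct = intercept + slope * log10(copies)` plus Gaussian noise. Zero input
#' copies yield the "undetermined" sentinel `NA`.
#'
#' @param true_copies Non-negative template copies per reaction.
#' @param curve A [standard_curve()] (or list with `slope` and `intercept`).
#' @param ct_sd Standard deviation of Ct noise (cycles), `>= 0`.
#' @param rng_seed Optional integer seed.
#' @return Numeric vector of Ct values (`NA` = undetermined).
#' @export
simulate_qpcr_plate <- function(true_copies, curve, ct_sd = 0, rng_seed = NULL) {
  if (any(true_copies < 0)) .stopf("true_copies must be >= 0")
  if (ct_sd < 0) .stopf("ct_sd must be >= 0")
  .seed_rng(rng_seed)
  ct <- rep(NA_real_, length(true_copies))
  pos <- true_copies > 0
  ct[pos] <- curve$intercept + curve$slope * log10(true_copies[pos]) +
    rnorm(sum(pos), 0, ct_sd)
  ct
}
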