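#' Define a pooled miR dropout-screen scenario
#'
#' Describes the study conditions of a pooled gain-of-function lentiviral miR
#' screen: a library of constructs is transduced into a cell population at low
#' multiplicity of infection (MOI), the culture grows, and at each sampling
#' day a fixed number of cells is harvested and each construct's template
#' copies are measured by qPCR. Defaults reproduce a 578-construct library
#' transduced at MOI 0.3 into 1.8e6 cells, sampled at 2e6 cells on days
#' 4/12/20/28 across 3 replicate screens.
#'
#' @param library_size Number of constructs in the pooled library.
#' @param n_cells_infected Number of cells exposed to the pooled virus.
#' @param moi Multiplicity of infection (virions per cell), `>= 0`. The
#'   transduced fraction follows the Poisson single-hit model
#'   `1 - exp(-moi)`.
#' @param timepoints Sampling days after infection, strictly increasing.
#' @param n_replicates Number of independent replicate screens.
#' @param cells_sampled_per_tp Cells harvested per timepoint for detection.
#' @param fitness Per-day relative fitness `w > 0` for each construct
#'   (`w = 1` neutral). Either `NULL` (all neutral), a full vector of length
#'   `library_size`, or a named vector of exceptions applied over a neutral
#'   baseline (names must be construct ids, see Details).
#' @param representation Library composition: `"uniform"` (default),
#'   `"lognormal"` (log-normal skew with `representation_sd`), or a numeric
#'   vector of fractions summing to 1.
#' @param representation_sd Standard deviation (log scale) of the log-normal
#'   skew when `representation = "lognormal"`.
#' @param dropout_floor Template copies below which qPCR detection becomes
#'   stochastic (the "Monte Carlo effect"); `0` disables stochastic dropout
#'   (any positive copy number is detected).
#' @param detection_slope Slope (per log10 copies) of the logistic detection
#'   curve centered at `dropout_floor`.
#' @param rng_seed Optional integer seed used by [simulate_screen()].
#'
#' @details Constructs are labelled `construct_0001 ...` in library order.
#'   When `representation = "lognormal"` the fractions are drawn once at
#'   scenario creation (under `rng_seed`) so a scenario is a fixed object.
#'
#' @return An object of class `"screen_scenario"`.
#' @seealso [simulate_screen()]
#' @export
screen_scenario <- function(library_size = 578,
                            n_cells_infected = 1.8e6,
                            moi = 0.3,
                            timepoints = c(4, 12, 20, 28),
                            n_replicates = 3,
                            cells_sampled_per_tp = 2e6,
                            fitness = NULL,
                            representation = "uniform",
                            representation_sd = 0.5,
                            dropout_floor = 50,
                            detection_slope = 4,
                            rng_seed = NULL) {
  if (!.is_count(library_size) || library_size < 1)
    .stopf("library_size must be a positive count")
  if (!is.numeric(moi) || length(moi) != 1L || !is.finite(moi) || moi < 0)
    .stopf("moi must be a single non-negative number")
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0))
    .stopf("timepoints must be strictly increasing")
  if (!.is_count(n_replicates) || n_replicates < 1)
    .stopf("n_replicates must be a positive count")
  if (!.is_count(cells_sampled_per_tp) || cells_sampled_per_tp < 1)
    .stopf("cells_sampled_per_tp must be a positive count")
  if (dropout_floor < 0) .stopf("dropout_floor must be >= 0")

  constructs <- sprintf("construct_%04d", seq_len(library_size))

  w <- rep(1, library_size)
  names(w) <- constructs
  if (!is.null(fitness)) {
    if (is.null(names(fitness)) && length(fitness) == library_size) {
      w[] <- fitness
    } else if (!is.null(names(fitness))) {
      unknown <- setdiff(names(fitness), constructs)
      if (length(unknown)) .stopf("unknown construct in fitness: %s", unknown[1])
      w[names(fitness)] <- fitness
    } else {
      .stopf("fitness must be named or of length library_size")
    }
  }
  if (any(!is.finite(w)) || any(w <= 0)) .stopf("all fitness values must be finite and > 0")

  if (is.character(representation)) {
    representation <- match.arg(representation, c("uniform", "lognormal"))
    if (representation == "uniform") {
      rep_frac <- rep(1 / library_size, library_size)
    } else {
      .seed_rng(rng_seed)
      raw <- rlnorm(library_size, meanlog = 0, sdlog = representation_sd)
      rep_frac <- raw / sum(raw)
    }
  } else {
    rep_frac <- as.numeric(representation)
    if (length(rep_frac) != library_size)
      .stopf("representation must have length library_size")
    if (abs(sum(rep_frac) - 1) > 1e-9)
      .stopf("representation must sum to 1 (got %.12f)", sum(rep_frac))
  }
  names(rep_frac) <- constructs

  structure(
    list(
      library_size = as.integer(library_size),
      n_cells_infected = n_cells_infected,
      moi = moi,
      timepoints = timepoints,
      n_replicates = as.integer(n_replicates),
      cells_sampled_per_tp = cells_sampled_per_tp,
      fitness = w,
      representation = rep_frac,
      dropout_floor = dropout_floor,
      detection_slope = detection_slope,
      rng_seed = rng_seed,
      transduced_fraction_expected = 1 - exp(-moi)
    ),
    class = "screen_scenario"
  )
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat("Pooled miR screen scenario\n")
  cat(sprintf("  library: %d constructs; %g cells at MOI %.3g (Poisson single-hit: %.1f%% transduced)\n",
              x$library_size, x$n_cells_infected, x$moi,
              100 * x$transduced_fraction_expected))
  cat(sprintf("  sampling: days %s; %g cells/timepoint; %d replicates\n",
              paste(x$timepoints, collapse = ", "), x$cells_sampled_per_tp,
              x$n_replicates))
  n_non_neutral <- sum(x$fitness != 1)
  cat(sprintf("  fitness: %d non-neutral construct(s); dropout floor %g copies\n",
              n_non_neutral, x$dropout_floor))
  invisible(x)
}

#' Define a two-population GFP competition scenario
#'
#' Describes a GFP competition assay: transduced (GFP+) cells are mixed
#' ~50:50 with mock-transduced cells at day 0 and the GFP+ fraction is
#' measured over time by flow cytometry. The GFP+ population grows at
#' per-day log-fitness `s` relative to the GFP- population, so the true
#' fraction follows `p_t = p0*exp(s*t) / (p0*exp(s*t) + 1 - p0)`; each
#' measurement observes `Binomial(events_per_measurement, p_t)` events.
#'
#' @param p0 True GFP+ fraction at day 0, in (0, 1).
#' @param s Per-day selection coefficient (log relative fitness); `s < 0`
#'   means the transduced population is out-competed.
#' @param days Sampling days, starting at 0 (default weekly over 35 days).
#' @param events_per_measurement Flow events counted per measurement.
#' @param n_replicates Number of independent cultures.
#' @param label Construct label carried into the series.
#' @param rng_seed Optional integer seed used by [simulate_competition()].
#'
#' @return An object of class `"competition_scenario"`.
#' @seealso [simulate_competition()], [fit_selection()]
#' @export
competition_scenario <- function(p0 = 0.5,
                                 s = 0,
                                 days = seq(0, 35, by = 7),
                                 events_per_measurement = 1e4,
                                 n_replicates = 3,
                                 label = "",
                                 rng_seed = NULL) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    .stopf("p0 must be in (0, 1)")
  if (length(days) < 1L || days[1] != 0 || any(diff(days) < 0))
    .stopf("days must start at 0 and be non-decreasing")
  if (!.is_count(events_per_measurement) || events_per_measurement < 1)
    .stopf("events_per_measurement must be a positive count")
  if (!.is_count(n_replicates) || n_replicates < 1)
    .stopf("n_replicates must be a positive count")
  structure(
    list(p0 = p0, s = s, days = days,
         events_per_measurement = events_per_measurement,
         n_replicates = as.integer(n_replicates),
         label = label, rng_seed = rng_seed),
    class = "competition_scenario"
  )
}

#' @export
print.competition_scenario <- function(x, ...) {
  cat(sprintf("GFP competition scenario: p0 = %.3g, s = %+.4g/day, days %s, %g events x %d replicates\n",
              x$p0, x$s, paste(range(x$days), collapse = "-"),
              x$events_per_measurement, x$n_replicates))
  invisible(x)
}

#' A single GFP competition time series
#'
#' @param days Measurement days (day 0 = mixing day), non-decreasing.
#' @param pct_gfp GFP+ fractions in `[0, 1]` (percentages 0-100 are also
#'   accepted by [fit_selection()] and rescaled).
#' @param replicate Replicate identifier.
#' @param label Construct label (or empty-vector control label).
#' @param events_per_measurement Flow events per measurement, used to choose
#'   the default clamping pseudo-fraction when fitting.
#'
#' @return An object of class `"competition_series"`: a data.frame with
#'   columns `replicate`, `day`, `pct_gfp` and attributes `label`,
#'   `events_per_measurement`.
#' @export
competition_series <- function(days, pct_gfp, replicate = 1L, label = "",
                               events_per_measurement = NULL) {
  if (length(days) != length(pct_gfp)) .stopf("days and pct_gfp lengths differ")
  if (any(diff(days) < 0)) .stopf("days must be non-decreasing")
  if (any(!is.finite(pct_gfp))) .stopf("pct_gfp must be finite")
  scale_max <- if (any(pct_gfp > 1)) 100 else 1
  if (any(pct_gfp < 0 | pct_gfp > scale_max))
    .stopf("pct_gfp must lie in [0, 1] (or [0, 100] as percentages)")
  out <- data.frame(replicate = replicate, day = days, pct_gfp = pct_gfp)
  attr(out, "label") <- label
  attr(out, "events_per_measurement") <- events_per_measurement
  class(out) <- c("competition_series", "data.frame")
  out
}
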