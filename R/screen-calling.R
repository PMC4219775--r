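#' Call depleted constructs in one replicate screen
#'
#' A construct is called depleted when it is detected at the reference
#' timepoint and its abundance at `min_later_tps` or more later timepoints
#' falls to `depletion_ratio` times its reference abundance or lower
#' (inclusive at the threshold). Non-detection at a later timepoint counts as
#' abundance 0 and is therefore always depleted; constructs undetected at the
#' reference timepoint are not callable by this rule (see
#' [rescue_never_detected()]).
#'
#' @param replicate_table data.frame with columns `construct`,
#'   `timepoint_day`, `detected` (logical) and `abundance` (measured value,
#'   `NA` when undetected), as produced by [simulate_screen()].
#' @param reference_timepoint Day used as reference (must be present).
#' @param depletion_ratio Threshold ratio in (0, 1].
#' @param min_later_tps Minimum number of later timepoints below threshold.
#' @return Sorted character vector of called constructs.
#' @export
call_depleted <- function(replicate_table, reference_timepoint = NULL,
                          depletion_ratio = 0.5, min_later_tps = 2) {
  if (!is.numeric(depletion_ratio) || depletion_ratio <= 0 || depletion_ratio > 1)
    .stopf("depletion_ratio must be in (0, 1]")
  tps <- sort(unique(replicate_table$timepoint_day))
  reference_timepoint <- reference_timepoint %||% tps[1]
  if (!reference_timepoint %in% tps)
    .stopf("reference timepoint %g not present", reference_timepoint)

  ref <- replicate_table[replicate_table$timepoint_day == reference_timepoint, ]
  later <- replicate_table[replicate_table$timepoint_day > reference_timepoint, ]
  ref_ok <- ref[ref$detected %in% TRUE & !is.na(ref$abundance) & ref$abundance > 0, ]
  if (!nrow(ref_ok)) return(character())

  ref_ab <- setNames(ref_ok$abundance, ref_ok$construct)
  later <- later[later$construct %in% names(ref_ab), ]
  ab <- ifelse(later$detected %in% TRUE & !is.na(later$abundance), later$abundance, 0)
  below <- ab <= depletion_ratio * ref_ab[later$construct]
  n_below <- tapply(below, later$construct, sum)
  sort(names(n_below)[n_below >= min_later_tps])
}

#' Rescue never-detected constructs via cross-line evidence
#'
#' Constructs undetected at every timepoint of this screen, but detected at
#' the reference timepoint in at least one other screened cell line, are
#' flagged as candidates: complete absence despite confirmed library
#' representation is consistent with very strong growth inhibition (though it
#' may also reflect failed transduction).
#'
#' @param replicate_table As in [call_depleted()].
#' @param cross_line_reference Character vector of constructs detected at the
#'   reference timepoint in other cell lines screened with the same library.
#' @return Sorted character vector of rescued constructs.
#' @export
rescue_never_detected <- function(replicate_table, cross_line_reference) {
  if (is.null(cross_line_reference)) .stopf("cross_line_reference is required")
  det <- tapply(replicate_table$detected %in% TRUE, replicate_table$construct, any)
  never <- names(det)[!det]
  sort(intersect(never, cross_line_reference))
}

#' Consensus candidates across replicate screens
#'
#' @param per_replicate_calls List of character vectors (one per replicate
#'   screen) of constructs called in that replicate.
#' @param min_screens Minimum number of replicates a construct must be called
#'   in (default 2, i.e. "at least 2 of 3").
#' @return Sorted character vector of consensus candidates.
#' @export
consensus_candidates <- function(per_replicate_calls, min_screens = 2) {
  if (!length(per_replicate_calls)) .stopf("no replicate call sets supplied")
  if (min_screens > length(per_replicate_calls))
    .stopf("min_screens exceeds the number of replicates")
  counts <- table(unlist(lapply(per_replicate_calls, unique)))
  sort(names(counts)[counts >= min_screens])
}

#' Call candidate constructs from a full screen dataset
#'
#' Runs [call_depleted()] and (when a cross-line reference is available)
#' [rescue_never_detected()] on each replicate, then forms the consensus.
#'
#' @param dataset A `"screen_dataset"` (see [simulate_screen()]) or a list of
#'   replicate tables.
#' @param depletion_ratio,min_later_tps Passed to [call_depleted()].
#' @param min_screens Passed to [consensus_candidates()].
#' @param cross_line_reference Optional constructs detected at the reference
#'   timepoint in other cell lines (overrides `dataset$cross_line_reference`).
#' @return data.frame of class `"candidate_calls"` with one row per construct
#'   ever called: per-replicate flag columns (`"depleted"`,
#'   `"never_detected_rescued"` or `"negative"`), `consensus` (logical) and
#'   `validation` (initialized `"untested"`; see [set_validation()]).
#' @export
call_candidates <- function(dataset, depletion_ratio = 0.5, min_later_tps = 2,
                            min_screens = 2, cross_line_reference = NULL) {
  replicates <- if (inherits(dataset, "screen_dataset")) dataset$replicates else dataset
  ref_tp <- if (inherits(dataset, "screen_dataset")) dataset$reference_timepoint else NULL
  xref <- cross_line_reference %||%
    (if (inherits(dataset, "screen_dataset")) dataset$cross_line_reference else NULL)

  depleted <- lapply(replicates, call_depleted, reference_timepoint = ref_tp,
                     depletion_ratio = depletion_ratio,
                     min_later_tps = min_later_tps)
  rescued <- if (!is.null(xref)) {
    lapply(replicates, rescue_never_detected, cross_line_reference = xref)
  } else {
    rep(list(character()), length(replicates))
  }
  per_rep <- Map(function(d, r) union(d, r), depleted, rescued)
  consensus <- consensus_candidates(per_rep, min_screens = min_screens)

  all_called <- sort(unique(unlist(per_rep)))
  if (!length(all_called)) {
    out <- data.frame(construct = character(),
                      matrix(character(), nrow = 0,
                             ncol = length(replicates),
                             dimnames = list(NULL, paste0("replicate_", seq_along(replicates)))),
                      consensus = logical(), validation = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_calls", "data.frame")
    return(out)
  }
  flags <- vapply(seq_along(replicates), function(r) {
    f <- rep("negative", length(all_called))
    f[all_called %in% depleted[[r]]] <- "depleted"
    f[all_called %in% rescued[[r]]] <- "never_detected_rescued"
    f
  }, character(length(all_called)))
  flags <- matrix(flags, nrow = length(all_called),
                  dimnames = list(NULL, paste0("replicate_", seq_along(replicates))))

  out <- data.frame(construct = all_called, flags,
                    consensus = all_called %in% consensus,
                    validation = "untested",
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_calls", "data.frame")
  out
}

#' Record validation outcomes for candidate constructs
#'
#' @param calls A `"candidate_calls"` data.frame from [call_candidates()] (or
#'   any data.frame with `construct` and `validation` columns).
#' @param construct Construct ids to update.
#' @param status `"validated"`, `"not_validated"` or `"untested"`.
#' @return The updated calls table.
#' @export
set_validation <- function(calls, construct, status) {
  status <- match.arg(status, c("validated", "not_validated", "untested"))
  missing <- setdiff(construct, calls$construct)
  if (length(missing)) .stopf("unknown construct: %s", missing[1])
  calls$validation[calls$construct %in% construct] <- status
  calls
}

#' Candidate validation rate
#'
#' Percentage of tested consensus candidates that validated:
#' `100 * validated / (validated + not_validated)`.
#'
#' @param calls A calls table with `consensus` (logical) and `validation`
#'   (`"validated"` / `"not_validated"` / `"untested"`) columns.
#' @return Percentage (0-100).
#' @export
validation_rate <- function(calls) {
  cc <- calls[calls$consensus %in% TRUE, ]
  n_val <- sum(cc$validation == "validated")
  n_not <- sum(cc$validation == "not_validated")
  if (n_val + n_not == 0) .stopf("no tested consensus candidates")
  100 * n_val / (n_val + n_not)
}
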