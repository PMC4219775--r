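#' Default scenario with planted growth-inhibitory constructs
#'
#' The package's reference simulation: the full pooled library under the
#' default screen conditions with a handful of constructs planted at reduced
#' per-day fitness. Used for recall / false-positive-rate checks of the
#' calling rules.
#'
#' @param n_planted Number of growth-inhibitory constructs to plant.
#' @param planted_fitness Their per-day relative fitness (`< 1`).
#' @param rng_seed Optional integer seed.
#' @param ... Further arguments to [screen_scenario()].
#' @return A `"screen_scenario"`; the planted construct ids are
#'   `names(which(scenario$fitness < 1))`.
#' @export
planted_screen_scenario <- function(n_planted = 5, planted_fitness = 0.85,
                                    rng_seed = NULL, ...) {
  sc <- screen_scenario(rng_seed = rng_seed, ...)
  if (n_planted > sc$library_size) .stopf("n_planted exceeds library_size")
  planted <- names(sc$representation)[seq_len(n_planted)]
  sc$fitness[planted] <- planted_fitness
  sc
}

.pipeline_defaults <- function() {
  list(
    rng_seed = 1L,
    screen = list(
      n_planted = 5L, planted_fitness = 0.85, dropout_floor = 50,
      depletion_ratio = 0.5, min_later_tps = 2L, min_screens = 2L
    ),
    competition = list(
      p0 = 0.5, s_inhibitory = -0.0582, days = seq(0, 35, by = 7),
      events_per_measurement = 10000L, n_replicates = 3L,
      alpha = 0.05, s_threshold = 0
    ),
    qpcr = list(
      slope = -3.3219, intercept = 37, ct_sd = 0.1,
      standard_copies = 10^(1:7), rna_input_ng = 10, rna_per_cell_pg = 12.5,
      truth_copies_per_cell = c(mir_5p = 1814, mir_3p = 3656),
      n_replicate_plates = 3L
    ),
    filter = list(
      n_genes = 1000L, planted = c("TGT1", "TGT2")
    ),
    utr = list(
      length = 803L,
      # synthetic miR sequence (not a natural miR); supply your own via config
      mir_seq = "UACUGCAGACAGUGGCAAUCA",
      site_starts = c(66L, 759L),
      site_types = c("7mer-m8", "8mer-A1")
    )
  )
}

# merge user values over defaults, rejecting unknown keys at both levels
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .stopf("unknown config key: %s%s", path, unknown[1])
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], as.list(user[[k]]),
                                     path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build (and validate) a pipeline configuration
#'
#' All stage parameters default to the package's reference study conditions;
#' supply overrides as nested lists. Unknown keys are rejected by name.
#'
#' @param ... Named overrides, e.g. `rng_seed = 7`,
#'   `screen = list(dropout_floor = 400)`.
#' @return A validated config list of class `"pipeline_config"`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(...) {
  cfg <- .merge_config(.pipeline_defaults(), list(...))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of (possibly partial) configuration values; unknown
#'   keys are rejected by name.
#' @return A validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  structure(.merge_config(.pipeline_defaults(), user),
            class = c("pipeline_config", "list"))
}

#' Run the all-synthetic demonstration pipeline
#'
#' Executes every stage end to end on synthetic data: simulate a pooled
#' screen and call candidates; simulate hit and empty-vector competition
#' series, fit selection coefficients and classify; fit a qPCR standard curve
#' and recover absolute copies per cell; build a prediction universe, filter
#' and shortlist targets; plant and re-scan 3'UTR seed sites. Writes tidy TSV
#' artifacts, a `summary.json` of headline numbers, and a `manifest.json`
#' with the config echo, seed and md5 of every artifact. Byte-identical
#' outputs are produced for identical config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) .stopf("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  artifacts <- character()
  emit <- function(name) artifacts <<- c(artifacts, file.path(out_dir, name))

  ## screen stage
  sc <- config$screen
  scen <- planted_screen_scenario(n_planted = sc$n_planted,
                                  planted_fitness = sc$planted_fitness,
                                  dropout_floor = sc$dropout_floor,
                                  rng_seed = .stage_seed(seed, "screen"))
  ds <- simulate_screen(scen)
  calls <- call_candidates(ds, depletion_ratio = sc$depletion_ratio,
                           min_later_tps = sc$min_later_tps,
                           min_screens = sc$min_screens)
  write_screen_dataset(ds, file.path(out_dir, "screen_detection.tsv"))
  emit("screen_detection.tsv")
  write_tsv_checked(calls, file.path(out_dir, "screen_candidates.tsv"))
  emit("screen_candidates.tsv")
  planted <- names(which(scen$fitness < 1))
  consensus <- calls$construct[calls$consensus]
  screen_summary <- list(
    n_consensus_candidates = length(consensus),
    recall = if (length(planted)) mean(planted %in% consensus) else NA,
    false_positive_rate = mean(setdiff(ds$constructs, planted) %in% consensus)
  )

  ## competition stage
  cm <- config$competition
  fits <- list()
  rows <- list()
  for (grp in c("hit", "empty_vector")) {
    s_true <- if (grp == "hit") cm$s_inhibitory else 0
    p0 <- if (grp == "hit") 0.46 else cm$p0
    series <- simulate_competition(
      competition_scenario(p0 = p0, s = s_true, days = cm$days,
                           events_per_measurement = cm$events_per_measurement,
                           n_replicates = cm$n_replicates, label = grp),
      rng_seed = .stage_seed(seed, "competition") + (grp == "hit"))
    pooled <- as_competition_tidy(series)
    attr(pooled, "events_per_measurement") <- cm$events_per_measurement
    fit <- fit_selection(pooled)
    verdict <- classify_inhibitory(fit, alpha = cm$alpha,
                                   s_threshold = cm$s_threshold)
    fits[[grp]] <- fit
    rows[[grp]] <- data.frame(label = grp, s_true = s_true, s_hat = fit$s,
                              se = fit$se, p0_hat = fit$p0_hat,
                              inhibitory = verdict$inhibitory)
    write_tsv_checked(pooled, file.path(out_dir, paste0("competition_", grp, ".tsv")))
    emit(paste0("competition_", grp, ".tsv"))
  }
  comp_tab <- do.call(rbind, rows)
  rownames(comp_tab) <- NULL
  write_tsv_checked(comp_tab, file.path(out_dir, "competition_fits.tsv"))
  emit("competition_fits.tsv")

  ## quantitation stage
  qc <- config$qpcr
  qseed <- .stage_seed(seed, "qpcr")
  truth_curve <- standard_curve(qc$slope, qc$intercept)
  std_ct <- simulate_qpcr_plate(qc$standard_copies, truth_curve,
                                ct_sd = qc$ct_sd, rng_seed = qseed)
  curve <- fit_standard_curve(qc$standard_copies, std_ct)
  cells <- cell_equivalents(qc$rna_input_ng, qc$rna_per_cell_pg)
  truth_rxn <- qc$truth_copies_per_cell * cells$cells
  sample_ct <- simulate_qpcr_plate(rep(truth_rxn, qc$n_replicate_plates),
                                   truth_curve, ct_sd = qc$ct_sd,
                                   rng_seed = qseed + 1L)
  quant <- quant_absolute(sample_ct, curve, cells)
  quant <- cbind(assay = rep(names(qc$truth_copies_per_cell) %||%
                               seq_along(truth_rxn), qc$n_replicate_plates),
                 quant)
  write_tsv_checked(quant, file.path(out_dir, "qpcr_absolute.tsv"))
  emit("qpcr_absolute.tsv")
  mean_cpc <- tapply(quant$copies_per_cell, quant$assay, mean)

  ## target-filter stage
  fc <- config$filter
  uni <- simulate_prediction_universe(n_genes = fc$n_genes,
                                      planted_targets = fc$planted,
                                      rng_seed = .stage_seed(seed, "filter"))
  sets <- build_sets(uni$predictions, uni$hit_mirs, uni$non_hit_mirs,
                     uni$expression)
  survivors <- filter_targets(sets$set1, sets$set2, sets$set3)
  shortlist <- annotate_and_shortlist(survivors, uni$annotations,
                                      uni$predictions, uni$hit_mirs)
  write_tsv_checked(shortlist, file.path(out_dir, "target_shortlist.tsv"))
  emit("target_shortlist.tsv")

  ## UTR seed-site stage
  uc <- config$utr
  utr <- plant_utr_sites(uc$length, uc$mir_seq, uc$site_starts, uc$site_types,
                         rng_seed = .stage_seed(seed, "utr"))
  write_fasta(utr, file.path(out_dir, "synthetic_utr.fasta"))
  emit("synthetic_utr.fasta")
  sites <- find_seed_sites(utr, uc$mir_seq)
  write_tsv_checked(sites, file.path(out_dir, "seed_sites.tsv"))
  emit("seed_sites.tsv")

  summary <- list(
    screen = screen_summary,
    competition = list(
      s_hat_hit = fits$hit$s, s_hat_empty_vector = fits$empty_vector$s,
      hit_called_inhibitory = comp_tab$inhibitory[comp_tab$label == "hit"],
      empty_vector_called_inhibitory =
        comp_tab$inhibitory[comp_tab$label == "empty_vector"]
    ),
    quantitation = list(
      curve_slope = curve$slope, curve_efficiency = curve$efficiency,
      mean_copies_per_cell = as.list(mean_cpc)
    ),
    target_filter = list(
      set_sizes = lapply(sets, length),
      n_filtered = length(survivors),
      n_growth_related = nrow(shortlist),
      n_shortlisted = sum(shortlist$shortlisted),
      planted_recovered = all(uni$planted %in% shortlist$gene[shortlist$shortlisted])
    ),
    seed_sites = list(n_sites = nrow(sites),
                      classes = as.list(table(sites$site_class)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("summary.json")

  manifest <- list(
    package = "mirhts",
    rng_seed = seed,
    config = unclass(config),
    files = lapply(setNames(artifacts, basename(artifacts)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
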