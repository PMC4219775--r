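#' Simulate a miR target-prediction universe with planted true targets
#'
#' Builds the three inputs of the target-prioritization filter — a prediction
#' table (two sources), an expression-call table and a growth-annotation
#' table — over a synthetic gene universe. Planted targets are guaranteed to
#' survive [filter_targets()] and [annotate_and_shortlist()]: they are
#' predicted for a hit miR by \emph{both} sources with strong scores, called
#' "present", flagged growth-related, and excluded from non-hit-miR
#' predictions. Decoy genes populate every other region of the Venn diagram
#' at the supplied rates.
#'
#' @param n_genes Number of decoy genes in the universe.
#' @param planted_targets Character vector of gene symbols to plant as true
#'   targets (added to the universe if not of the decoy naming scheme).
#' @param hit_mirs miR ids whose predicted targets form Set 1.
#' @param non_hit_mirs miR ids (tested, non-inhibitory) whose predicted
#'   targets form the exclusion Set 2.
#' @param overlap_rates Named list of decoy membership probabilities:
#'   `hit` (predicted for a hit miR), `non_hit` (predicted for a non-hit
#'   miR), `expressed` (call marginal-or-present; 3:1 present:marginal),
#'   `growth` (growth-related annotation), `literature`
#'   (leukemia/oncogenesis literature flag), `both_sources` (probability a
#'   predicted gene is predicted by both sources rather than one).
#' @param rng_seed Optional integer seed.
#'
#' @return A list of class `"prediction_universe"` with elements
#'   `predictions`, `expression`, `annotations` (see [prediction_table()],
#'   [expression_call_table()], [annotation_table()]), plus `planted`,
#'   `hit_mirs`, `non_hit_mirs`.
#' @export
simulate_prediction_universe <- function(n_genes = 1000,
                                         planted_targets = character(),
                                         hit_mirs = c("hit-miR-5p", "hit-miR-3p"),
                                         non_hit_mirs = paste0("ctrl-miR-", 1:4),
                                         overlap_rates = list(hit = 0.3,
                                                              non_hit = 0.4,
                                                              expressed = 0.6,
                                                              growth = 0.2,
                                                              literature = 0.05,
                                                              both_sources = 0.3),
                                         rng_seed = NULL) {
  if (!.is_count(n_genes)) .stopf("n_genes must be a count")
  needed <- c("hit", "non_hit", "expressed", "growth", "literature", "both_sources")
  missing_rates <- setdiff(needed, names(overlap_rates))
  if (length(missing_rates))
    .stopf("overlap_rates missing: %s", paste(missing_rates, collapse = ", "))
  if (length(intersect(hit_mirs, non_hit_mirs)))
    .stopf("hit_mirs and non_hit_mirs must be disjoint")
  .seed_rng(rng_seed)

  decoys <- sprintf("GENE%05d", seq_len(n_genes))
  planted <- toupper(planted_targets)
  if (length(bad <- intersect(planted, decoys)))
    decoys <- setdiff(decoys, bad)
  genes <- c(planted, decoys)

  pred_rows <- list()
  add_pred <- function(gene, mir, sources, score_a, score_b) {
    rows <- data.frame(gene = gene, mir = mir, source = sources,
                       score = ifelse(sources == "predictorA", score_a, score_b))
    pred_rows[[length(pred_rows) + 1L]] <<- rows
  }

  # planted true targets: both sources, strong scores, for every hit miR
  for (g in planted) {
    for (m in hit_mirs) {
      add_pred(g, m, c("predictorA", "predictorB"),
               score_a = -round(runif(1, 0.5, 0.8), 3),
               score_b = round(runif(1, 85, 95), 1))
    }
  }

  # decoys: independent membership in each region
  for (g in decoys) {
    if (runif(1) < overlap_rates$hit) {
      m <- sample(hit_mirs, 1L)
      srcs <- if (runif(1) < overlap_rates$both_sources)
        c("predictorA", "predictorB") else sample(c("predictorA", "predictorB"), 1L)
      add_pred(g, m, srcs,
               score_a = -round(runif(1, 0.05, 0.6), 3),
               score_b = round(runif(1, 50, 90), 1))
    }
    if (runif(1) < overlap_rates$non_hit) {
      m <- sample(non_hit_mirs, 1L)
      src <- sample(c("predictorA", "predictorB"), 1L)
      add_pred(g, m, src,
               score_a = -round(runif(1, 0.05, 0.6), 3),
               score_b = round(runif(1, 50, 90), 1))
    }
  }
  if (length(pred_rows)) {
    predictions <- prediction_table(do.call(rbind, c(pred_rows,
                                                     list(make.row.names = FALSE))))
  } else {
    predictions <- data.frame(gene = character(), mir = character(),
                              source = character(), score = numeric())
  }

  u <- runif(length(decoys))
  call <- ifelse(u < 0.75 * overlap_rates$expressed, "present",
                 ifelse(u < overlap_rates$expressed, "marginal", "absent"))
  expression <- expression_call_table(data.frame(
    gene = genes,
    call = c(rep("present", length(planted)), call)))

  annotations <- annotation_table(data.frame(
    gene = genes,
    growth_related = c(rep(TRUE, length(planted)),
                       runif(length(decoys)) < overlap_rates$growth),
    leukemia_oncogenesis_literature = c(runif(length(planted)) < 0.5,
                                        runif(length(decoys)) < overlap_rates$literature)))

  structure(
    list(predictions = predictions, expression = expression,
         annotations = annotations, planted = planted,
         hit_mirs = hit_mirs, non_hit_mirs = non_hit_mirs),
    class = "prediction_universe"
  )
}

#' @export
print.prediction_universe <- function(x, ...) {
  cat(sprintf("Synthetic prediction universe: %d genes (%d planted targets), %d prediction rows\n",
              nrow(x$expression), length(x$planted), nrow(x$predictions)))
  invisible(x)
}

#' Build a synthetic 3'UTR with planted miR seed-match sites
#'
#' Generates a random-background DNA sequence of the requested length that is
#' guaranteed free of spurious seed matches to `mir_seq`, then plants seed
#' sites of the requested classes at the requested 1-based start positions.
#' Site spans are: 8 nt for `8mer-A1`, 7 nt for `7mer-m8` and `7mer-A1`.
#'
#' @param utr_length Length of the UTR in nucleotides.
#' @param mir_seq Mature miR sequence (RNA or DNA alphabet), length >= 8;
#'   the seed is positions 2-8 read 5'->3'.
#' @param site_positions 1-based start positions of the sites on the UTR.
#' @param site_types Site classes, one per position: `"8mer-A1"`,
#'   `"7mer-m8"` or `"7mer-A1"`.
#' @param rng_seed Optional integer seed.
#' @param name Sequence name for the FASTA record.
#'
#' @return A named character vector of length 1 (the sequence, DNA alphabet)
#'   with attribute `"sites"`: the planted-site table as returned by
#'   [find_seed_sites()] on the result.
#' @seealso [find_seed_sites()], [write_fasta()]
#' @export
plant_utr_sites <- function(utr_length, mir_seq, site_positions = integer(),
                            site_types = character(), rng_seed = NULL,
                            name = "synthetic_utr") {
  if (!.is_count(utr_length) || utr_length < 1)
    .stopf("utr_length must be a positive count")
  mir <- .as_dna(mir_seq)
  if (nchar(mir) < 8) .stopf("mir_seq must be at least 8 nt")
  if (length(site_positions) != length(site_types))
    .stopf("site_positions and site_types lengths differ")
  if (length(site_types))
    site_types <- match.arg(site_types, c("8mer-A1", "7mer-m8", "7mer-A1"),
                            several.ok = TRUE)
  .seed_rng(rng_seed)

  seed_str <- .seed_strings(mir)
  site_seq <- c(`8mer-A1` = seed_str$s8, `7mer-m8` = seed_str$s7m8,
                `7mer-A1` = seed_str$s7a1)[site_types]
  len <- nchar(site_seq)
  ends <- site_positions + len - 1L
  if (any(site_positions < 1) || any(ends > utr_length))
    .stopf("a site exceeds the UTR bounds")
  if (length(site_positions) > 1L) {
    o <- order(site_positions)
    if (any(site_positions[o][-1] <= ends[o][-length(ends)]))
      .stopf("planted sites overlap")
  }

  comp_m8 <- substr(seed_str$s7m8, 1L, 1L)  # UTR base pairing miR position 8
  for (attempt in seq_len(100L)) {
    bases <- sample(c("A", "C", "G", "T"), utr_length, replace = TRUE)
    utr <- paste(bases, collapse = "")
    # scrub spurious seed cores from the background
    for (i in seq_len(200L)) {
      hit <- regexpr(seed_str$core, utr, fixed = TRUE)
      if (hit == -1L) break
      substr(utr, hit, hit + 5L) <- paste(
        sample(c("A", "C", "G", "T"), 6L, replace = TRUE), collapse = "")
    }
    if (regexpr(seed_str$core, utr, fixed = TRUE) != -1L) next

    for (j in seq_along(site_positions)) {
      substr(utr, site_positions[j], ends[j]) <- site_seq[j]
      # keep flanks from upgrading the planted class
      if (site_types[j] == "7mer-m8" && ends[j] < utr_length &&
          substr(utr, ends[j] + 1L, ends[j] + 1L) == "A")
        substr(utr, ends[j] + 1L, ends[j] + 1L) <- sample(c("C", "G", "T"), 1L)
      if (site_types[j] == "7mer-A1" && site_positions[j] > 1L &&
          substr(utr, site_positions[j] - 1L, site_positions[j] - 1L) == comp_m8)
        substr(utr, site_positions[j] - 1L, site_positions[j] - 1L) <-
          sample(setdiff(c("A", "C", "G", "T"), comp_m8), 1L)
    }

    found <- find_seed_sites(utr, mir)
    ok <- nrow(found) == length(site_positions) &&
      (length(site_positions) == 0L ||
         (all(sort(found$start) == sort(site_positions)) &&
            all(found$site_class[order(found$start)] ==
                  site_types[order(site_positions)])))
    if (ok) {
      out <- setNames(utr, name)
      attr(out, "sites") <- found
      return(out)
    }
  }
  .stopf("could not generate a clean background in 100 attempts")
}
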