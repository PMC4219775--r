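#' Validated input tables for target prioritization
#'
#' Constructors that validate and normalize the three tables consumed by the
#' prioritization filter. Gene symbols are matched case-insensitively
#' (uppercased on input); an alias map may be applied first with
#' [normalize_gene_symbols()].
#'
#' @param x A data.frame. For `prediction_table`: columns `gene`, `mir`,
#'   `source` (one of `"predictorA"`, `"predictorB"`) and `score` (finite;
#'   predictorA context-type scores are more negative = stronger, predictorB
#'   target-type scores are higher = stronger); `(gene, mir, source)` must be
#'   unique. For `expression_call_table`: columns `gene`, `call` (one of
#'   `"absent"`, `"marginal"`, `"present"`), one call per gene. For
#'   `annotation_table`: columns `gene`, `growth_related` (logical) and
#'   optionally `leukemia_oncogenesis_literature` (logical, default `FALSE`).
#' @return The validated data.frame with normalized gene symbols.
#' @name filter-tables
NULL

#' @rdname filter-tables
#' @export
prediction_table <- function(x) {
  need <- c("gene", "mir", "source", "score")
  if (length(miss <- setdiff(need, names(x))))
    .stopf("prediction table missing column(s): %s", paste(miss, collapse = ", "))
  x <- x[, need]
  x$gene <- normalize_gene_symbols(x$gene)
  bad <- setdiff(unique(x$source), c("predictorA", "predictorB"))
  if (length(bad)) .stopf("unknown prediction source: %s", bad[1])
  if (any(!is.finite(x$score))) .stopf("scores must be finite")
  key <- paste(x$gene, x$mir, x$source, sep = "\r")
  if (anyDuplicated(key)) .stopf("(gene, mir, source) rows must be unique")
  rownames(x) <- NULL
  x
}

#' @rdname filter-tables
#' @export
expression_call_table <- function(x) {
  need <- c("gene", "call")
  if (length(miss <- setdiff(need, names(x))))
    .stopf("expression table missing column(s): %s", paste(miss, collapse = ", "))
  x <- x[, need]
  x$gene <- normalize_gene_symbols(x$gene)
  bad <- setdiff(unique(x$call), c("absent", "marginal", "present"))
  if (length(bad)) .stopf("unknown expression call: %s", bad[1])
  if (anyDuplicated(x$gene)) .stopf("one expression call per gene required")
  rownames(x) <- NULL
  x
}

#' @rdname filter-tables
#' @export
annotation_table <- function(x) {
  if (!"gene" %in% names(x)) .stopf("annotation table missing column: gene")
  if (!"growth_related" %in% names(x))
    .stopf("annotation table missing column: growth_related")
  if (!"leukemia_oncogenesis_literature" %in% names(x))
    x$leukemia_oncogenesis_literature <- FALSE
  x <- x[, c("gene", "growth_related", "leukemia_oncogenesis_literature")]
  x$gene <- normalize_gene_symbols(x$gene)
  if (!is.logical(x$growth_related) || !is.logical(x$leukemia_oncogenesis_literature))
    .stopf("annotation flags must be logical")
  if (anyDuplicated(x$gene)) .stopf("one annotation row per gene required")
  rownames(x) <- NULL
  x
}

#' Normalize gene symbols (case-insensitive, optional alias map)
#'
#' @param genes Character vector of gene symbols.
#' @param alias_map Optional named character vector mapping alias -> symbol
#'   (applied after uppercasing both sides).
#' @return Uppercased, alias-resolved symbols.
#' @export
normalize_gene_symbols <- function(genes, alias_map = NULL) {
  g <- toupper(as.character(genes))
  if (!is.null(alias_map)) {
    map <- setNames(toupper(alias_map), toupper(names(alias_map)))
    hit <- g %in% names(map)
    g[hit] <- unname(map[g[hit]])
  }
  g
}

#' Build the three gene sets of the prioritization filter
#'
#' Set 1: genes predicted (either source) as targets of any hit miR.
#' Set 2: genes predicted (either source) as targets of any tested
#' non-inhibitory miR. Set 3: genes with expression call `"marginal"` or
#' `"present"` in the screened cell line.
#'
#' @param predictions A [prediction_table()].
#' @param hit_mirs miR ids validated as growth-inhibitory.
#' @param non_hit_mirs miR ids tested and found non-inhibitory. Must be
#'   disjoint from `hit_mirs`; miRs whose overexpression could not be
#'   confirmed should be omitted here (their targets are not excluded).
#' @param expression An [expression_call_table()].
#' @return A list with sorted character vectors `set1`, `set2`, `set3`.
#' @seealso [filter_targets()]
#' @export
build_sets <- function(predictions, hit_mirs, non_hit_mirs, expression) {
  predictions <- prediction_table(predictions)
  expression <- expression_call_table(expression)
  if (length(intersect(hit_mirs, non_hit_mirs)))
    .stopf("hit_mirs and non_hit_mirs overlap: %s",
           intersect(hit_mirs, non_hit_mirs)[1])
  list(
    set1 = sort(unique(predictions$gene[predictions$mir %in% hit_mirs])),
    set2 = sort(unique(predictions$gene[predictions$mir %in% non_hit_mirs])),
    set3 = sort(unique(expression$gene[expression$call %in% c("marginal", "present")]))
  )
}

#' Intersect-and-exclude target filter
#'
#' Returns `(set1 intersect set3) minus set2`: genes predicted as hit-miR
#' targets and expressed in the screened cells, excluding genes also
#' predicted as targets of the tested non-inhibitory miRs.
#'
#' @param set1,set2,set3 Character vectors of gene symbols (as from
#'   [build_sets()]).
#' @return Sorted character vector of surviving genes.
#' @export
filter_targets <- function(set1, set2, set3) {
  s1 <- unique(toupper(set1)); s2 <- unique(toupper(set2)); s3 <- unique(toupper(set3))
  sort(setdiff(intersect(s1, s3), s2))
}

#' Annotate surviving genes and rank the shortlist
#'
#' Restricts the filtered gene set to growth-related genes (per the
#' annotation table; genes missing from it count as not growth-related), then
#' flags genes that are either (a) linked to leukemia/oncogenesis in the
#' literature or (b) predicted for at least one hit miR by \emph{both}
#' prediction sources. Flagged genes are ranked by best (most negative)
#' predictorA score, ties by best (highest) predictorB score, then
#' lexicographically.
#'
#' @param genes Character vector of genes (typically [filter_targets()] output).
#' @param annotations An [annotation_table()].
#' @param predictions A [prediction_table()].
#' @param hit_mirs Hit miR ids (used for the both-source rule and scores).
#' @param alias_map Optional alias map, see [normalize_gene_symbols()].
#' @return A data.frame with one row per growth-related gene: `gene`,
#'   `literature`, `both_sources`, `best_score_a`, `best_score_b`,
#'   `shortlisted`, `rank` (NA for unflagged genes). Rows are ordered
#'   shortlist-first in rank order.
#' @export
annotate_and_shortlist <- function(genes, annotations, predictions, hit_mirs,
                                   alias_map = NULL) {
  genes <- unique(normalize_gene_symbols(genes, alias_map))
  annotations <- annotation_table(annotations)
  predictions <- prediction_table(predictions)

  idx <- match(genes, annotations$gene)
  growth <- !is.na(idx) & annotations$growth_related[idx]
  kept <- genes[growth]
  if (!length(kept)) {
    return(data.frame(gene = character(), literature = logical(),
                      both_sources = logical(), best_score_a = numeric(),
                      best_score_b = numeric(), shortlisted = logical(),
                      rank = integer()))
  }
  lit <- annotations$leukemia_oncogenesis_literature[match(kept, annotations$gene)]

  hp <- predictions[predictions$mir %in% hit_mirs & predictions$gene %in% kept, ]
  best_a <- vapply(kept, function(g) {
    s <- hp$score[hp$gene == g & hp$source == "predictorA"]
    if (length(s)) min(s) else NA_real_
  }, numeric(1))
  best_b <- vapply(kept, function(g) {
    s <- hp$score[hp$gene == g & hp$source == "predictorB"]
    if (length(s)) max(s) else NA_real_
  }, numeric(1))
  both <- !is.na(best_a) & !is.na(best_b)

  out <- data.frame(gene = kept, literature = lit, both_sources = both,
                    best_score_a = best_a, best_score_b = best_b,
                    shortlisted = lit | both)
  ord_key_a <- ifelse(is.na(out$best_score_a), Inf, out$best_score_a)
  ord_key_b <- ifelse(is.na(out$best_score_b), -Inf, out$best_score_b)
  out$rank <- NA_integer_
  fl <- which(out$shortlisted)
  fl <- fl[order(ord_key_a[fl], -ord_key_b[fl], out$gene[fl])]
  out$rank[fl] <- seq_along(fl)
  out <- out[order(!out$shortlisted,
                   ifelse(is.na(out$rank), .Machine$integer.max, out$rank),
                   out$gene), ]
  rownames(out) <- NULL
  out
}

# the three site strings implied by a miR sequence, plus the 6-nt seed core
# (reverse complement of miR positions 2-7) shared by all canonical classes
.seed_strings <- function(mir_dna) {
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  core <- rc(substr(mir_dna, 2L, 7L))
  s7m8 <- rc(substr(mir_dna, 2L, 8L))
  list(core = core, s7m8 = s7m8, s8 = paste0(s7m8, "A"), s7a1 = paste0(core, "A"))
}

#' Scan a 3'UTR for canonical miR seed-match sites
#'
#' Finds Watson-Crick matches on the UTR sense strand to the miR seed
#' (positions 2-7), classifying each locus by its flanks: a match extended by
#' pairing to miR position 8 \emph{and} an adenine opposite miR position 1 is
#' an `8mer-A1`; position-8 pairing alone is a `7mer-m8`; the A1 adenine
#' alone is a `7mer-A1`. The longest class wins at a locus; bare 6mers are
#' not reported. Per TargetScan convention the A1 nucleotide must be an A on
#' the UTR regardless of miR position 1. Coordinates are 1-based inclusive.
#'
#' @param utr UTR sequence (DNA or RNA alphabet). Ambiguous bases never match
#'   and trigger a warning.
#' @param mir_seq Mature miR sequence, length >= 8.
#' @param mir_id Identifier recorded in the output.
#' @return data.frame with columns `mir`, `start`, `end`, `site_class`,
#'   `site_seq`, ordered by `start` (zero rows if no sites).
#' @seealso [plant_utr_sites()], [apply_site_deletion()]
#' @export
find_seed_sites <- function(utr, mir_seq, mir_id = "miR") {
  u <- .as_dna(unname(utr))
  mir <- .as_dna(mir_seq)
  if (nchar(mir) < 8) .stopf("mir_seq must be at least 8 nt")
  s <- strsplit(u, "")[[1]]
  if (any(!s %in% c("A", "C", "G", "T")))
    .warnf("ambiguous bases in UTR: positions containing them are skipped")
  L <- length(s)
  empty <- data.frame(mir = character(), start = integer(), end = integer(),
                      site_class = character(), site_seq = character())
  if (L < 7) return(empty)

  ss <- .seed_strings(mir)
  core <- strsplit(ss$core, "")[[1]]
  comp_m8 <- substr(ss$s7m8, 1L, 1L)

  # all (overlapping) starts of the 6-nt seed core
  n <- L - 5L
  is_core <- rep(TRUE, n)
  for (k in 0:5) is_core <- is_core & s[seq_len(n) + k] == core[k + 1L]
  starts <- which(is_core)
  if (!length(starts)) return(empty)

  rows <- lapply(starts, function(i) {
    m8 <- i > 1L && s[i - 1L] == comp_m8
    a1 <- (i + 6L) <= L && s[i + 6L] == "A"
    if (m8 && a1) {
      data.frame(start = i - 1L, end = i + 6L, site_class = "8mer-A1")
    } else if (m8) {
      data.frame(start = i - 1L, end = i + 5L, site_class = "7mer-m8")
    } else if (a1) {
      data.frame(start = i, end = i + 6L, site_class = "7mer-A1")
    } else {
      NULL
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- data.frame(mir = mir_id, out,
                    site_seq = substring(u, out$start, out$end))
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Delete a seed site from a UTR sequence
#'
#' Excises the site's span, emulating the deletion reporter constructs used
#' to validate direct targeting: re-scanning the returned sequence no longer
#' reports the deleted site, and downstream sites shift left by the deleted
#' width.
#'
#' @param utr UTR sequence.
#' @param site Either a one-row data.frame with `start` and `end` columns
#'   (as returned by [find_seed_sites()]) or a numeric `c(start, end)`
#'   (1-based inclusive).
#' @return The UTR with the span removed (names preserved).
#' @export
apply_site_deletion <- function(utr, site) {
  if (is.data.frame(site)) {
    if (nrow(site) != 1L) .stopf("site must be a single site")
    start <- site$start; end <- site$end
  } else {
    start <- site[1]; end <- site[2]
  }
  u <- unname(utr)
  L <- nchar(u)
  if (start < 1 || end > L || start > end) .stopf("site out of bounds")
  out <- paste0(substr(u, 1L, start - 1L), substr(u, end + 1L, L))
  if (!is.null(names(utr))) names(out) <- names(utr)
  out
}
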