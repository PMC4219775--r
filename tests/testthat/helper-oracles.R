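# Independent oracles and small fixture generators used across test files.

# reverse complement without Biostrings (independent route)
naive_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive position-by-position seed scan: walk every UTR position,
# compare substrings to the site strings spelled out from first principles
naive_seed_scan <- function(utr, mir) {
  utr <- chartr("U", "T", toupper(utr))
  mir <- chartr("U", "T", toupper(mir))
  core <- naive_revcomp(substr(mir, 2, 7))
  m8_base <- naive_revcomp(substr(mir, 8, 8))
  L <- nchar(utr)
  out <- list()
  if (L >= 6) {
    for (i in seq_len(L - 5)) {
      if (substr(utr, i, i + 5) != core) next
      m8 <- i > 1 && substr(utr, i - 1, i - 1) == m8_base
      a1 <- (i + 6) <= L && substr(utr, i + 6, i + 6) == "A"
      if (m8 && a1) {
        out[[length(out) + 1]] <- data.frame(start = i - 1, end = i + 6,
                                             site_class = "8mer-A1")
      } else if (m8) {
        out[[length(out) + 1]] <- data.frame(start = i - 1, end = i + 5,
                                             site_class = "7mer-m8")
      } else if (a1) {
        out[[length(out) + 1]] <- data.frame(start = i, end = i + 6,
                                             site_class = "7mer-A1")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      site_class = character()))
  }
  do.call(rbind, out)
}

# per-gene membership test of the intersect-and-exclude filter, straight from
# the three raw tables
oracle_filter <- function(pred, hit_mirs, non_hit_mirs, expr) {
  genes <- unique(toupper(expr$gene))
  keep <- vapply(genes, function(g) {
    pg <- toupper(pred$gene) == g
    in1 <- any(pg & pred$mir %in% hit_mirs)
    in2 <- any(pg & pred$mir %in% non_hit_mirs)
    in3 <- expr$call[match(g, toupper(expr$gene))] %in% c("marginal", "present")
    in1 && in3 && !in2
  }, logical(1))
  sort(genes[keep])
}

# a random small prediction/expression universe for oracle comparisons
random_filter_universe <- function(n_genes = 30) {
  genes <- paste0("G", seq_len(n_genes))
  hit <- c("mh1", "mh2")
  non <- c("mn1", "mn2", "mn3")
  combos <- expand.grid(gene = genes, mir = c(hit, non),
                        source = c("predictorA", "predictorB"),
                        stringsAsFactors = FALSE)
  pred <- combos[runif(nrow(combos)) < 0.15, ]
  pred$score <- ifelse(pred$source == "predictorA",
                       -round(runif(nrow(pred), 0.01, 1), 3),
                       round(runif(nrow(pred), 40, 99), 1))
  expr <- data.frame(gene = genes,
                     call = sample(c("absent", "marginal", "present"),
                                   n_genes, replace = TRUE))
  list(pred = pred, expr = expr, hit = hit, non = non)
}

# two-component flow mixture with known quadrant weights
flow_mixture <- function(n, weights, x_hi = 100, y_hi = 100) {
  quadrant <- sample(1:4, n, replace = TRUE, prob = weights)
  data.frame(
    x = ifelse(quadrant %in% c(2, 4), x_hi, 0) + runif(n, 0, 10),
    y = ifelse(quadrant %in% c(3, 4), y_hi, 0) + runif(n, 0, 10)
  )
}

# minimal one-replicate detection table builder
detection_table <- function(construct, timepoint_day, abundance) {
  data.frame(construct = construct, timepoint_day = timepoint_day,
             copies = ifelse(is.na(abundance), 0, abundance),
             detected = !is.na(abundance),
             abundance = abundance)
}
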