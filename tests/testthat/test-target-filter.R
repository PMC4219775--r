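test_that("set construction honors the hit / non-hit miR split", {
  pred <- data.frame(
    gene = c("A", "B", "C", "D", "E", "F"),
    mir = c("hit-1", "hit-2", "non-1", "non-2", "excluded-mir", "non-4"),
    source = c("predictorA", "predictorB", "predictorA", "predictorB",
               "predictorA", "predictorA"),
    score = c(-0.6, 90, -0.3, 70, -0.2, 60))
  expr <- data.frame(gene = LETTERS[1:6],
                     call = c("present", "marginal", "present", "absent",
                              "present", "present"))
  # the miR whose overexpression failed is omitted from the exclusion set,
  # so its targets do not enter Set 2
  sets <- build_sets(pred, hit_mirs = c("hit-1", "hit-2"),
                     non_hit_mirs = c("non-1", "non-2", "non-3", "non-4"),
                     expression = expr)
  expect_setequal(sets$set1, c("A", "B"))
  expect_setequal(sets$set2, c("C", "D", "F"))
  expect_false("E" %in% sets$set2)
  expect_setequal(sets$set3, c("A", "B", "C", "E", "F"))
  expect_error(build_sets(pred, "hit-1", c("hit-1", "non-1"), expr), "overlap")
})

test_that("the intersect-and-exclude filter is exact set arithmetic", {
  expect_setequal(filter_targets(c("A", "B", "C", "D"), "B", c("A", "B", "C")),
                  c("A", "C"))
  expect_length(filter_targets(c("A", "B"), c("A", "B", "C"), c("A", "B")), 0)
  # idempotent and order-independent
  out <- filter_targets(c("b", "a", "C"), "B", c("c", "A", "b"))
  expect_identical(out, filter_targets(rev(c("b", "a", "C")), "B",
                                       sample(c("c", "A", "b"))))
  expect_identical(filter_targets(out, "B", out), setdiff(out, "B"))
})

test_that("filter output equals the brute-force membership oracle on random universes", {
  set.seed(404)
  for (i in 1:100) {
    u <- random_filter_universe(n_genes = sample(10:40, 1))
    sets <- build_sets(u$pred, u$hit, u$non, u$expr)
    got <- filter_targets(sets$set1, sets$set2, sets$set3)
    expect_identical(got, oracle_filter(u$pred, u$hit, u$non, u$expr))
    # monotonicity: dropping genes from the exclusion set never shrinks output
    smaller_set2 <- sets$set2[-1][seq_len(max(0, length(sets$set2) - 1))]
    expect_true(all(got %in% filter_targets(sets$set1, smaller_set2, sets$set3)))
    expect_lte(length(got), length(sets$set1))
  }
})

test_that("shortlist keeps growth genes and ranks by prediction strength", {
  pred <- data.frame(
    gene = c("STRONG", "STRONG", "WEAK", "WEAK", "LITONLY", "NOGROWTH", "NOGROWTH"),
    mir = "hit-1",
    source = c("predictorA", "predictorB", "predictorA", "predictorB",
               "predictorA", "predictorA", "predictorB"),
    score = c(-0.65, 91, -0.30, 80, -0.2, -0.99, 99))
  ann <- data.frame(
    gene = c("STRONG", "WEAK", "LITONLY", "UNFLAGGED"),
    growth_related = TRUE,
    leukemia_oncogenesis_literature = c(FALSE, FALSE, TRUE, FALSE))
  out <- annotate_and_shortlist(c("STRONG", "WEAK", "LITONLY", "NOGROWTH", "UNFLAGGED"),
                                ann, pred, hit_mirs = "hit-1")
  # genes missing from the annotation table or not growth-related are dropped
  expect_false("NOGROWTH" %in% out$gene)
  expect_true("UNFLAGGED" %in% out$gene)
  expect_false(out$shortlisted[out$gene == "UNFLAGGED"])
  # both-source support with stronger scores outranks weaker support;
  # literature-only genes are flagged even without both-source support
  sl <- out[out$shortlisted, ]
  expect_equal(sl$gene[sl$rank == 1], "STRONG")
  expect_equal(sl$gene[sl$rank == 2], "WEAK")
  expect_true("LITONLY" %in% sl$gene)
  # empty when nothing is growth-related
  none <- annotate_and_shortlist("X", data.frame(gene = "X", growth_related = FALSE,
                                                 leukemia_oncogenesis_literature = FALSE),
                                 pred, "hit-1")
  expect_equal(nrow(none), 0)
})

test_that("shortlist ranking matches an explicit pairwise comparator", {
  set.seed(77)
  uni <- simulate_prediction_universe(n_genes = 300, planted_targets = "TGTX",
                                      rng_seed = 88)
  sets <- build_sets(uni$predictions, uni$hit_mirs, uni$non_hit_mirs, uni$expression)
  surv <- filter_targets(sets$set1, sets$set2, sets$set3)
  out <- annotate_and_shortlist(surv, uni$annotations, uni$predictions, uni$hit_mirs)
  ranked <- out[out$shortlisted, ]
  ranked <- ranked[order(ranked$rank), ]
  key <- function(row) {
    a <- if (is.na(row$best_score_a)) Inf else row$best_score_a
    b <- if (is.na(row$best_score_b)) -Inf else row$best_score_b
    list(a = a, b = b, g = row$gene)
  }
  if (nrow(ranked) > 1) {
    for (i in seq_len(nrow(ranked) - 1)) {
      k1 <- key(ranked[i, ]); k2 <- key(ranked[i + 1, ])
      expect_true(k1$a < k2$a ||
                    (k1$a == k2$a && k1$b > k2$b) ||
                    (k1$a == k2$a && k1$b == k2$b && k1$g < k2$g))
    }
  }
})

test_that("seed-site scanner matches the exhaustive naive scan on random input", {
  set.seed(303)
  for (i in 1:250) {
    mir <- random_dna(sample(19:23, 1))
    utr <- random_dna(sample(40:250, 1))
    got <- find_seed_sites(utr, mir)
    want <- naive_seed_scan(utr, mir)
    expect_equal(got[, c("start", "end", "site_class")], want,
                 ignore_attr = TRUE)
  }
})

test_that("sliding a planted site shifts its reported coordinates accordingly", {
  mir <- "UACUGCAGACAGUGGCAAUCA"
  for (k in c(0, 5, 40)) {
    utr <- plant_utr_sites(200, mir, 30 + k, "8mer-A1", rng_seed = 99)
    s <- find_seed_sites(utr, mir)
    expect_equal(c(s$start, s$end), c(30 + k, 37 + k))
  }
})

test_that("site deletion removes exactly the targeted site", {
  mir <- "UACUGCAGACAGUGGCAAUCA"
  utr <- plant_utr_sites(803, mir, c(66, 759), c("7mer-m8", "8mer-A1"),
                         rng_seed = 17)
  sites <- find_seed_sites(utr, mir)
  d1 <- apply_site_deletion(utr, sites[1, ])
  after1 <- find_seed_sites(d1, mir)
  expect_equal(nrow(after1), 1)
  expect_equal(after1$site_class, "8mer-A1")
  expect_equal(after1$start, 759 - (sites$end[1] - sites$start[1] + 1))
  d2 <- apply_site_deletion(utr, sites[2, ])
  expect_equal(find_seed_sites(d2, mir)$site_class, "7mer-m8")
  d12 <- apply_site_deletion(d1, find_seed_sites(d1, mir))
  expect_equal(nrow(find_seed_sites(d12, mir)), 0)
  # deleting a non-site span keeps both sites, shifted
  d_mid <- apply_site_deletion(utr, c(200, 209))
  after <- find_seed_sites(d_mid, mir)
  expect_equal(after$start, c(66, 749))
  expect_error(apply_site_deletion(utr, c(800, 950)), "bounds")
})

test_that("ambiguous UTR bases are skipped with a warning", {
  mir <- "UACUGCAGACAGUGGCAAUCA"
  utr <- plant_utr_sites(100, mir, 40, "8mer-A1", rng_seed = 12)
  masked <- unname(utr)
  substr(masked, 43, 43) <- "N"   # inside the seed core
  expect_warning(res <- find_seed_sites(masked, mir), "ambiguous")
  expect_equal(nrow(res), 0)
})

test_that("table constructors validate their contracts", {
  expect_error(prediction_table(data.frame(gene = "A")), "missing column")
  expect_error(prediction_table(data.frame(gene = "A", mir = "m",
                                           source = "other", score = 1)),
               "unknown prediction source")
  dup <- data.frame(gene = c("a", "A"), mir = "m", source = "predictorA",
                    score = 1:2)
  expect_error(prediction_table(dup), "unique")
  expect_error(expression_call_table(data.frame(gene = "A", call = "high")),
               "unknown expression call")
  expect_error(annotation_table(data.frame(gene = "A", growth_related = 1)),
               "logical")
  # alias mapping is case-insensitive
  expect_equal(normalize_gene_symbols(c("rab5c", "OldName"),
                                      alias_map = c(oldname = "NEWNAME")),
               c("RAB5C", "NEWNAME"))
})
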