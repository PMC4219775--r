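make_replicate <- function(abundances) {
  # abundances: named list construct -> vector over days 4/12/20/28 (NA = undetected)
  do.call(rbind, lapply(names(abundances), function(cn) {
    detection_table(cn, c(4, 12, 20, 28), abundances[[cn]])
  }))
}

test_that("ratio-threshold depletion calling covers the canonical patterns", {
  tab <- make_replicate(list(
    vanish   = c(100, NA, NA, NA),     # detected at reference only
    constant = c(100, 100, 100, 100),  # stable
    halving  = c(100, 50, 25, 12.5),   # exactly at the inclusive threshold
    dip_once = c(100, 30, 90, 95),     # only one later timepoint below
    never    = c(NA, NA, NA, NA)       # not callable by this rule
  ))
  called <- call_depleted(tab, reference_timepoint = 4,
                          depletion_ratio = 0.5, min_later_tps = 2)
  expect_setequal(called, c("vanish", "halving"))
  expect_error(call_depleted(tab, depletion_ratio = 0), "depletion_ratio")
  expect_error(call_depleted(tab, reference_timepoint = 5), "not present")
})

test_that("depletion calls are monotone in the depletion ratio", {
  tab <- make_replicate(list(
    a = c(100, 60, 55, 50), b = c(100, 40, 35, 30),
    c = c(100, 10, 8, 5), d = c(100, 90, 95, 100)
  ))
  ratios <- c(0.05, 0.1, 0.35, 0.55, 0.65, 1)
  calls <- lapply(ratios, function(r) call_depleted(tab, 4, r, 2))
  for (i in seq_along(ratios)[-1]) {
    expect_true(all(calls[[i - 1]] %in% calls[[i]]))
  }
})

test_that("never-detected constructs are rescued only with cross-line evidence", {
  tab <- make_replicate(list(
    ghost  = c(NA, NA, NA, NA),
    absent = c(NA, NA, NA, NA),
    seen   = c(100, NA, NA, NA)
  ))
  expect_equal(rescue_never_detected(tab, c("ghost", "seen")), "ghost")
  expect_length(rescue_never_detected(tab, character()), 0)
  expect_error(rescue_never_detected(tab, NULL), "cross_line_reference")
})

test_that("consensus is plain at-least-k set arithmetic, order-invariant", {
  calls <- list(c("A", "B"), c("B", "C"), "D")
  expect_equal(consensus_candidates(calls, 2), "B")
  expect_setequal(consensus_candidates(calls, 1), c("A", "B", "C", "D"))
  expect_error(consensus_candidates(list(), 1), "no replicate")
  expect_error(consensus_candidates(calls, 4), "min_screens")
  # permutation invariance over replicates
  set.seed(2)
  for (i in 1:10) {
    perm <- sample(calls)
    expect_identical(consensus_candidates(perm, 2), consensus_candidates(calls, 2))
  }
})

test_that("validation-rate bookkeeping matches the worked ratios", {
  calls <- data.frame(construct = paste0("m", 1:5), consensus = TRUE,
                      validation = c("validated", rep("not_validated", 4)))
  expect_equal(validation_rate(calls), 20)
  calls4 <- data.frame(construct = paste0("m", 1:4), consensus = TRUE,
                       validation = c(rep("validated", 3), "not_validated"))
  expect_equal(validation_rate(calls4), 75)
  all_val <- data.frame(construct = "m", consensus = TRUE, validation = "validated")
  expect_equal(validation_rate(all_val), 100)
  untested <- data.frame(construct = "m", consensus = TRUE, validation = "untested")
  expect_error(validation_rate(untested), "no tested")
})

test_that("planted inhibitory constructs are recovered with few false positives", {
  sc <- planted_screen_scenario(n_planted = 5, planted_fitness = 0.85,
                                rng_seed = 101)
  ds <- simulate_screen(sc)
  calls <- call_candidates(ds)
  planted <- names(which(sc$fitness < 1))
  consensus <- calls$construct[calls$consensus]
  recall <- mean(planted %in% consensus)
  fpr <- mean(setdiff(ds$constructs, planted) %in% consensus)
  expect_gte(recall, 0.8)
  expect_lte(fpr, 0.05)
  # the validation workflow runs end to end on the calls table
  calls <- set_validation(calls, consensus[1], "validated")
  others <- setdiff(consensus, consensus[1])
  if (length(others)) calls <- set_validation(calls, others, "not_validated")
  expect_equal(validation_rate(calls), 100 / length(consensus))
})

test_that("raising the dropout floor inflates false candidates in neutral screens", {
  # sporadic detection failure at low template copies creates false dropout
  # calls; the effect grows as the stochastic-detection floor approaches the
  # typical per-construct template abundance
  n_false <- sapply(c(50, 400), function(fl) {
    sc <- screen_scenario(dropout_floor = fl, rng_seed = 73)
    calls <- call_candidates(simulate_screen(sc))
    sum(calls$consensus)
  })
  expect_lte(n_false[1], 2)
  expect_gt(n_false[2], n_false[1])
})

test_that("candidate tables route reference-undetected constructs to the rescue flag", {
  tabs <- lapply(1:3, function(r) make_replicate(list(
    ghost = c(NA, NA, NA, NA),
    drop  = c(100, 20, NA, NA),
    ok    = c(100, 100, 100, 100)
  )))
  calls <- call_candidates(tabs, cross_line_reference = "ghost")
  expect_setequal(calls$construct, c("ghost", "drop"))
  expect_true(all(calls$consensus))
  expect_equal(unname(unlist(calls[calls$construct == "ghost",
                                   paste0("replicate_", 1:3)])),
               rep("never_detected_rescued", 3))
  expect_equal(unname(unlist(calls[calls$construct == "drop",
                                   paste0("replicate_", 1:3)])),
               rep("depleted", 3))
})
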