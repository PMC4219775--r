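test_that("transduced fraction follows the Poisson single-hit zero class", {
  sc <- screen_scenario(library_size = 10, n_cells_infected = 2e5,
                        timepoints = c(4), n_replicates = 3,
                        cells_sampled_per_tp = 1e5, dropout_floor = 0,
                        rng_seed = 41)
  expect_equal(sc$transduced_fraction_expected, 1 - exp(-0.3))
  # empirical founder fraction across replicates (binomial, ~3e-3 sd here)
  set.seed(41)
  n_trans <- replicate(20, rbinom(1, 2e5, sc$transduced_fraction_expected))
  expect_lt(abs(mean(n_trans) / 2e5 - (1 - exp(-0.3))), 0.002)
  expect_error(screen_scenario(library_size = 0), "library_size")
  expect_error(screen_scenario(moi = -0.1), "moi")
})

test_that("neutral screens reproduce the library representation at every timepoint", {
  rep_frac <- (1:20) / sum(1:20)
  sc <- screen_scenario(library_size = 20, representation = rep_frac,
                        dropout_floor = 0, rng_seed = 7)
  ds <- simulate_screen(sc)
  for (r in seq_along(ds$replicates)) {
    tab <- ds$replicates[[r]]
    for (tp in ds$timepoints) {
      share <- tab$copies[tab$timepoint_day == tp] / sc$cells_sampled_per_tp
      # untransduced cells absorb the remainder; compare construct proportions
      expect_lt(max(abs(share / sum(share) - rep_frac)), 0.005)
      expect_true(all(tab$detected[tab$timepoint_day == tp] == (tab$copies[tab$timepoint_day == tp] > 0)))
    }
  }
})

test_that("a low-fitness construct's abundance share declines across timepoints", {
  sc <- screen_scenario(library_size = 50, fitness = c(construct_0001 = 0.85),
                        dropout_floor = 0, rng_seed = 13)
  ds <- simulate_screen(sc)
  shares <- sapply(ds$timepoints, function(tp) {
    mean(sapply(ds$replicates, function(tab) {
      tot <- sum(tab$copies[tab$timepoint_day == tp])
      tab$copies[tab$timepoint_day == tp & tab$construct == "construct_0001"] / tot
    }))
  })
  expect_true(all(diff(shares) < 0))
  # closed-form expectation over the growth model
  p_tr <- 1 - exp(-sc$moi)
  expected <- sapply(ds$timepoints, function(t) {
    clone <- p_tr * sc$representation * sc$fitness^t
    (clone / (sum(clone) + (1 - p_tr)))[["construct_0001"]]
  })
  expect_equal(unname(shares), unname(expected), tolerance = 0.05)
})

test_that("screen simulation is reproducible under a fixed seed", {
  sc <- screen_scenario(library_size = 30, rng_seed = 99)
  expect_identical(simulate_screen(sc), simulate_screen(sc))
})

test_that("competition simulator matches the two-population closed form", {
  # neutral fixed point
  neutral <- simulate_competition(competition_scenario(s = 0, rng_seed = 5))
  finals <- sapply(neutral, function(s) s$pct_gfp[s$day == 35])
  expect_equal(mean(finals), 0.5, tolerance = 0.015)
  # the printed-endpoint trajectory: logit-slope chosen to go 46% -> 10%
  s_true <- (qlogis(0.10) - qlogis(0.46)) / 35
  expect_equal(project_gfp(0.46, s_true, 35), 0.10, tolerance = 1e-12)
  expect_equal(project_gfp(0.46, -0.0582, 35), 0.100, tolerance = 1e-3)
  # monotone decline for s < 0
  traj <- project_gfp(0.46, -0.02, 0:35)
  expect_true(all(diff(traj) < 0))
  expect_error(competition_scenario(events_per_measurement = 0), "events")
  expect_error(competition_scenario(p0 = 1), "p0")
})

test_that("competition means converge to the deterministic trajectory", {
  sc_small <- competition_scenario(p0 = 0.4, s = -0.03,
                                   events_per_measurement = 100,
                                   n_replicates = 200, rng_seed = 11)
  sc_big <- competition_scenario(p0 = 0.4, s = -0.03,
                                 events_per_measurement = 1e5,
                                 n_replicates = 200, rng_seed = 11)
  truth <- project_gfp(0.4, -0.03, sc_small$days)
  err <- function(sim) {
    obs <- rowMeans(sapply(sim, function(s) s$pct_gfp))
    max(abs(obs - truth))
  }
  expect_lt(err(simulate_competition(sc_big)), err(simulate_competition(sc_small)))
  expect_lt(err(simulate_competition(sc_big)), 5e-4)
})

test_that("qPCR plate simulation follows the standard-curve line", {
  curve <- standard_curve(-3.3219, 37)
  expect_equal(simulate_qpcr_plate(1, curve, ct_sd = 0), 37.0)
  expect_equal(simulate_qpcr_plate(1000, curve, ct_sd = 0), 37 - 3.3219 * 3,
               tolerance = 1e-12)
  expect_true(is.na(simulate_qpcr_plate(0, curve, ct_sd = 0)))
  expect_error(simulate_qpcr_plate(-1, curve), "true_copies")
  set.seed(1)
  noisy <- simulate_qpcr_plate(rep(1000, 2000), curve, ct_sd = 0.3, rng_seed = 8)
  expect_equal(sd(noisy), 0.3, tolerance = 0.05)
})

test_that("prediction universe region counts match a brute-force recount", {
  uni <- simulate_prediction_universe(n_genes = 500,
                                      planted_targets = c("TGTA", "TGTB"),
                                      rng_seed = 21)
  sets <- build_sets(uni$predictions, uni$hit_mirs, uni$non_hit_mirs,
                     uni$expression)
  # recount each set straight from the raw tables
  expect_identical(sets$set1,
                   sort(unique(toupper(uni$predictions$gene[uni$predictions$mir %in% uni$hit_mirs]))))
  expect_identical(sets$set2,
                   sort(unique(toupper(uni$predictions$gene[uni$predictions$mir %in% uni$non_hit_mirs]))))
  expect_identical(sets$set3,
                   sort(unique(toupper(uni$expression$gene[uni$expression$call != "absent"]))))
  # planted targets survive the filter by construction
  surv <- filter_targets(sets$set1, sets$set2, sets$set3)
  expect_true(all(uni$planted %in% surv))
  # with zero rates and no planted targets the filter output is empty
  zero <- simulate_prediction_universe(n_genes = 100,
                                       overlap_rates = list(hit = 0, non_hit = 0,
                                                            expressed = 0, growth = 0,
                                                            literature = 0, both_sources = 0),
                                       rng_seed = 3)
  zsets <- build_sets(zero$predictions, zero$hit_mirs, zero$non_hit_mirs,
                      zero$expression)
  expect_length(filter_targets(zsets$set1, zsets$set2, zsets$set3), 0)
})

test_that("planted UTR sites are recovered exactly and backgrounds are clean", {
  mir <- "UACUGCAGACAGUGGCAAUCA"
  utr <- plant_utr_sites(803, mir, c(66, 759), c("7mer-m8", "8mer-A1"),
                         rng_seed = 17)
  sites <- find_seed_sites(utr, mir)
  expect_equal(sites$start, c(66, 759))
  expect_equal(sites$end, c(72, 766))
  expect_equal(sites$site_class, c("7mer-m8", "8mer-A1"))
  # empty plant: background guaranteed free of matches
  bare <- plant_utr_sites(500, mir, rng_seed = 18)
  expect_equal(nrow(find_seed_sites(bare, mir)), 0)
  # site planted flush against the 5' edge keeps full coordinates
  edge <- plant_utr_sites(40, mir, 1, "8mer-A1", rng_seed = 19)
  esites <- find_seed_sites(edge, mir)
  expect_equal(c(esites$start, esites$end), c(1, 8))
  expect_equal(esites[, c("start", "end", "site_class")],
               naive_seed_scan(edge, mir), ignore_attr = TRUE)
  expect_error(plant_utr_sites(100, mir, c(10, 12), c("7mer-m8", "7mer-m8")),
               "overlap")
  expect_error(plant_utr_sites(100, mir, 99, "8mer-A1"), "bounds")
  # reproducible under seed
  expect_identical(plant_utr_sites(200, mir, 50, "7mer-A1", rng_seed = 4),
                   plant_utr_sites(200, mir, 50, "7mer-A1", rng_seed = 4))
})
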