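test_that("world configuration validates its invariants", {
  expect_error(world_config(data.frame()), "nonempty")
  sp <- tiny_species(2)
  expect_error(world_config(sp, survey_years = c(1993, 1990),
                            registry = shared_registry(sp$species)),
               "strictly increasing")
  expect_error(world_config(sp, age_simplex = c("0" = 0.5, "1" = 0.6,
                                                "2" = 0, "3+" = 0),
                            registry = shared_registry(sp$species)),
               "sum to 1")
  bad <- sp; bad$diet_pollock <- c(1.2, 0.1)
  expect_error(world_config(bad, registry = shared_registry(sp$species)),
               "\\[0, 1\\]")
  expect_error(world_config(sp, registry = bioenergetics_params()),
               "registry")
})

test_that("truth is deterministic and stores configured parameters", {
  cfg <- world_config_dominant(seed = 3)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$density, t2$density)
  expect_equal(unique(t1$diet$p_pollock[t1$diet$species == "ATF"]), 0.74)
  ts <- truth_summary(t1)
  expect_equal(mean(ts$p_pollock[ts$species == "ATF"]), 0.74)
  # true relative densities are a simplex over areas per species-year
  sums <- tapply(ts$rD, paste(ts$species, ts$year), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("a uniform intensity surface yields equal cell densities", {
  cfg <- uniform_world()
  truth <- generate_truth(cfg)
  expect_equal(length(unique(truth$density$D)), 1L)
})

test_that("survey catches are zero-inflated around the truth density", {
  cfg <- uniform_world(seed = 2, occupancy = 0.7, years = c(1990, 1993))
  truth <- generate_truth(cfg)
  svy <- simulate_survey(truth, survey_design(truth, 200), seed = 10)
  n <- nrow(svy$catches)
  expect_equal(n, nrow(svy$hauls))
  # occupancy of catches matches the configured rate within binomial error
  occ_hat <- mean(svy$catches$cpue > 0)
  expect_lt(abs(occ_hat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  # mean CPUE (zeros included) estimates the uniform truth density
  d <- truth$density$D[1]
  se <- sd(svy$catches$cpue) / sqrt(n)
  expect_lt(abs(mean(svy$catches$cpue) - d), 3 * se)
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- tiny_world(seed = 4)
  truth <- generate_truth(cfg)
  s1 <- simulate_survey(truth, survey_design(truth, 10), seed = 77)
  s2 <- simulate_survey(truth, survey_design(truth, 10), seed = 77)
  expect_identical(s1, s2)
  st1 <- simulate_stomachs(truth, s1, seed = 78)
  st2 <- simulate_stomachs(truth, s1, seed = 78)
  expect_identical(st1, st2)
})

test_that("zero-density species catch nothing and absent area-years stay absent", {
  sp <- tiny_species(2)
  sp$base_density[2] <- 0
  cfg <- world_config(sp, survey_years = c(1990, 1993),
                      registry = shared_registry(sp$species), seed = 5)
  truth <- generate_truth(cfg)
  design <- survey_design(truth, 10)
  design <- design[!(design$year == 1993 & design$stat_area == "650"), ]
  svy <- simulate_survey(truth, design, seed = 6)
  expect_true(all(svy$catches$cpue[svy$catches$species == "SP2"] == 0))
  h <- merge(svy$hauls, data.frame(year = 1993, stat_area = "650"))
  expect_equal(nrow(h), 0)
  expect_error(simulate_survey(truth, data.frame(year = 1990,
                                                 stat_area = "999",
                                                 n_hauls = 5)),
               "undefined areas")
})

test_that("the bin cap limits stomachs per haul and bin", {
  cfg <- tiny_world(seed = 8, n = 1, diet = 0.5)
  truth <- generate_truth(cfg)
  svy <- simulate_survey(truth, survey_design(truth, 10), seed = 9)
  st <- simulate_stomachs(truth, svy, bin_cap = 1, seed = 10)
  preds <- unique(st[, c("stomach_id", "haul", "pred_length_cm")])
  preds$bin <- length_bin(preds$pred_length_cm)
  per_bin <- table(paste(preds$haul, preds$bin))
  expect_true(all(per_bin <= 1))
  # a haul whose catch spans 3 bins yields at most 3 stomachs
  per_haul <- table(preds$haul)
  catch_bins <- tapply(length_bin(svy$lengths$length_cm),
                       svy$lengths$haul,
                       function(x) length(unique(x)))
  expect_true(all(per_haul <= catch_bins[names(per_haul)]))
})

test_that("zero diet share produces no focal-prey items", {
  cfg <- tiny_world(seed = 12, n = 1, diet = 0)
  truth <- generate_truth(cfg)
  svy <- simulate_survey(truth, survey_design(truth, 10), seed = 13)
  st <- simulate_stomachs(truth, svy, seed = 14)
  expect_false(any(st$prey_taxon %in% "pollock"))
})

test_that("unbiased subsampling recovers the raw gravimetric diet share", {
  cfg <- tiny_world(seed = 15, n = 1, diet = 0.6,
                    years = c(1990, 1993))
  truth <- generate_truth(cfg)
  svy <- simulate_survey(truth, survey_design(truth, 60), seed = 16)
  st <- simulate_stomachs(truth, svy, bin_cap = NULL, srs_n = 4, seed = 17)
  # brute-force averaging of the simulated prey masses
  pol <- sum(st$prey_mass_g[st$prey_taxon %in% "pollock"])
  tot <- sum(st$prey_mass_g, na.rm = TRUE)
  expect_equal(pol / tot, 0.6, tolerance = 0.05)
  # empty catch table -> empty stomach table, not an error
  svy0 <- svy
  svy0$lengths <- svy0$lengths[0, ]
  expect_equal(nrow(simulate_stomachs(truth, svy0, seed = 1)), 0)
})
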