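test_that("length weighting factors are catch over subsample proportions", {
  # one haul: catch composition (0.27, 0.52, 0.21), subsample (0.35, 0.35, 0.30)
  catch <- data.frame(haul = 1, species = "SBL",
                      length_cm = c(47, 58, 66),
                      count = c(27, 52, 21))
  stom <- data.frame(haul = 1, species = "SBL",
                     length_cm = rep(c(47, 58, 66), c(7, 7, 6)))
  wf <- length_weighting_factors(catch, stom)
  expect_equal(wf$WF_L[wf$bin == 40], 0.27 / 0.35)  # down-weight ~ 0.771
  expect_equal(wf$WF_L[wf$bin == 50], 0.52 / 0.35)  # up-weight ~ 1.486
  expect_equal(sum(wf$P_T), 1)
  expect_equal(sum(wf$P_F), 1)
})

test_that("matching compositions give unit length weights", {
  catch <- data.frame(haul = 1, species = "A",
                      length_cm = c(15, 25, 35), count = c(2, 4, 2))
  stom <- data.frame(haul = 1, species = "A",
                     length_cm = rep(c(15, 25, 35), c(2, 4, 2)))
  wf <- length_weighting_factors(catch, stom)
  expect_equal(wf$WF_L, rep(1, 3))
})

test_that("biomass weighting factors are densities over their mean", {
  field <- data.frame(species = "A", year = 1990, cell = 1:3,
                      D = c(2, 4, 6))
  wf <- biomass_weighting_factors(field)
  expect_equal(wf$WF_B, c(0.5, 1, 1.5))
  field$D <- 5
  expect_equal(biomass_weighting_factors(field)$WF_B, rep(1, 3))
  set.seed(4)
  rnd <- data.frame(species = "A", year = 1990, cell = 1:50,
                    D = rlnorm(50))
  expect_equal(mean(biomass_weighting_factors(rnd)$WF_B), 1)
})

test_that("gravimetric proportions follow the weighted prey-mass ratio", {
  s <- data.frame(stomach_id = 1, species = "A", haul = 1, year = 1990,
                  area = "610", pred_length_cm = 42,
                  prey_taxon = c("pollock", "other"),
                  prey_mass_g = c(3, 1))
  out <- prey_proportions(s)
  expect_equal(out$target$p_target, 0.75)
  expect_equal(sum(out$proportions$p), 1)
})

test_that("weighted proportions equal a brute-force item-level oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n_stom <- sample(3:8, 1)
    items <- do.call(rbind, lapply(seq_len(n_stom), function(r) {
      q <- sample(1:3, 1)
      data.frame(stomach_id = r, species = "A",
                 haul = sample(1:2, 1), year = 1990, area = "610",
                 pred_length_cm = runif(1, 10, 60), cell = sample(1:2, 1),
                 prey_taxon = sample(c("pollock", "other", "shrimp"), q),
                 prey_mass_g = runif(q, 0.1, 9))
    }))
    wfl <- expand.grid(species = "A", haul = 1:2,
                       bin = seq(10, 50, 10), stringsAsFactors = FALSE)
    wfl$WF_L <- runif(nrow(wfl), 0.5, 2)
    wfb <- data.frame(species = "A", year = 1990, cell = 1:2,
                      WF_B = runif(2, 0.5, 2))
    out <- prey_proportions(items, wf_l = wfl, wf_b = wfb)
    # independent oracle: explicit loop over all prey items
    ww <- numeric(nrow(items))
    for (k in seq_len(nrow(items))) {
      b <- floor(items$pred_length_cm[k] / 10) * 10
      l <- wfl$WF_L[wfl$haul == items$haul[k] & wfl$bin == b]
      bw <- wfb$WF_B[wfb$cell == items$cell[k]]
      ww[k] <- items$prey_mass_g[k] * l * bw
    }
    p_oracle <- sum(ww[items$prey_taxon == "pollock"]) / sum(ww)
    expect_equal(out$target$p_target, p_oracle, tolerance = 1e-12)
  }
})

test_that("weighting is neutral when subsampling is representative and density uniform", {
  set.seed(8)
  catch <- data.frame(haul = 1, species = "A",
                      length_cm = rep(c(15, 25), c(3, 3)), count = 1)
  stom_pred <- data.frame(haul = 1, species = "A",
                          length_cm = c(15, 25))
  wfl <- length_weighting_factors(catch, stom_pred)
  wfb <- data.frame(species = "A", year = 1990, cell = 1, WF_B = 1)
  items <- data.frame(stomach_id = c(1, 1, 2), species = "A", haul = 1,
                      year = 1990, area = "610",
                      pred_length_cm = c(15, 15, 25), cell = 1,
                      prey_taxon = c("pollock", "other", "pollock"),
                      prey_mass_g = c(2, 1, 4))
  weighted <- prey_proportions(items, wf_l = wfl, wf_b = wfb)
  unweighted <- prey_proportions(items)
  expect_equal(weighted$target$p_target, unweighted$target$p_target)
  expect_equal(unweighted$target$p_target, 6 / 7)
})

test_that("empty stomachs add to counts but not to mass", {
  items <- data.frame(stomach_id = 1:3, species = "A", haul = 1,
                      year = 1990, area = "610", pred_length_cm = 30,
                      prey_taxon = c("pollock", "other", NA),
                      prey_mass_g = c(1, 1, 0))
  out <- prey_proportions(items)
  expect_equal(out$target$n_stomachs, 3L)
  expect_equal(out$target$p_target, 0.5)
})

test_that("species-years without stomachs take the area mean across years, flagged", {
  items <- rbind(
    data.frame(stomach_id = 1, species = "A", haul = 1, year = 1990,
               area = "610", pred_length_cm = 30,
               prey_taxon = c("pollock", "other"), prey_mass_g = c(1, 3)),
    data.frame(stomach_id = 2, species = "A", haul = 2, year = 1993,
               area = "610", pred_length_cm = 30,
               prey_taxon = c("pollock", "other"), prey_mass_g = c(3, 1)))
  out <- prey_proportions(items, years = c(1990, 1993, 1996))
  t96 <- out$target[out$target$year == 1996, ]
  expect_true(t96$imputed)
  expect_equal(t96$p_target, 0.5)  # mean of 0.25 and 0.75
  expect_false(any(out$target$imputed[out$target$year != 1996]))
})
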