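test_that("the spatial frame partitions the domain into consistent areas", {
  fr <- make_spatial_frame()
  expect_s3_class(fr, "spatial_frame")
  expect_false(anyNA(fr$cells$stat_area))
  expect_setequal(unique(fr$cells$stat_area),
                  c("610", "620", "630", "640", "650"))
  # subregion mapping and assessment flag follow the area boundaries
  expect_true(all(fr$cells$subregion[fr$cells$stat_area == "610"] == "W"))
  expect_true(all(fr$cells$subregion[fr$cells$stat_area %in%
                                       c("620", "630")] == "C"))
  expect_true(all(fr$cells$assessment == (fr$cells$lon < -140)))
  expect_identical(assign_stat_area(c(-165, -155, -150, -145, -135)),
                   c("610", "620", "630", "640", "650"))
})

test_that("assessed CPUE fraction matches a per-fish mass oracle", {
  # flat allometry turns masses into counts: 6 of 10 fish below threshold
  expect_equal(assessed_cpue_fraction(c(10, 30), counts = c(6, 4),
                                      lw_a = 1, lw_b = 0,
                                      threshold_cm = 20), 0.4)
  expect_equal(5 * 0.4, 2)  # kg/ha after adjustment
  expect_identical(assessed_cpue_fraction(c(10, 30), lw_a = 1, lw_b = 0,
                                          threshold_cm = 0), 1)
  set.seed(1)
  L <- runif(200, 5, 90)
  a <- 0.0049; b <- 3.1; thr <- 45
  oracle <- sum((a * L^b)[L >= thr]) / sum(a * L^b)
  expect_equal(assessed_cpue_fraction(L, lw_a = a, lw_b = b,
                                      threshold_cm = thr), oracle)
  expect_error(assessed_cpue_fraction(numeric(0), lw_a = a, lw_b = b,
                                      threshold_cm = 10), "zero")
})

test_that("delta model recovers occupancy and a homogeneous density surface", {
  cfg <- uniform_world(seed = 11, occupancy = 0.7)
  truth <- generate_truth(cfg)
  survey <- simulate_survey(truth, survey_design(truth, 80), seed = 5)
  fit <- fit_delta_model(survey$hauls, survey$catches, "SP1",
                         select = FALSE)
  n <- fit$n
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(fit$occupancy - 0.7), 3 * se)
  field <- predict_density_grid(fit, truth$frame,
                                temperature_fun = truth$temperature_fun)
  truth_d <- truth$density$D[1]
  # homogeneous world: cell predictions hover around the spatial constant
  expect_lt(abs(median(field$D) - truth_d) / truth_d, 0.25)
  expect_true(all(field$D >= 0))
  # constant cell count across years
  expect_equal(sum(field$year == 1990), sum(field$year == 1993))
})

test_that("a species present everywhere skips the occurrence component", {
  cfg <- uniform_world(seed = 3, occupancy = 1.0)
  truth <- generate_truth(cfg)
  survey <- simulate_survey(truth, survey_design(truth, 40), seed = 2)
  fit <- fit_delta_model(survey$hauls, survey$catches, "SP1",
                         select = FALSE)
  expect_null(fit$po_fit)
  field <- predict_density_grid(fit, truth$frame)
  mu <- predict(fit$pa_fit, newdata = transform(truth$frame$cells,
                                                year = 1990))
  # PO = 1 so density equals the back-transformed positive component
  expect_equal(field$D[field$year == 1990],
               as.numeric(exp(mu + fit$sigma^2 / 2))[
                 truth$frame$cells$cell %in% field$cell[field$year == 1990]],
               tolerance = 1e-10)
})

test_that("model selection never returns a worse-AIC candidate", {
  cfg <- uniform_world(seed = 9)
  truth <- generate_truth(cfg)
  survey <- simulate_survey(truth, survey_design(truth, 30), seed = 8)
  fit <- fit_delta_model(survey$hauls, survey$catches, "SP1",
                         select = TRUE, tie_delta = 2)
  for (trace in list(fit$po_trace, fit$pa_trace)) {
    sel_aic <- min(trace$aic)
    expect_true(all(trace$aic >= sel_aic - 1e-9))
    # tie rule: nothing simpler exists within the tie window
    near <- trace[trace$aic <= sel_aic + 2, ]
    chosen_terms <- if (identical(trace, fit$po_trace)) fit$po_terms
                    else fit$pa_terms
    expect_lte(min(near$n_terms), length(chosen_terms))
  }
  expect_error(fit_delta_model(survey$hauls[survey$hauls$year == 1990, ],
                               survey$catches, "SP1"), "two survey years")
})

test_that("relative densities form a simplex and fill missing years cellwise", {
  field <- data.frame(species = "X", year = 1990, cell = 1:2,
                      lon = 0, lat = 0, stat_area = c("A", "B"),
                      subregion = c("A", "B"),
                      assessment = TRUE, D = c(1, 3))
  rd <- relative_density(field)
  expect_equal(rd$rD, c(0.25, 0.75))
  field2 <- rbind(field, transform(field, year = 1993, D = c(3, 1)))
  rd2 <- relative_density(field2, years = c(1990, 1993, 1996))
  sums <- tapply(rd2$rD, rd2$year, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
  filled <- rd2[rd2$year == 1996, ]
  expect_true(all(filled$imputed))
  expect_equal(filled$rD, c(0.5, 0.5))  # mean of [0.25,0.75] and [0.75,0.25]
  field$D <- 0
  expect_error(relative_density(field), "all-zero")
})

test_that("aggregation is additive across nested scales", {
  areas4 <- list(breaks = c(-160, -150, -140),
                 labels = c("A", "B", "C", "D"))
  fr <- make_spatial_frame(lon_range = c(-170, -130),
                           areas = areas4,
                           subregion_map = c(A = "W", B = "C", C = "C",
                                             D = "E"),
                           assessment_lon_max = -140)
  cells <- fr$cells
  field <- data.frame(species = "X", year = 1990, cell = cells$cell,
                      lon = cells$lon, lat = cells$lat,
                      stat_area = cells$stat_area,
                      subregion = cells$subregion,
                      assessment = cells$assessment, D = 1)
  rd <- relative_density(field)
  by_area <- aggregate_density(rd, "stat_area")
  # equal-width bands over a uniform field -> equal shares
  expect_equal(by_area$rD, rep(0.25, 4), tolerance = 0.05)
  expect_equal(sum(by_area$rD), 1, tolerance = 1e-9)
  by_sub <- aggregate_density(rd, "subregion")
  expect_equal(by_sub$rD[by_sub$area == "C"],
               sum(by_area$rD[by_area$area %in% c("B", "C")]),
               tolerance = 1e-12)
  # assessment area equals basin minus cells east of the cutoff (oracle)
  by_assess <- aggregate_density(rd, "assessment")
  east <- sum(rd$rD[rd$lon >= -140])
  expect_equal(by_assess$rD, 1 - east, tolerance = 1e-12)
})
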