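make_factors <- function(species = "A", years = 1990, areas = "610",
                         B = 1e12, rD = 0.5, ration = 3, p = 0.4,
                         a = c(0, 0, 0, 1)) {
  grid_sy <- expand.grid(species = species, year = years,
                         stringsAsFactors = FALSE)
  biomass <- transform(grid_sy, biomass_g = B)
  attr(biomass, "units") <- "g"
  grid <- merge(grid_sy, data.frame(area = areas))
  rd <- transform(grid, rD = rD)
  rations <- transform(grid, ration = ration)
  diets <- transform(grid, p_target = p)
  ages <- do.call(rbind, lapply(seq_len(nrow(grid_sy)), function(k) {
    data.frame(species = grid_sy$species[k], year = grid_sy$year[k],
               age_class = c("0", "1", "2", "3+"), proportion = a)
  }))
  list(biomass = biomass, rd = rd, rations = rations, diets = diets,
       ages = ages)
}

test_that("the index tensor is the five-factor product", {
  f <- make_factors()
  tensor <- assemble_index(f$biomass, f$rd, f$rations, f$diets, f$ages)
  expect_equal(tensor$consumption_g[tensor$age_class == "3+"], 6e11)
  expect_equal(g_to_Tg(6e11), 0.6)
  expect_equal(sum(tensor$consumption_g), 1e12 * 0.5 * 3 * 0.4,
               tolerance = 1e-9)
  f0 <- make_factors(p = 0)
  t0 <- assemble_index(f0$biomass, f0$rd, f0$rations, f0$diets, f0$ages)
  expect_true(all(t0$consumption_g == 0))
  # biomass without gram units is rejected
  bad <- f$biomass; attr(bad, "units") <- NULL
  expect_error(assemble_index(bad, f$rd, f$rations, f$diets, f$ages),
               "grams")
})

test_that("a random fixture matches the brute-force product-sum oracle", {
  set.seed(13)
  species <- c("A", "B"); years <- c(1990, 1993); areas <- c("610", "620")
  f <- make_factors(species, years, areas)
  f$rd$rD <- runif(nrow(f$rd))
  f$rations$ration <- runif(nrow(f$rations), 1, 5)
  f$diets$p_target <- runif(nrow(f$diets))
  f$ages$proportion <- as.vector(apply(
    matrix(runif(16), 4), 2, function(x) x / sum(x)))
  f$biomass$biomass_g <- runif(4, 1e11, 1e12)
  tensor <- assemble_index(f$biomass, f$rd, f$rations, f$diets, f$ages)
  for (k in sample(nrow(tensor), 10)) {
    row <- tensor[k, ]
    B <- f$biomass$biomass_g[f$biomass$species == row$species &
                               f$biomass$year == row$year]
    rD <- f$rd$rD[f$rd$species == row$species & f$rd$year == row$year &
                    f$rd$area == row$area]
    cc <- f$rations$ration[f$rations$species == row$species &
                             f$rations$year == row$year &
                             f$rations$area == row$area]
    p <- f$diets$p_target[f$diets$species == row$species &
                            f$diets$year == row$year &
                            f$diets$area == row$area]
    a <- f$ages$proportion[f$ages$species == row$species &
                             f$ages$year == row$year &
                             f$ages$age_class == row$age_class]
    expect_equal(row$consumption_g, B * rD * cc * p * a,
                 tolerance = 1e-12)
  }
  # exact additivity: ages collapse back to the four-factor product
  by_pred <- aggregate_index(tensor, "predator_total")
  for (k in seq_len(nrow(by_pred))) {
    row <- by_pred[k, ]
    parts <- tensor$consumption_g[tensor$species == row$species &
                                    tensor$year == row$year &
                                    tensor$area == row$area]
    expect_identical(row$consumption_g, sum(parts))
  }
  # area rollup equals basin-level sums
  basin <- aggregate_index(tensor, "total",
                           area_map = c("610" = "basin", "620" = "basin"))
  expect_equal(sum(basin$consumption_g), sum(tensor$consumption_g))
})

test_that("contributions form a predator simplex", {
  f <- make_factors(species = c("A", "B"))
  f$diets$p_target <- c(0.4, 0.4)
  f$rations$ration <- c(3, 1)
  tensor <- assemble_index(f$biomass, f$rd, f$rations, f$diets, f$ages)
  co <- aggregate_index(tensor, "contributions")
  expect_equal(sort(co$contribution), c(0.25, 0.75))
  expect_equal(sum(co$contribution), 1)
})

test_that("missing factor cells become explicit gaps, not zeros", {
  f <- make_factors(species = "A", years = c(1990, 1993),
                    areas = c("610", "620"))
  f$diets <- f$diets[!(f$diets$year == 1993 & f$diets$area == "620"), ]
  tensor <- assemble_index(f$biomass, f$rd, f$rations, f$diets, f$ages)
  gaps <- attr(tensor, "gaps")
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$area, "620")
  expect_false(any(tensor$year == 1993 & tensor$area == "620"))
})

test_that("anomalies behave in ratio and difference modes", {
  cons <- data.frame(species = "A", year = c(1990, 1993, 1996),
                     area = "W", consumption_g = c(2, 2, 2))
  expect_equal(consumption_anomalies(cons)$anomaly, rep(1, 3))
  cons$consumption_g <- c(1, 1, 4)
  expect_equal(consumption_anomalies(cons)$anomaly[3], 2)
  d <- consumption_anomalies(cons, "difference")
  expect_equal(sum(d$anomaly), 0, tolerance = 1e-12)
})

test_that("consumption-to-biomass ratios divide like units", {
  f <- make_factors(B = 6.3e12, rD = 1, ration = 1, p = 1)
  tensor <- assemble_index(f$biomass, f$rd, f$rations, f$diets, f$ages)
  pb <- data.frame(year = 1990, biomass_g = 2e12)
  attr(pb, "units") <- "g"
  out <- consumption_to_biomass(tensor, pb, area = NULL)
  expect_equal(out$ratio, 3.15)
  pb2 <- transform(pb, biomass_g = 6.3e12)
  attr(pb2, "units") <- "g"
  expect_equal(consumption_to_biomass(tensor, pb2, area = NULL)$ratio, 1)
  attr(pb, "units") <- "Mg"
  expect_error(consumption_to_biomass(tensor, pb, area = NULL), "grams")
})
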