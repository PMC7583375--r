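#' Configure a synthetic predator-prey survey world
#'
#' Defines a seeded "world" with known ground truth: per-species spatial
#' density surfaces over a coastline-like domain split into statistical
#' areas, constant-per-species occupancy, biomass trajectories, diet
#' simplexes (share of the focal prey), prey age-class simplexes, prey
#' growth, and a smooth bottom-temperature field. Surveys and stomach
#' subsampling are then simulated from this truth so every pipeline stage
#' can be validated against known parameters.
#'
#' @param species data frame with one row per predator and columns:
#'   \code{species}, \code{biomass_mg}, \code{base_density},
#'   \code{center_lon}, \code{center_lat}, \code{field_sd_deg},
#'   \code{background} (relative density floor), \code{occupancy} (0-1),
#'   \code{length_mean_cm}, \code{length_sd_cm}, \code{lw_a}, \code{lw_b},
#'   \code{diet_pollock} (true gravimetric share of the focal prey).
#' @param survey_years strictly increasing survey years; default the 12
#'   biennial/triennial years 1990-2015.
#' @param age_simplex named numeric 4-simplex over classes 0/1/2/3+ for
#'   prey found in stomachs (common to all predators by default).
#' @param growth prey growth list: \code{Linf} (cm), \code{k} (1/yr),
#'   \code{t0} (yr), \code{length_sd_cm} (within-class SD).
#' @param temperature list: \code{base} (deg C at the western edge),
#'   \code{lon_gradient} (deg C across the domain), \code{anomaly_amp}
#'   (amplitude of a deterministic sinusoidal year anomaly).
#' @param cpue_cv lognormal CV of positive CPUE (default 0.5).
#' @param lon_range,lat_range,cell_km domain extents and grid cell size
#'   passed to [make_spatial_frame()].
#' @param registry bioenergetics parameter registry used when analyzing
#'   worlds built from this config (default the bundled one); scenario
#'   configs may supply a controlled registry.
#' @param seed integer root seed.
#' @return Object of class \code{world_config}.
#' @export
world_config <- function(species,
                         survey_years = c(1990, 1993, 1996, 1999, 2001,
                                          2003, 2005, 2007, 2009, 2011,
                                          2013, 2015),
                         age_simplex = c("0" = 0.14, "1" = 0.27,
                                         "2" = 0.20, "3+" = 0.39),
                         growth = list(Linf = 65, k = 0.25, t0 = -0.5,
                                       length_sd_cm = 1.5),
                         temperature = list(base = 5, lon_gradient = 2,
                                            anomaly_amp = 0.5),
                         cpue_cv = 0.5,
                         lon_range = c(-170, -132),
                         lat_range = c(52, 60),
                         cell_km = 50,
                         registry = bioenergetics_params(),
                         seed = 1L) {
  needed <- c("species", "biomass_mg", "base_density", "center_lon",
              "center_lat", "field_sd_deg", "background", "occupancy",
              "length_mean_cm", "length_sd_cm", "lw_a", "lw_b",
              "diet_pollock")
  if (!is.data.frame(species) || !nrow(species)) {
    stop("species must be a nonempty data frame", call. = FALSE)
  }
  miss <- setdiff(needed, names(species))
  if (length(miss)) stop("species table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(diff(survey_years) <= 0)) {
    stop("survey years must be strictly increasing", call. = FALSE)
  }
  assert_simplex(age_simplex, "age simplex")
  if (any(species$diet_pollock < 0 | species$diet_pollock > 1)) {
    stop("diet_pollock shares must lie in [0, 1]", call. = FALSE)
  }
  if (any(species$occupancy <= 0 | species$occupancy > 1)) {
    stop("occupancy must lie in (0, 1]", call. = FALSE)
  }
  unknown <- setdiff(species$species, registry$species)
  if (length(unknown)) {
    stop("species missing from bioenergetics registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(species = species, survey_years = survey_years,
                 age_simplex = age_simplex, growth = growth,
                 temperature = temperature, cpue_cv = cpue_cv,
                 lon_range = lon_range, lat_range = lat_range,
                 cell_km = cell_km, registry = registry,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Packaged dominant-predator scenario
#'
#' Five predators with identical biomass, physiology (one shared
#' bioenergetics parameter set), size structure and occupancy, but distinct
#' spatial density fields and focal-prey diet shares of 0.74, 0.16, 0.06,
#' 0.03 and 0.01. With every other factor equal, the true basin-scale
#' contribution of each predator to total consumption equals its diet
#' share, so the configured 0.74 dominant share is also the ground-truth
#' contribution the pipeline should recover.
#'
#' @param seed root seed.
#' @param survey_years survey years (default 1990 and 1993).
#' @return A \code{world_config}.
#' @export
world_config_dominant <- function(seed = 1L,
                                  survey_years = c(1990, 1993)) {
  shares <- c(ATF = 0.74, PH = 0.16, PC = 0.06, SBL = 0.03, WEP = 0.01)
  sp <- data.frame(
    species = names(shares),
    biomass_mg = 1e6,
    base_density = 20,
    center_lon = c(-165, -157, -150, -143, -136),
    center_lat = c(55, 57, 55, 57, 55),
    field_sd_deg = 6,
    background = 0.05,
    occupancy = 0.8,
    length_mean_cm = 45, length_sd_cm = 12,
    lw_a = 0.0055, lw_b = 3.05,
    diet_pollock = unname(shares))
  base <- bioenergetics_params("ATF")
  reg <- base[rep(1, length(shares)), ]
  reg$species <- names(shares)
  rownames(reg) <- NULL
  world_config(sp, survey_years = survey_years, registry = reg,
               seed = seed)
}

temperature_field_fun <- function(config) {
  tp <- config$temperature
  lon0 <- config$lon_range[1]
  lon_span <- diff(config$lon_range)
  yrs <- config$survey_years
  function(lon, lat, year) {
    phase <- 2 * pi * (match(year, yrs) %||% 1) / max(length(yrs), 2)
    tp$base + tp$lon_gradient * (lon - lon0) / lon_span +
      tp$anomaly_amp * sin(phase)
  }
}

#' Realize the deterministic ground truth of a world
#'
#' Computes per-cell predator densities (Gaussian-bump surface over a flat
#' background), the temperature field, true area-level relative densities,
#' diet and age simplexes, and the biomass table. No randomness is
#' involved; the truth is a deterministic function of the configuration.
#'
#' @param config a [world_config()].
#' @return Object of class \code{world_truth}: list with \code{frame},
#'   \code{density} (species, year, cell, D), \code{temperature_fun},
#'   \code{diet}, \code{ages}, \code{biomass}, \code{occupancy},
#'   \code{config}.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "world_config"))
  frame <- make_spatial_frame(config$lon_range, config$lat_range,
                              config$cell_km)
  cells <- frame$cells
  dens <- lapply(seq_len(nrow(config$species)), function(k) {
    sp <- config$species[k, ]
    bump <- exp(-((cells$lon - sp$center_lon)^2 +
                    (cells$lat - sp$center_lat)^2) /
                  (2 * sp$field_sd_deg^2))
    d <- sp$base_density * (sp$background + bump)
    do.call(rbind, lapply(config$survey_years, function(yr) {
      data.frame(species = sp$species, year = yr, cell = cells$cell,
                 lon = cells$lon, lat = cells$lat,
                 stat_area = cells$stat_area,
                 subregion = cells$subregion,
                 assessment = cells$assessment, D = d)
    }))
  })
  density <- do.call(rbind, dens)

  diet <- expand.grid(species = config$species$species,
                      year = config$survey_years,
                      area = unique(cells$stat_area),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  diet$p_pollock <- config$species$diet_pollock[
    match(diet$species, config$species$species)]

  ages <- expand.grid(species = config$species$species,
                      year = config$survey_years,
                      age_class = age_class_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ages$proportion <- config$age_simplex[ages$age_class]

  biomass <- expand.grid(species = config$species$species,
                         year = config$survey_years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  biomass$partition <- NA_character_
  biomass$biomass_mg <- config$species$biomass_mg[
    match(biomass$species, config$species$species)]

  structure(list(frame = frame, density = density,
                 temperature_fun = temperature_field_fun(config),
                 diet = diet, ages = ages, biomass = biomass,
                 occupancy = setNames(config$species$occupancy,
                                      config$species$species),
                 config = config),
            class = "world_truth")
}

#' Summarize recoverable truth parameters per species, year and area
#'
#' @param truth a [generate_truth()] result.
#' @return Data frame with one row per (species, year, area): true relative
#'   density \code{rD}, diet share \code{p_pollock}, biomass \code{B_mg},
#'   and the age-class proportions as columns \code{age_0} ... \code{age_3p}.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "world_truth"))
  rd <- truth$density %>%
    dplyr::group_by(.data$species, .data$year) %>%
    dplyr::mutate(rD_cell = .data$D / sum(.data$D)) %>%
    dplyr::group_by(.data$species, .data$year, .data$stat_area) %>%
    dplyr::summarise(rD = sum(.data$rD_cell), .groups = "drop") %>%
    dplyr::rename(area = "stat_area")
  out <- dplyr::left_join(rd, truth$diet,
                          by = c("species", "year", "area"))
  out <- dplyr::left_join(out, truth$biomass[, c("species", "year",
                                                 "biomass_mg")],
                          by = c("species", "year"))
  ages <- tidyr::pivot_wider(truth$ages, names_from = "age_class",
                             values_from = "proportion")
  names(ages)[match(age_class_levels(), names(ages))] <-
    c("age_0", "age_1", "age_2", "age_3p")
  out <- dplyr::left_join(out, ages, by = c("species", "year"))
  dplyr::rename(as.data.frame(out), B_mg = "biomass_mg")
}

#' Default survey design: equal haul allocation per area-year
#'
#' @param truth a world truth.
#' @param hauls_per_area hauls per statistical area and year.
#' @param years,areas optional subsets (omit an area-year to emulate
#'   missing survey coverage).
#' @return Data frame (year, stat_area, n_hauls).
#' @export
survey_design <- function(truth, hauls_per_area = 40, years = NULL,
                          areas = NULL) {
  years <- years %||% truth$config$survey_years
  areas <- areas %||% unique(truth$frame$cells$stat_area)
  expand.grid(year = years, stat_area = areas, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(n_hauls = hauls_per_area)
}

#' Simulate a bottom-trawl-style survey from a world truth
#'
#' Hauls are placed uniformly within each designed statistical area and
#' year. Per haul and species, catch is zero-inflated: a Bernoulli
#' occupancy draw times a lognormal positive CPUE whose mean is
#' proportional to the local truth density (mean of the zero-inflated
#' catch equals the truth density). Fish lengths are drawn from the
#' species' length distribution and haul temperature from the temperature
#' field.
#'
#' @param truth a [generate_truth()] result.
#' @param design a [survey_design()] data frame; areas must exist in the
#'   frame.
#' @param seed integer seed (default derived from the config seed).
#' @param mean_fish_measured mean number of fish measured per positive
#'   haul-species (Poisson, min 2).
#' @return List of data frames: \code{hauls} (haul, year, lon, lat, depth,
#'   temperature, stat_area, cell), \code{catches} (haul, species, cpue),
#'   \code{lengths} (haul, species, length_cm, count).
#' @export
simulate_survey <- function(truth, design = survey_design(truth),
                            seed = NULL, mean_fish_measured = 15) {
  stopifnot(inherits(truth, "world_truth"))
  known <- unique(truth$frame$cells$stat_area)
  bad <- setdiff(design$stat_area, known)
  if (length(bad)) stop("design places hauls in undefined areas: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(design$n_hauls < 1)) {
    stop("each designed area-year needs at least one haul", call. = FALSE)
  }
  seed <- seed %||% substream_seed(truth$config$seed, "survey")
  set.seed(seed)
  cfg <- truth$config
  cells <- truth$frame$cells
  brk <- truth$frame$areas
  lon_edges <- c(cfg$lon_range[1], brk$breaks, cfg$lon_range[2])

  hauls <- list(); catches <- list(); lengths <- list()
  hid <- 0L
  sdlog <- sqrt(log(1 + cfg$cpue_cv^2))
  for (k in seq_len(nrow(design))) {
    yr <- design$year[k]; area <- design$stat_area[k]
    ai <- match(area, brk$labels)
    n <- design$n_hauls[k]
    lon <- runif(n, lon_edges[ai], lon_edges[ai + 1])
    lat <- runif(n, cfg$lat_range[1], cfg$lat_range[2])
    cell <- frame_cell_at(truth$frame, lon, lat)
    depth <- cells$depth[match(cell, cells$cell)] * exp(rnorm(n, 0, 0.1))
    temp <- truth$temperature_fun(lon, lat, yr) + rnorm(n, 0, 0.1)
    ids <- hid + seq_len(n); hid <- hid + n
    hauls[[k]] <- data.frame(haul = ids, year = yr, lon = lon, lat = lat,
                             depth = depth, temperature = temp,
                             stat_area = area, cell = cell)
    for (sp_i in seq_len(nrow(cfg$species))) {
      sp <- cfg$species[sp_i, ]
      d_loc <- truth$density$D[truth$density$species == sp$species &
                                 truth$density$year == yr][
                                   match(cell, cells$cell)]
      occ <- rbinom(n, 1, sp$occupancy)
      pos_mean <- d_loc / sp$occupancy
      cpue <- ifelse(occ == 1 & pos_mean > 0,
                     rlnorm(n, log(pmax(pos_mean, 1e-12)) - sdlog^2 / 2,
                            sdlog),
                     0)
      cpue[d_loc == 0] <- 0
      catches[[length(catches) + 1L]] <-
        data.frame(haul = ids, species = sp$species, cpue = cpue)
      posi <- which(cpue > 0)
      if (length(posi)) {
        nf <- pmax(rpois(length(posi), mean_fish_measured), 2L)
        lengths[[length(lengths) + 1L]] <- data.frame(
          haul = rep(ids[posi], nf),
          species = sp$species,
          length_cm = pmax(rnorm(sum(nf), sp$length_mean_cm,
                                 sp$length_sd_cm), 5),
          count = 1)
      }
    }
  }
  list(hauls = dplyr::bind_rows(hauls),
       catches = dplyr::bind_rows(catches),
       lengths = dplyr::bind_rows(lengths))
}

#' Simulate size-structured stomach subsampling
#'
#' Selects fish for stomach analysis from the measured catch with a
#' per-haul, per-10-cm-bin cap, which intentionally biases the subsample's
#' length composition relative to the catch (so length weighting factors
#' differ from 1). Prey masses are drawn so that the expected gravimetric
#' share of the focal prey equals the truth diet simplex (gamma-split
#' stomach contents), and a subset of focal-prey items carries standard
#' lengths (mm) drawn from the age-class length distributions implied by
#' the truth growth curve and age simplex.
#'
#' @param truth a [generate_truth()] result.
#' @param survey a [simulate_survey()] result.
#' @param bin_cap maximum stomachs per haul, species and 10-cm length bin
#'   (default 2); \code{NULL} selects a simple random subsample of
#'   \code{srs_n} fish per haul-species instead (unbiased variant).
#' @param srs_n subsample size per haul-species for the unbiased variant.
#' @param measured_fraction probability a focal-prey item is measurable.
#' @param content_fraction mean stomach content mass as a fraction of
#'   predator mass.
#' @param seed integer seed (default derived from the config seed).
#' @return Data frame with one row per prey item (empty stomachs carry one
#'   row with \code{prey_taxon} NA and mass 0): stomach_id, species, haul,
#'   year, area, cell, pred_length_cm, pred_mass_g, temperature_c,
#'   prey_taxon, prey_mass_g, prey_sl_mm.
#' @export
simulate_stomachs <- function(truth, survey, bin_cap = 2, srs_n = 5,
                              measured_fraction = 0.7,
                              content_fraction = 0.02, seed = NULL) {
  stopifnot(inherits(truth, "world_truth"))
  if (!is.null(bin_cap) && bin_cap < 1) stop("bin_cap must be >= 1",
                                             call. = FALSE)
  empty <- data.frame(stomach_id = integer(0), species = character(0),
                      haul = integer(0), year = numeric(0),
                      area = character(0), cell = integer(0),
                      pred_length_cm = numeric(0),
                      pred_mass_g = numeric(0),
                      temperature_c = numeric(0),
                      prey_taxon = character(0), prey_mass_g = numeric(0),
                      prey_sl_mm = numeric(0))
  if (!nrow(survey$lengths)) return(empty)
  seed <- seed %||% substream_seed(truth$config$seed, "stomachs")
  set.seed(seed)
  cfg <- truth$config
  g <- cfg$growth
  ref <- age_class_ref_ages()
  class_means <- g$Linf * (1 - exp(-g$k * (ref - g$t0)))

  fish <- dplyr::left_join(
    survey$lengths,
    survey$hauls[, c("haul", "year", "stat_area", "cell", "temperature")],
    by = "haul")
  fish$bin <- length_bin(fish$length_cm)

  picked <- fish %>%
    dplyr::group_by(.data$haul, .data$species,
                    dplyr::across(dplyr::all_of(
                      if (is.null(bin_cap)) character(0) else "bin"))) %>%
    dplyr::slice_sample(n = if (is.null(bin_cap)) srs_n else bin_cap) %>%
    dplyr::ungroup()

  n <- nrow(picked)
  sp_row <- match(picked$species, cfg$species$species)
  picked$pred_mass_g <- cfg$species$lw_a[sp_row] *
    picked$length_cm^cfg$species$lw_b[sp_row]
  p_true <- cfg$species$diet_pollock[sp_row]
  total_mean <- content_fraction * picked$pred_mass_g
  theta <- total_mean / 4
  w_pol <- ifelse(p_true > 0, rgamma(n, shape = 4 * p_true) * theta, 0)
  w_oth <- ifelse(p_true < 1, rgamma(n, shape = 4 * (1 - p_true)) * theta,
                  0)

  sid <- seq_len(n)
  base <- data.frame(stomach_id = sid, species = picked$species,
                     haul = picked$haul, year = picked$year,
                     area = picked$stat_area, cell = picked$cell,
                     pred_length_cm = picked$length_cm,
                     pred_mass_g = picked$pred_mass_g,
                     temperature_c = picked$temperature)
  rows <- list()
  has_pol <- w_pol > 0
  if (any(has_pol)) {
    pol <- base[has_pol, ]
    pol$prey_taxon <- "pollock"
    pol$prey_mass_g <- w_pol[has_pol]
    cls <- sample(age_class_levels(), sum(has_pol), replace = TRUE,
                  prob = cfg$age_simplex)
    len <- rnorm(sum(has_pol), class_means[cls], g$length_sd_cm)
    measured <- runif(sum(has_pol)) < measured_fraction
    pol$prey_sl_mm <- ifelse(measured, pmax(len, 1) * 10, NA_real_)
    rows$pol <- pol
  }
  has_oth <- w_oth > 0
  if (any(has_oth)) {
    oth <- base[has_oth, ]
    oth$prey_taxon <- "other"
    oth$prey_mass_g <- w_oth[has_oth]
    oth$prey_sl_mm <- NA_real_
    rows$oth <- oth
  }
  none <- !(has_pol | has_oth)
  if (any(none)) {
    emp <- base[none, ]
    emp$prey_taxon <- NA_character_
    emp$prey_mass_g <- 0
    emp$prey_sl_mm <- NA_real_
    rows$emp <- emp
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$stomach_id), ]
}

#' Simulate prey growth and length-mass calibration samples
#'
#' Draws age-length pairs from the truth von Bertalanffy curve and
#' length-mass pairs from a cubic allometry with lognormal error, for
#' fitting the relationships the age-composition stage needs.
#'
#' @param truth a world truth.
#' @param n pairs per sample.
#' @param length_noise_sd additive length noise (cm).
#' @param lw_sigma lognormal SD of the mass residuals.
#' @param seed integer seed.
#' @return List with \code{age_length} (age, length_cm) and
#'   \code{length_mass} (length_cm, mass_g).
#' @export
simulate_prey_biology <- function(truth, n = 400, length_noise_sd = 1,
                                  lw_sigma = 0.15, seed = NULL) {
  stopifnot(inherits(truth, "world_truth"))
  seed <- seed %||% substream_seed(truth$config$seed, "prey_biology")
  set.seed(seed)
  g <- truth$config$growth
  age <- runif(n, 0.3, 10)
  len <- pmax(g$Linf * (1 - exp(-g$k * (age - g$t0))) +
                rnorm(n, 0, length_noise_sd), 1)
  l2 <- runif(n, 5, g$Linf)
  mass <- 0.006 * l2^3.05 * rlnorm(n, 0, lw_sigma)
  list(age_length = data.frame(age = age, length_cm = len),
       length_mass = data.frame(length_cm = l2, mass_g = mass))
}

#' Simulate predator consumption series under a synchrony regime
#'
#' Generates multi-predator consumption time series with a known synchrony
#' regime, for validating variance-ratio classification:
#' \describe{
#'  \item{synchronous}{a shared multiplicative year signal drives all
#'    predators, plus small independent noise (VR well above 1);}
#'  \item{asynchronous}{a near-constant total is reallocated among
#'    predators year to year (compensatory dynamics, VR well below 1);}
#'  \item{independent}{each predator fluctuates on its own (VR near 1 on
#'    average).}
#' }
#'
#' @param regime one of \code{"synchronous"}, \code{"asynchronous"},
#'   \code{"independent"}.
#' @param n_predators,n_years dimensions (defaults 5 predators, 5 years).
#' @param common_cv coefficient of variation of the shared signal
#'   (synchronous regime).
#' @param noise_cv coefficient of variation of independent fluctuations.
#' @param seed integer seed.
#' @return Numeric matrix, predators x years.
#' @export
simulate_consumption_regime <- function(regime = c("synchronous",
                                                   "asynchronous",
                                                   "independent"),
                                        n_predators = 5, n_years = 5,
                                        common_cv = 0.4, noise_cv = 0.05,
                                        seed = 1L) {
  regime <- match.arg(regime)
  set.seed(seed)
  mu <- runif(n_predators, 0.5, 2)
  out <- switch(regime,
    synchronous = {
      z <- rnorm(n_years, 0, common_cv)
      sweep(matrix(rnorm(n_predators * n_years, 0, noise_cv),
                   n_predators), 2, 1 + z, "*") * mu + outer(mu, 1 + z)
    },
    asynchronous = {
      shares <- matrix(rgamma(n_predators * n_years, shape = 20 * mu /
                                mean(mu)), n_predators)
      shares <- sweep(shares, 2, colSums(shares), "/")
      total <- sum(mu) * (1 + rnorm(n_years, 0, noise_cv / 2))
      sweep(shares, 2, total, "*")
    },
    independent = {
      mu * matrix(1 + rnorm(n_predators * n_years, 0, common_cv),
                  n_predators)
    })
  out <- pmax(out, 0)
  dimnames(out) <- list(paste0("pred", seq_len(n_predators)),
                        seq(1990, by = 2, length.out = n_years))
  out
}
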