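#' Bundle pipeline settings
#'
#' @param world a [world_config()] describing the synthetic world (or the
#'   world emulating the structure of real survey inputs).
#' @param hauls_per_area hauls per statistical area and survey year.
#' @param design optional explicit [survey_design()] table (overrides
#'   \code{hauls_per_area}; omit area-years to emulate survey gaps).
#' @param select enumerate delta-model covariate subsets (slower) or fit
#'   the full model per component.
#' @param use_temperature include temperature in delta-model candidates.
#' @param spatial try the spatial-autocorrelation mixed variant.
#' @param window variance-ratio window length in survey years (>= 2).
#' @param prey_species species code whose biomass the consumption-to-
#'   biomass ratio uses (NULL to skip).
#' @param age_method age-composition method, see
#'   [estimate_age_composition()].
#' @param seed root seed (defaults to the world's seed).
#' @param out_dir optional directory to write CSV outputs and manifest.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(world, hauls_per_area = 40, design = NULL,
                            select = FALSE, use_temperature = FALSE,
                            spatial = FALSE, window = 5,
                            prey_species = "WEP",
                            age_method = "multinomial",
                            seed = NULL, out_dir = NULL) {
  structure(list(world = world, hauls_per_area = hauls_per_area,
                 design = design, select = select,
                 use_temperature = use_temperature, spatial = spatial,
                 window = window, prey_species = prey_species,
                 age_method = age_method,
                 seed = seed %||% world$seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks cross-references without side effects: every species has
#' bioenergetics parameters, simplexes are valid, the window length is at
#' least 2, and any explicit design only references defined areas.
#'
#' @param config a [pipeline_config()].
#' @return List with \code{valid} (logical) and \code{errors} (character).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  w <- config$world
  if (!inherits(w, "world_config")) {
    errors <- c(errors, "world is not a world_config")
  } else {
    missing_par <- setdiff(w$species$species, w$registry$species)
    if (length(missing_par)) {
      errors <- c(errors, paste0("species without bioenergetics parameters: ",
                                 paste(missing_par, collapse = ", ")))
    }
    if (!is_simplex(w$age_simplex)) {
      errors <- c(errors, "age simplex does not sum to 1")
    }
    if (any(w$species$diet_pollock < 0 | w$species$diet_pollock > 1)) {
      errors <- c(errors, "diet shares outside [0, 1]")
    }
    if (length(w$survey_years) < 2) {
      errors <- c(errors, "need at least two survey years")
    }
  }
  if (is.null(config$window) || config$window < 2) {
    errors <- c(errors, "window length must be >= 2")
  }
  if (!is.null(config$design)) {
    known <- default_area_breaks()$labels
    bad <- setdiff(config$design$stat_area, known)
    if (length(bad)) {
      errors <- c(errors, paste0("design references undefined areas: ",
                                 paste(bad, collapse = ", ")))
    }
  }
  list(valid = length(errors) == 0L, errors = errors)
}

#' Run the full predation-index pipeline on a synthetic world
#'
#' Executes the stages in dependency order: world truth, survey and stomach
#' simulation, biomass assembly, delta-model densities, rations, weighted
#' diet proportions, prey age compositions, index assembly at statistical-
#' area scale, rollups (contributions, anomalies, consumption-to-biomass),
#' and moving-window variance ratios where enough survey years exist. All
#' randomness derives from the root seed via named substreams, so reruns
#' with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @return List of class \code{predation_run} with the truth, intermediate
#'   tables, the predation tensor, diagnostics, and a run \code{manifest}
#'   (seed, per-stage row counts, imputation counts, output hash).
#' @export
run_pipeline <- function(config) {
  chk <- validate_config(config)
  if (!chk$valid) {
    stop("invalid configuration:\n  - ",
         paste(chk$errors, collapse = "\n  - "), call. = FALSE)
  }
  w <- config$world
  seed <- config$seed
  years <- w$survey_years

  truth <- generate_truth(w)
  areas <- sort(unique(truth$frame$cells$stat_area))
  design <- config$design %||%
    survey_design(truth, hauls_per_area = config$hauls_per_area)
  survey <- simulate_survey(truth, design,
                            seed = substream_seed(seed, "survey"))
  stomachs <- simulate_stomachs(truth, survey,
                                seed = substream_seed(seed, "stomachs"))

  # --- biomass (Mg -> g) -------------------------------------------------
  biomass <- assemble_biomass_table(truth$biomass, years = years)

  # --- densities: assessed CPUE, delta models, grid, rD ------------------
  reg <- data.frame(
    species = w$species$species,
    assessed_min_length_cm = w$species$assessed_min_length_cm %||% 0,
    cpue_prefiltered = FALSE,
    lw_a = w$species$lw_a, lw_b = w$species$lw_b)
  catches <- adjust_catch_cpue(survey$catches, survey$lengths, reg)
  fits <- lapply(w$species$species, function(sp) {
    fit_delta_model(survey$hauls, catches, sp,
                    use_temperature = config$use_temperature,
                    select = config$select, spatial = config$spatial)
  })
  names(fits) <- w$species$species
  field <- dplyr::bind_rows(lapply(fits, function(f) {
    predict_density_grid(f, truth$frame,
                         years = intersect(years, f$years),
                         temperature_fun = truth$temperature_fun)
  }))
  field <- relative_density(field, years = years)
  rd_area <- aggregate_density(field, "stat_area")

  # --- rations -----------------------------------------------------------
  surveyed <- unique(data.frame(year = design$year,
                                area = design$stat_area))
  fish <- unique(stomachs[, c("stomach_id", "species", "year", "area",
                              "pred_length_cm", "pred_mass_g",
                              "temperature_c")])
  names(fish)[names(fish) == "pred_length_cm"] <- "length_cm"
  names(fish)[names(fish) == "pred_mass_g"] <- "mass_g"
  rations <- mean_annual_ration(fish, registry = w$registry,
                                years = years, areas = areas,
                                surveyed = surveyed)

  # --- weighted diet proportions -----------------------------------------
  stomach_preds <- unique(stomachs[, c("stomach_id", "species", "haul",
                                       "pred_length_cm")])
  names(stomach_preds)[4] <- "length_cm"
  wf_l <- length_weighting_factors(survey$lengths, stomach_preds)
  wf_b <- biomass_weighting_factors(field)
  # hauls near the domain edge can sit just outside the masked prediction
  # grid; snap their stomachs to the nearest predicted cell
  cells <- truth$frame$cells
  for (sp in unique(stomachs$species)) {
    ok_cells <- unique(field$cell[field$species == sp])
    idx <- stomachs$species == sp & !(stomachs$cell %in% ok_cells)
    if (any(idx)) {
      cand <- cells[cells$cell %in% ok_cells, ]
      from <- cells[match(stomachs$cell[idx], cells$cell), ]
      near <- vapply(seq_len(nrow(from)), function(i) {
        cand$cell[which.min((cand$lon - from$lon[i])^2 +
                              (cand$lat - from$lat[i])^2)]
      }, integer(1))
      stomachs$cell[idx] <- near
    }
  }
  diets <- prey_proportions(stomachs, wf_l = wf_l, wf_b = wf_b,
                            target_taxon = "pollock", years = years,
                            surveyed = surveyed)

  # --- prey age compositions ---------------------------------------------
  bio <- simulate_prey_biology(truth,
                               seed = substream_seed(seed, "prey_biology"))
  growth <- fit_von_bertalanffy(bio$age_length$age,
                                bio$age_length$length_cm)
  lw <- fit_length_mass(bio$length_mass$length_cm,
                        bio$length_mass$mass_g)
  prey <- stomachs[stomachs$prey_taxon %in% "pollock" &
                     !is.na(stomachs$prey_sl_mm), ]
  prey <- data.frame(species = prey$species, year = prey$year,
                     length_cm = standard_length_to_fork_cm(prey$prey_sl_mm))
  ages <- estimate_age_composition(prey, growth, lw,
                                   method = config$age_method,
                                   years = years)

  # --- assemble and aggregate --------------------------------------------
  tensor <- assemble_index(biomass, rd_area, rations, diets$target, ages,
                           scale = "stat_area")
  sub_map <- truth$frame$subregion_map
  basin_map <- setNames(rep("basin", length(sub_map)), names(sub_map))
  contributions <- aggregate_index(tensor, "contributions",
                                   area_map = basin_map)
  by_subregion <- aggregate_index(tensor, "predator_total",
                                  area_map = sub_map)
  anomalies <- consumption_anomalies(by_subregion, "ratio")

  ctb <- NULL
  if (!is.null(config$prey_species) &&
      config$prey_species %in% biomass$species) {
    assess_areas <- unique(
      truth$frame$cells$stat_area[truth$frame$cells$assessment])
    tb <- tensor[tensor$area %in% assess_areas, ]
    pb <- biomass[biomass$species == config$prey_species, ]
    attr(pb, "units") <- "g"
    ctb <- consumption_to_biomass(tb, pb, area = NULL)
  }

  synchrony <- NULL
  if (length(years) >= config$window) {
    series <- aggregate_index(tensor, "predator_total",
                              area_map = basin_map)
    long <- data.frame(year = series$year, predator = series$species,
                       value = g_to_Tg(series$consumption_g))
    synchrony <- moving_window_variance_ratios(long,
                                               window = config$window)
  }

  n_imputed <- sum(rations$imputed) + sum(diets$target$imputed) +
    sum(ages$imputed[!duplicated(ages[, c("species", "year")])]) +
    sum(rd_area$imputed[!duplicated(rd_area[, c("species", "year")])])
  tables <- list(biomass = biomass, rd = rd_area, rations = rations,
                 diet = diets$target, ages = ages,
                 tensor = as.data.frame(tensor),
                 contributions = contributions,
                 anomalies = anomalies,
                 consumption_to_biomass = ctb,
                 synchrony = synchrony)
  manifest <- list(
    seed = seed,
    survey_years = years,
    rows = lapply(Filter(Negate(is.null), tables), nrow),
    n_hauls = nrow(survey$hauls),
    n_stomachs = length(unique(stomachs$stomach_id)),
    n_imputed = n_imputed,
    hash = rlang::hash(tables))

  run <- structure(c(list(truth = truth, survey = survey,
                          stomachs = stomachs, fits = fits,
                          field = field, manifest = manifest),
                     tables),
                   class = "predation_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.predation_run <- function(x, ...) {
  m <- x$manifest
  cat("<predation_run>\n")
  cat("  seed:", m$seed, " hash:", m$hash, "\n")
  cat("  survey years:", paste(m$survey_years, collapse = ", "), "\n")
  cat(sprintf("  %d hauls, %d stomachs, %d imputed cells\n",
              m$n_hauls, m$n_stomachs, m$n_imputed))
  tot <- x$tensor %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(Tg = g_to_Tg(sum(.data$consumption_g)))
  cat("  total consumption (Tg):",
      paste(sprintf("%s=%.3g", tot$year, tot$Tg), collapse = ", "), "\n")
  invisible(x)
}

#' Write run outputs as CSV plus a JSON manifest
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("biomass", "rd", "rations", "diet", "ages", "tensor",
            "contributions", "anomalies", "consumption_to_biomass",
            "synchrony")
  paths <- character(0)
  for (tb in tabs) {
    if (is.null(run[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    write.csv(run[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
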