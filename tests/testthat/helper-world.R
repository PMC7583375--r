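# Small synthetic worlds shared across tests. A controlled registry reuses
# one parameter column for every species so ration differences never
# confound spatial or dietary checks.

shared_registry <- function(species) {
  base <- bioenergetics_params("ATF")
  reg <- base[rep(1, length(species)), ]
  reg$species <- species
  rownames(reg) <- NULL
  reg
}

tiny_species <- function(n = 2,
                         diet = seq(0.6, 0.2, length.out = n),
                         occupancy = 0.8,
                         base_density = 20,
                         field_sd_deg = 6,
                         background = 0.05) {
  data.frame(
    species = paste0("SP", seq_len(n)),
    biomass_mg = 1e6,
    base_density = base_density,
    center_lon = seq(-165, -137, length.out = n),
    center_lat = rep(c(55, 57), length.out = n),
    field_sd_deg = field_sd_deg,
    background = background,
    occupancy = occupancy,
    length_mean_cm = 45, length_sd_cm = 12,
    lw_a = 0.0055, lw_b = 3.05,
    diet_pollock = diet)
}

tiny_world <- function(seed = 1, n = 2, years = c(1990, 1993), ...) {
  sp <- tiny_species(n, ...)
  world_config(sp, survey_years = years,
               registry = shared_registry(sp$species), seed = seed)
}

# a single uniform-density species (exact spatial symmetry)
uniform_world <- function(seed = 1, occupancy = 0.7, years = c(1990, 1993)) {
  sp <- tiny_species(1, diet = 0.5, occupancy = occupancy)
  sp$field_sd_deg <- Inf  # bump identically 1 everywhere
  world_config(sp, survey_years = years,
               registry = shared_registry(sp$species), seed = seed)
}
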