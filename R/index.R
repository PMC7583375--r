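#' Assemble the predation index tensor
#'
#' Joins the five factors of the index and forms, for every predator
#' species s, prey age class a, survey year i and area j:
#' \deqn{P_{s,a,i,j} = B_{s,i} \times rD_{s,i,j} \times \bar{C}_{s,i,j}
#'   \times p_{s,i,j} \times a_{s,i}}
#' in grams. The canonical scale of assembly is the statistical area; sum
#' the result for coarser scales (see [aggregate_index()]), since
#' proportions and rations are estimated at that scale and coarser values
#' are sums of consumption, not products of averaged factors.
#'
#' Species-year-area combinations missing any factor are returned as
#' explicit gaps (attribute \code{"gaps"}), never as zeros; assembly fails
#' only when a factor table lacks a species or year entirely.
#'
#' @param biomass (species, year, biomass_g), attr units "g"
#'   ([assemble_biomass_table()]).
#' @param rd (species, year, area, rD) ([aggregate_density()]).
#' @param rations (species, year, area, ration) ([mean_annual_ration()]).
#' @param diets (species, year, area, p_target)
#'   (\code{prey_proportions()$target}).
#' @param ages (species, year, age_class, proportion)
#'   ([estimate_age_composition()]).
#' @param scale label recorded on the tensor (default "stat_area").
#' @return Data frame of class \code{predation_tensor} (species, age_class,
#'   year, area, consumption_g) with attributes \code{scale}, \code{units}
#'   and \code{gaps}.
#' @export
assemble_index <- function(biomass, rd, rations, diets, ages,
                           scale = "stat_area") {
  if (!identical(attr(biomass, "units"), "g")) {
    stop("biomass table must be in grams (attr units == 'g'); got '",
         attr(biomass, "units") %||% "unset", "'", call. = FALSE)
  }
  base <- rd[, c("species", "year", "area", "rD")]
  base <- dplyr::inner_join(base, biomass[, c("species", "year",
                                              "biomass_g")],
                            by = c("species", "year"))
  base <- dplyr::left_join(base,
                           rations[, c("species", "year", "area", "ration")],
                           by = c("species", "year", "area"))
  base <- dplyr::left_join(base,
                           diets[, c("species", "year", "area", "p_target")],
                           by = c("species", "year", "area"))
  gaps <- base[!complete.cases(base), c("species", "year", "area")]
  base <- base[complete.cases(base), ]
  if (!nrow(base)) {
    stop("no species-year-area cell has all five factors", call. = FALSE)
  }
  tensor <- dplyr::inner_join(
    base, ages[, c("species", "year", "age_class", "proportion")],
    by = c("species", "year"), relationship = "many-to-many")
  tensor$consumption_g <- tensor$biomass_g * tensor$rD * tensor$ration *
    tensor$p_target * tensor$proportion
  out <- tensor[, c("species", "age_class", "year", "area",
                    "consumption_g")]
  out <- out[order(out$species, out$year, out$area,
                   match(out$age_class, age_class_levels())), ]
  rownames(out) <- NULL
  structure(out, scale = scale, units = "g", gaps = gaps,
            class = c("predation_tensor", "data.frame"))
}

#' Aggregate the predation tensor and compute predator contributions
#'
#' @param tensor a [assemble_index()] result.
#' @param grouping one of \code{"predator_total"} (sum over ages:
#'   P_{s,i,j}), \code{"age_total"} (sum over predators: P_{a,i,j}),
#'   \code{"total"} (sum over both), \code{"area_rollup"} (sum areas into a
#'   single total per species-age-year) or \code{"contributions"}
#'   (predator shares of total consumption per area-year, a simplex;
#'   undefined where the total is zero, emitted as NA).
#' @param area_map optional named vector mapping area labels to coarser
#'   labels before aggregating (e.g. statistical areas to subregions).
#' @return Data frame; consumption in grams (shares for contributions).
#' @export
aggregate_index <- function(tensor,
                            grouping = c("predator_total", "age_total",
                                         "total", "area_rollup",
                                         "contributions"),
                            area_map = NULL) {
  grouping <- match.arg(grouping)
  d <- as.data.frame(tensor)
  if (!is.null(area_map)) {
    d$area <- unname(area_map[d$area])
    if (anyNA(d$area)) stop("area_map does not cover all areas",
                            call. = FALSE)
  }
  tot <- function(d, by) {
    d %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
      dplyr::summarise(consumption_g = sum(.data$consumption_g),
                       .groups = "drop") %>%
      as.data.frame()
  }
  switch(grouping,
    predator_total = tot(d, c("species", "year", "area")),
    age_total = tot(d, c("age_class", "year", "area")),
    total = tot(d, c("year", "area")),
    area_rollup = tot(d, c("species", "age_class", "year")),
    contributions = {
      ps <- tot(d, c("species", "year", "area"))
      ps %>%
        dplyr::group_by(.data$year, .data$area) %>%
        dplyr::mutate(contribution = {
          t <- sum(.data$consumption_g)
          if (t > 0) .data$consumption_g / t else NA_real_
        }) %>%
        dplyr::ungroup() %>%
        as.data.frame()
    })
}

#' Spatiotemporal consumption anomalies
#'
#' Compares species-, area- and year-specific consumption to the
#' species-specific mean over the whole domain and time series. Ratio mode
#' (default) divides by the mean; difference mode subtracts it (differences
#' sum to zero over complete coverage).
#'
#' @param consumption data frame (species, year, area, consumption_g), e.g.
#'   \code{aggregate_index(tensor, "predator_total")} with a subregion map.
#' @param mode \code{"ratio"} or \code{"difference"}.
#' @return Data frame (species, area, year, anomaly, mode).
#' @export
consumption_anomalies <- function(consumption,
                                  mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(all(c("species", "year", "area", "consumption_g") %in%
                  names(consumption)))
  out <- consumption %>%
    dplyr::group_by(.data$species) %>%
    dplyr::mutate(anomaly = {
      m <- mean(.data$consumption_g)
      if (mode == "ratio") {
        if (m <= 0) stop("species mean consumption is zero", call. = FALSE)
        .data$consumption_g / m
      } else {
        .data$consumption_g - m
      }
    }) %>%
    dplyr::ungroup()
  out <- as.data.frame(out[, c("species", "area", "year", "anomaly")])
  out$mode <- mode
  out
}

#' Ratio of age-3+ consumption to prey biomass
#'
#' Year-specific ratio of consumption of age-3+ prey (within the
#' assessment area) to assessed total prey biomass. Both sides must be in
#' grams; a biomass table without the grams unit attribute is rejected.
#'
#' @param tensor predation tensor restricted to (or containing) the
#'   assessment-area scale; rows with \code{age_class == "3+"} are used.
#' @param prey_biomass data frame (year, biomass_g) with attr units "g".
#' @param area area label to restrict to (default \code{"assessment"});
#'   NULL to use all rows.
#' @return Data frame (year, consumption_g, biomass_g, ratio).
#' @export
consumption_to_biomass <- function(tensor, prey_biomass,
                                   area = "assessment") {
  if (!identical(attr(prey_biomass, "units"), "g")) {
    stop("prey biomass must be in grams (attr units == 'g')",
         call. = FALSE)
  }
  d <- as.data.frame(tensor)
  d <- d[d$age_class == "3+", ]
  if (!is.null(area)) d <- d[d$area == area, ]
  cons <- d %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(consumption_g = sum(.data$consumption_g),
                     .groups = "drop")
  out <- dplyr::inner_join(cons,
                           prey_biomass[, c("year", "biomass_g")],
                           by = "year")
  if (any(out$biomass_g <= 0)) stop("zero prey biomass", call. = FALSE)
  out$ratio <- out$consumption_g / out$biomass_g
  as.data.frame(out)
}

#' Convert grams to teragrams for reporting
#'
#' @param x grams.
#' @return Teragrams (10^12 g).
#' @export
g_to_Tg <- function(x) x / 1e12
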