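#' Scale a coast-wide biomass estimate by a partition proportion
#'
#' Some assessments are conducted at a wider spatial scale than the study
#' region (the Pacific Halibut assessment is coast-wide). Multiplying the
#' coast-wide estimate by the proportion of assessed-size fish caught inside
#' the study region restricts it to the region of interest.
#'
#' @param biomass_mg coast-wide total biomass (Mg).
#' @param scalar proportion in [0, 1] of assessed fish inside the region.
#' @return Adjusted biomass (Mg) with a \code{"provenance"} attribute.
#' @export
#' @examples
#' adjust_partition_scalar(407620.3, 0.740)  # ~301639 Mg
adjust_partition_scalar <- function(biomass_mg, scalar) {
  if (any(scalar < 0 | scalar > 1)) {
    stop("partition scalar must lie in [0, 1]", call. = FALSE)
  }
  out <- biomass_mg * scalar
  attr(out, "provenance") <- sprintf("coastwide %.6g Mg x scalar %.4g",
                                     biomass_mg, scalar)
  out
}

#' Back-calculate biomass from a trend multiplier
#'
#' When an assessment does not cover early years, biomass is back-calculated
#' from a reference year using the ratio of predicted biomass between the
#' two years in an independent survey-based trend. Calls are chainable (e.g.
#' 1990 from 1993, itself derived from 1996).
#'
#' @param reference_mg biomass at the reference year (Mg).
#' @param multiplier positive trend ratio (target year / reference year).
#' @return Biomass at the target year (Mg).
#' @export
#' @examples
#' backcast_from_trend(799683, 1.045)  # halibut 1993
backcast_from_trend <- function(reference_mg, multiplier) {
  if (any(multiplier <= 0)) stop("trend multiplier must be > 0",
                                 call. = FALSE)
  reference_mg * multiplier
}

#' Trend multiplier from a predicted-biomass series
#'
#' Helper for users who hold a survey-model biomass series rather than a
#' ready-made multiplier: returns predicted(target) / predicted(reference).
#'
#' @param series data frame with columns \code{year} and \code{biomass}.
#' @param target_year,reference_year years present in \code{series}.
#' @return The ratio to pass to [backcast_from_trend()].
#' @export
trend_multiplier <- function(series, target_year, reference_year) {
  stopifnot(all(c("year", "biomass") %in% names(series)))
  get1 <- function(y) {
    v <- series$biomass[series$year == y]
    if (length(v) != 1L) stop("year ", y, " not uniquely present in series",
                              call. = FALSE)
    v
  }
  get1(target_year) / get1(reference_year)
}

#' Assemble a partition-free predator biomass table in grams
#'
#' Applies back-cast rules for missing species-years, sums spatial
#' partitions (e.g. a stock assessed separately west and east of 140 deg W),
#' verifies completeness over the requested species-year grid, and converts
#' megagrams to grams (x 10^6).
#'
#' @param raw data frame with columns \code{species}, \code{year},
#'   \code{partition} (may be NA), \code{biomass_mg}.
#' @param backcast optional data frame of rules with columns \code{species},
#'   \code{year} (target), \code{ref_year}, \code{multiplier}; rules may
#'   chain (a target year may serve as another rule's reference).
#' @param years optional survey years the table must cover (default: years
#'   present in \code{raw}).
#' @return Data frame (species, year, biomass_g) with attribute
#'   \code{units = "g"}.
#' @export
assemble_biomass_table <- function(raw, backcast = NULL, years = NULL) {
  stopifnot(all(c("species", "year", "biomass_mg") %in% names(raw)))
  if (!"partition" %in% names(raw)) raw$partition <- NA_character_
  if (any(raw$biomass_mg < 0)) stop("biomass must be nonnegative",
                                    call. = FALSE)
  key <- paste(raw$species, raw$year, raw$partition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, year, partition) rows", call. = FALSE)
  }

  # sum partitions first (back-casts reference partition-free totals)
  tab <- raw %>%
    dplyr::group_by(.data$species, .data$year) %>%
    dplyr::summarise(biomass_mg = sum(.data$biomass_mg), .groups = "drop") %>%
    as.data.frame()

  if (!is.null(backcast) && nrow(backcast)) {
    stopifnot(all(c("species", "year", "ref_year", "multiplier") %in%
                    names(backcast)))
    pending <- backcast
    repeat {
      resolvable <- mapply(function(s, ry) {
        any(tab$species == s & tab$year == ry)
      }, pending$species, pending$ref_year)
      if (!any(resolvable)) break
      for (k in which(resolvable)) {
        r <- pending[k, ]
        ref <- tab$biomass_mg[tab$species == r$species &
                                tab$year == r$ref_year]
        tab <- rbind(tab, data.frame(
          species = r$species, year = r$year,
          biomass_mg = backcast_from_trend(ref, r$multiplier)))
      }
      pending <- pending[!resolvable, , drop = FALSE]
      if (!nrow(pending)) break
    }
    if (nrow(pending)) {
      stop("back-cast rules with missing reference years: ",
           paste(paste(pending$species, pending$ref_year), collapse = "; "),
           call. = FALSE)
    }
  }

  years <- years %||% sort(unique(tab$year))
  grid <- expand.grid(species = unique(tab$species), year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  merged <- dplyr::left_join(grid, tab, by = c("species", "year"))
  if (anyNA(merged$biomass_mg)) {
    gaps <- merged[is.na(merged$biomass_mg), c("species", "year")]
    stop("unresolved species-year cells: ",
         paste(paste(gaps$species, gaps$year), collapse = "; "),
         call. = FALSE)
  }
  out <- data.frame(species = merged$species, year = merged$year,
                    biomass_g = merged$biomass_mg * MG_TO_G)
  out <- out[order(out$species, out$year), ]
  rownames(out) <- NULL
  attr(out, "units") <- "g"
  out
}

#' Bundled Gulf of Alaska assessment biomass table
#'
#' Reads the bundled fixture of assessed total biomass (Mg) for the five
#' pollock predators over the 12 survey years 1990-2015, applies the Pacific
#' Halibut back-cast rules (1993 = 1996 x 1.045, 1990 = 1993 x 0.706), sums
#' the Walleye Pollock west/east partitions, and returns grams.
#'
#' Halibut values for 1996 onward are stored post-scalar (the proportion of
#' fish at or above 82 cm inside the region is retained in the fixture's
#' \code{scalar} column for provenance).
#'
#' @param file optional alternative fixture path.
#' @return See [assemble_biomass_table()].
#' @export
goa_biomass_table <- function(file = NULL) {
  file <- file %||% system.file("extdata", "goa_biomass_mg.csv",
                                package = "predindex", mustWork = TRUE)
  raw <- read.csv(file, stringsAsFactors = FALSE)
  rules <- data.frame(species = "PH", year = c(1993, 1990),
                      ref_year = c(1996, 1993),
                      multiplier = c(1.045, 0.706))
  assemble_biomass_table(raw, backcast = rules)
}

#' Assessed-size thresholds and length-mass defaults per species
#'
#' Minimum assessed lengths (cm) used to align CPUE with assessment
#' coverage: ATF >= 19, PC >= 0, PH >= 82 (CPUE pre-filtered at source),
#' SBL >= 45, WEP >= 37. The length-mass coefficients are the synthetic
#' generator's defaults, not assessment values.
#'
#' @param file optional alternative registry path.
#' @return Data frame (species, assessed_min_length_cm, cpue_prefiltered,
#'   lw_a, lw_b).
#' @export
species_registry <- function(file = NULL) {
  file <- file %||% system.file("extdata", "species_registry.csv",
                                package = "predindex", mustWork = TRUE)
  read.csv(file, stringsAsFactors = FALSE)
}
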