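#' Wisconsin bioenergetics consumption parameters
#'
#' Registry of allometric and temperature parameters for the maximum daily
#' consumption model, one row per predator species: \code{CA} and \code{CB}
#' (intercept and slope of the allometric consumption equation at 1 g),
#' \code{CQ} (rate of increase of consumption at low temperature),
#' \code{TC0} (temperature of peak consumption, deg C), \code{TCM}
#' (temperature above which consumption ceases, deg C), juvenile and adult
#' foraging days per year, and the adult length cutoff (cm).
#'
#' The bundled registry covers the five Gulf of Alaska pollock predators:
#' Arrowtooth Flounder (ATF), Pacific Cod (PC), Pacific Halibut (PH),
#' Sablefish (SBL) and Walleye Pollock (WEP).
#'
#' @param species optional character vector of species codes to return.
#' @param file optional path to an alternative registry CSV with the same
#'   columns.
#' @return A data frame with one row per species.
#' @export
#' @examples
#' bioenergetics_params("ATF")$CA  # 0.125
bioenergetics_params <- function(species = NULL, file = NULL) {
  file <- file %||% system.file("extdata", "bioenergetics_params.csv",
                                package = "predindex", mustWork = TRUE)
  reg <- read.csv(file, stringsAsFactors = FALSE)
  required <- c("species", "CA", "CB", "CQ", "TC0", "TCM",
                "D_juvenile", "D_adult", "adult_cutoff_cm")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols)) {
    stop("parameter registry is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- reg$TCM <= reg$TC0 | reg$CQ <= 1 |
    reg$D_juvenile < 1 | reg$D_juvenile > 366 |
    reg$D_adult < 1 | reg$D_adult > 366
  if (any(bad)) {
    stop("invalid bioenergetics parameters for: ",
         paste(reg$species[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(species)) {
    unknown <- setdiff(species, reg$species)
    if (length(unknown)) {
      stop("no bioenergetics parameters for species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[match(species, reg$species), , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Temperature scaling of maximum consumption
#'
#' Evaluates the exponential temperature-dependence function f(T) of the
#' Wisconsin consumption model:
#' \deqn{f(T) = V^X e^{X (1 - V)}, \quad V = (T_{CM} - T) / (T_{CM} - T_{C0})}
#' with \eqn{Z = \log(C_Q)(T_{CM} - T_{C0})},
#' \eqn{Y = \log(C_Q)(T_{CM} - T_{C0} + 2)} and
#' \eqn{X = Z^2 (1 + \sqrt{1 + 40/Y})^2 / 400}.
#'
#' f equals 1 at \code{TC0}, declines towards 0 as T approaches \code{TCM},
#' and is defined as exactly 0 for T at or above \code{TCM} (consumption
#' ceases). Temperatures below \code{TC0} (V > 1) are evaluated by the same
#' expression.
#'
#' @param T_h water temperature (deg C); vectorized.
#' @param params a one-row data frame or named list with \code{CQ},
#'   \code{TC0}, \code{TCM} (e.g. a row of [bioenergetics_params()]).
#' @return Scaling factor in [0, 1], same length as \code{T_h}.
#' @export
#' @examples
#' p <- bioenergetics_params("WEP")
#' temperature_scaling(p$TC0, p)  # 1
temperature_scaling <- function(T_h, params) {
  CQ <- params$CQ; TC0 <- params$TC0; TCM <- params$TCM
  stopifnot(length(CQ) == 1L, TCM > TC0, CQ > 1)
  Z <- log(CQ) * (TCM - TC0)
  Y <- log(CQ) * (TCM - TC0 + 2)
  X <- Z^2 * (1 + sqrt(1 + 40 / Y))^2 / 400
  V <- (TCM - T_h) / (TCM - TC0)
  f <- ifelse(T_h >= TCM, 0, V^X * exp(X * (1 - V)))
  pmin(pmax(f, 0), 1)
}

#' Maximum daily consumption rate
#'
#' \deqn{C_{max} = C_A W^{C_B} f(T_h)} in g prey per g predator per day,
#' with predator mass \code{W} in grams and the allometric intercept
#' \code{CA} referenced to a 1-g fish.
#'
#' @param W predator mass (g); vectorized (recycled against \code{T_h}).
#' @param T_h water temperature (deg C).
#' @param params a one-row parameter set as for [temperature_scaling()],
#'   additionally containing \code{CA} and \code{CB}.
#' @param foraging_scalar optional relative foraging-rate multiplier on
#'   \eqn{C_{max}} (default 1: predators feed at the theoretical maximum).
#' @return Consumption rate (g g^-1 d^-1).
#' @export
#' @examples
#' cmax(W = 1, T_h = 20.512, params = bioenergetics_params("ATF"))  # 0.125
cmax <- function(W, T_h, params, foraging_scalar = 1) {
  if (any(W <= 0)) stop("predator mass W must be positive", call. = FALSE)
  stopifnot(foraging_scalar > 0)
  params$CA * W^params$CB * temperature_scaling(T_h, params) * foraging_scalar
}

#' Mean annual rations by species, year and area
#'
#' Converts stomach-sampled predator records into mean annual rations
#' \eqn{\bar{C}_{s,i,j}} (g g^-1 yr^-1). Each fish's maximum daily
#' consumption is scaled by the species' foraging days per year (juvenile or
#' adult, split at the registry's adult length cutoff), then averaged over
#' fish within each species-year-area cell.
#'
#' Two imputation rules fill gaps, each flagged in the output:
#' \itemize{
#'  \item fish with missing temperature borrow the mean temperature of the
#'    same area from the nearest year with data (temperature borrow rule);
#'  \item species-year-area cells with no sampled fish take the mean ration
#'    of the same species and area over the years that do have fish.
#' }
#'
#' @param fish data frame with columns \code{species}, \code{year},
#'   \code{area}, \code{length_cm}, \code{mass_g}, \code{temperature_c}
#'   (NA allowed).
#' @param registry parameter registry from [bioenergetics_params()].
#' @param years optional survey years defining the full species-year-area
#'   grid to fill (defaults to years present in \code{fish}).
#' @param areas optional area labels for the grid (defaults to areas
#'   present).
#' @param foraging_scalars optional named numeric vector of per-species
#'   relative foraging-rate multipliers (default 1 for all).
#' @param average one of \code{"fish"} (default: unweighted mean over
#'   sampled fish) or \code{"haul"} (mean of haul means; requires a
#'   \code{haul} column).
#' @param surveyed optional data frame (year, area) of area-years the
#'   survey actually covered. Cells in unsurveyed area-years are omitted
#'   (they are survey gaps, to be propagated, not species-specific missing
#'   data to be imputed). Default: every year-area combination.
#' @return A data frame (species, year, area, ration, n_fish, imputed).
#' @export
mean_annual_ration <- function(fish, registry = bioenergetics_params(),
                               years = NULL, areas = NULL,
                               foraging_scalars = NULL,
                               average = c("fish", "haul"),
                               surveyed = NULL) {
  average <- match.arg(average)
  needed <- c("species", "year", "area", "length_cm", "mass_g",
              "temperature_c")
  stopifnot(all(needed %in% names(fish)))
  unknown <- setdiff(unique(fish$species), registry$species)
  if (length(unknown)) {
    stop("species without bioenergetics parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  years <- sort(years %||% unique(fish$year))
  areas <- areas %||% sort(unique(fish$area))
  species <- sort(unique(fish$species))

  # temperature borrow: fill missing temps with the same area's mean
  # temperature from the nearest year that has observations
  area_temp <- fish %>%
    dplyr::filter(!is.na(.data$temperature_c)) %>%
    dplyr::group_by(.data$area, .data$year) %>%
    dplyr::summarise(t_mean = mean(.data$temperature_c), .groups = "drop")
  borrow_temp <- function(area, year) {
    cand <- area_temp[area_temp$area == area, ]
    if (!nrow(cand)) return(NA_real_)
    cand$t_mean[which.min(abs(cand$year - year))]
  }
  temp_imputed <- is.na(fish$temperature_c)
  if (any(temp_imputed)) {
    fish$temperature_c[temp_imputed] <- mapply(
      borrow_temp, fish$area[temp_imputed], fish$year[temp_imputed])
    if (anyNA(fish$temperature_c)) {
      stop("temperature missing for some fish and no same-area year ",
           "available to borrow from", call. = FALSE)
    }
  }
  fish$.temp_imputed <- temp_imputed

  # per-fish annual ration = C_max x foraging days
  per_fish <- lapply(split(fish, fish$species), function(d) {
    p <- registry[registry$species == d$species[1L], ]
    fs <- 1
    if (!is.null(foraging_scalars) && d$species[1L] %in% names(foraging_scalars))
      fs <- foraging_scalars[[d$species[1L]]]
    D <- ifelse(d$length_cm >= p$adult_cutoff_cm, p$D_adult, p$D_juvenile)
    d$ration <- cmax(d$mass_g, d$temperature_c, p, foraging_scalar = fs) * D
    d
  })
  per_fish <- dplyr::bind_rows(per_fish)

  if (average == "haul") {
    stopifnot("haul" %in% names(per_fish))
    per_fish <- per_fish %>%
      dplyr::group_by(.data$species, .data$year, .data$area, .data$haul) %>%
      dplyr::summarise(ration = mean(.data$ration),
                       n = dplyr::n(),
                       ti = any(.data$.temp_imputed), .groups = "drop") %>%
      dplyr::rename(.temp_imputed = "ti")
  } else {
    per_fish$n <- 1L
  }
  cells <- per_fish %>%
    dplyr::group_by(.data$species, .data$year, .data$area) %>%
    dplyr::summarise(ration = mean(.data$ration),
                     n_fish = sum(.data$n),
                     imputed = any(.data$.temp_imputed), .groups = "drop")

  # fill empty species-year-area cells with the same area's mean over years
  grid <- expand.grid(species = species, year = years, areas = areas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid)[3] <- "area"
  if (!is.null(surveyed)) {
    grid <- dplyr::semi_join(grid, surveyed, by = c("year", "area"))
  }
  out <- dplyr::left_join(grid, cells, by = c("species", "year", "area"))
  miss <- is.na(out$ration)
  if (any(miss)) {
    area_mean <- cells %>%
      dplyr::group_by(.data$species, .data$area) %>%
      dplyr::summarise(m = mean(.data$ration), .groups = "drop")
    out <- dplyr::left_join(out, area_mean, by = c("species", "area"))
    out$ration[miss] <- out$m[miss]
    out$n_fish[miss] <- 0L
    out$imputed[miss] <- TRUE
    out$m <- NULL
    if (anyNA(out$ration)) {
      bad <- out[is.na(out$ration), c("species", "area")]
      stop("no fish in any year for: ",
           paste(unique(paste(bad$species, bad$area)), collapse = "; "),
           call. = FALSE)
    }
  }
  dplyr::arrange(as.data.frame(out), .data$species, .data$year, .data$area)
}
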