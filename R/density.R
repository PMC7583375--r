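#' Fraction of haul CPUE attributable to assessed-size fish
#'
#' Stock-assessment biomass covers only fish above a species-specific
#' minimum length, so haul CPUE must be restricted to the same component.
#' Each measured fish is assigned a mass from an allometric length-mass
#' relationship \eqn{W = a L^b}; the ratio of assessed mass to total mass is
#' the CPUE multiplier.
#'
#' @param lengths_cm measured fork lengths (cm).
#' @param counts number of fish at each length (default 1 each).
#' @param lw_a,lw_b length-mass coefficients.
#' @param threshold_cm minimum assessed length; 0 yields multiplier 1.
#' @return Mass fraction in [0, 1].
#' @export
#' @examples
#' assessed_cpue_fraction(c(10, 30), lw_a = 0.01, lw_b = 3, threshold_cm = 20)
assessed_cpue_fraction <- function(lengths_cm, counts = NULL,
                                   lw_a, lw_b, threshold_cm) {
  if (threshold_cm <= 0) return(1)
  counts <- counts %||% rep(1, length(lengths_cm))
  stopifnot(length(counts) == length(lengths_cm))
  mass <- lw_a * lengths_cm^lw_b * counts
  total <- sum(mass)
  if (total <= 0) {
    stop("total measured mass is zero; cannot form assessed fraction",
         call. = FALSE)
  }
  sum(mass[lengths_cm >= threshold_cm]) / total
}

#' Adjust haul CPUE to assessed-size fish for all species
#'
#' Applies [assessed_cpue_fraction()] per haul and species using the
#' thresholds and length-mass coefficients of a species registry. Species
#' flagged \code{cpue_prefiltered} (e.g. a setline survey that already
#' reports CPUE of fish above the threshold) pass through unchanged.
#'
#' @param catches data frame (haul, species, cpue).
#' @param length_table data frame (haul, species, length_cm, count).
#' @param registry data frame as from [species_registry()].
#' @return \code{catches} with an added \code{cpue_assessed} column.
#' @export
adjust_catch_cpue <- function(catches, length_table,
                              registry = species_registry()) {
  stopifnot(all(c("haul", "species", "cpue") %in% names(catches)))
  catches$cpue_assessed <- catches$cpue
  for (k in seq_len(nrow(catches))) {
    sp <- catches$species[k]
    reg <- registry[registry$species == sp, ]
    if (!nrow(reg)) stop("species not in registry: ", sp, call. = FALSE)
    if (isTRUE(reg$cpue_prefiltered) || reg$assessed_min_length_cm <= 0 ||
        catches$cpue[k] == 0) next
    ln <- length_table[length_table$haul == catches$haul[k] &
                         length_table$species == sp, ]
    if (!nrow(ln)) {
      stop(sprintf("positive CPUE but no measured lengths (haul %s, %s)",
                   catches$haul[k], sp), call. = FALSE)
    }
    frac <- assessed_cpue_fraction(ln$length_cm, ln$count, reg$lw_a,
                                   reg$lw_b, reg$assessed_min_length_cm)
    catches$cpue_assessed[k] <- catches$cpue[k] * frac
  }
  catches
}

delta_terms <- function(terms) {
  rhs <- c("1",
           if ("year" %in% terms) "factor(year)",
           if ("lonlat" %in% terms) "s(lon, lat)",
           if ("depth" %in% terms) "s(depth, k = 5)",
           if ("temperature" %in% terms) "s(temperature, k = 5)")
  paste(rhs, collapse = " + ")
}

# enumerate covariate subsets, fit, and keep the lowest-AIC model;
# ties within `tie_delta` resolved toward fewer terms
select_gam <- function(response, data, candidates, family, select,
                       tie_delta = 2) {
  subsets <- if (select) {
    unlist(lapply(0:length(candidates), function(k) {
      utils::combn(candidates, k, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    list(candidates)
  }
  fits <- lapply(subsets, function(terms) {
    f <- as.formula(paste(response, "~", delta_terms(terms)))
    fit <- try(mgcv::gam(f, data = data, family = family, method = "GCV.Cp"),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(terms = terms, fit = fit, aic = stats::AIC(fit))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no candidate model converged", call. = FALSE)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  near <- which(aics <= min(aics) + tie_delta)
  sizes <- vapply(fits[near], function(x) length(x$terms), integer(1))
  best <- fits[[near[which.min(sizes)]]]
  trace <- data.frame(
    terms = vapply(fits, function(x) paste(x$terms, collapse = "+"),
                   character(1)),
    n_terms = vapply(fits, function(x) length(x$terms), integer(1)),
    aic = aics)
  list(best = best, trace = trace[order(trace$aic), ])
}

#' Fit a delta (hurdle) model of species density
#'
#' Two-part CPUE standardization: probability of occurrence (binomial GAM on
#' presence/absence) and log-transformed positive CPUE (Gaussian GAM), each
#' modeled as a function of survey year and smooths of location and depth
#' (and bottom temperature for gears that record it). Candidate covariate
#' subsets are enumerated and the lowest-AIC model retained per component;
#' ties within \code{tie_delta} AIC units go to the model with fewer terms.
#'
#' If the species occupies at least \code{occupancy_skip} of hauls, the
#' presence component is skipped and occurrence probability fixed at 1
#' (appropriate for species observed at nearly all stations). Optionally
#' each best-fit component is refit as a mixed model with a per-survey-year
#' Gaussian spatial autocorrelation structure; the variant is retained only
#' if its AIC improves, and a non-converging variant is dropped with a
#' warning rather than failing.
#'
#' @param hauls data frame (haul, year, lon, lat, depth, temperature).
#' @param catches data frame (haul, species, cpue or cpue_assessed).
#' @param species species code to model.
#' @param use_temperature include temperature among candidates (only for
#'   gears that record it).
#' @param select enumerate covariate subsets (TRUE) or fit the full model
#'   only (FALSE).
#' @param spatial also try the per-year Gaussian spatial-correlation mixed
#'   variant (slower; default FALSE).
#' @param occupancy_skip occupancy at or above which the presence component
#'   is skipped (default 0.99).
#' @param min_positive minimum positive observations required (default 30).
#' @param tie_delta AIC tie window for the parsimony rule (default 2).
#' @return Object of class \code{delta_fit}.
#' @export
fit_delta_model <- function(hauls, catches, species,
                            use_temperature = FALSE, select = TRUE,
                            spatial = FALSE, occupancy_skip = 0.99,
                            min_positive = 30, tie_delta = 2) {
  stopifnot(all(c("haul", "year", "lon", "lat", "depth") %in% names(hauls)))
  cpue_col <- if ("cpue_assessed" %in% names(catches)) "cpue_assessed"
              else "cpue"
  sp_catch <- catches[catches$species == species, c("haul", cpue_col)]
  names(sp_catch)[2] <- "cpue"
  d <- dplyr::left_join(hauls, sp_catch, by = "haul")
  d$cpue[is.na(d$cpue)] <- 0
  d$presence <- as.integer(d$cpue > 0)
  if (length(unique(d$year)) < 2) {
    stop("need at least two survey years", call. = FALSE)
  }
  if (sum(d$presence) < min_positive) {
    stop(sprintf("only %d positive observations (< %d)", sum(d$presence),
                 min_positive), call. = FALSE)
  }
  candidates <- c("year", "lonlat", "depth",
                  if (use_temperature) "temperature")
  occupancy <- mean(d$presence)

  po <- NULL; po_trace <- NULL
  if (occupancy < occupancy_skip) {
    sel <- select_gam("presence", d, candidates, stats::binomial(), select,
                      tie_delta)
    po <- sel$best; po_trace <- sel$trace
  }
  pos <- d[d$presence == 1, ]
  pos$log_cpue <- log(pos$cpue)
  sel <- select_gam("log_cpue", pos, candidates, stats::gaussian(), select,
                    tie_delta)
  pa <- sel$best; pa_trace <- sel$trace

  spatial_used <- c(po = FALSE, pa = FALSE)
  if (spatial) {
    refit <- function(best, data, family) {
      f <- as.formula(paste(all.vars(stats::formula(best$fit))[1], "~",
                            delta_terms(best$terms)))
      out <- tryCatch({
        g <- mgcv::gamm(f, data = data, family = family,
                        correlation = nlme::corGaus(
                          form = ~ lon + lat | year_f))
        list(fit = g, aic = stats::AIC(g$lme))
      }, error = function(e) {
        warning("spatial-correlation variant did not converge; keeping ",
                "uncorrelated fit (", conditionMessage(e), ")",
                call. = FALSE)
        NULL
      })
      out
    }
    d$year_f <- factor(d$year); pos$year_f <- factor(pos$year)
    if (!is.null(po)) {
      v <- refit(po, d, stats::binomial())
      if (!is.null(v) && v$aic < po$aic) {
        po$fit <- v$fit$gam; po$aic <- v$aic; spatial_used["po"] <- TRUE
      }
    }
    v <- refit(pa, pos, stats::gaussian())
    if (!is.null(v) && v$aic < pa$aic) {
      pa$fit <- v$fit$gam; pa$aic <- v$aic; spatial_used["pa"] <- TRUE
    }
  }

  structure(list(
    species = species,
    po_fit = if (!is.null(po)) po$fit, po_terms = if (!is.null(po)) po$terms,
    po_trace = po_trace,
    pa_fit = pa$fit, pa_terms = pa$terms, pa_trace = pa_trace,
    sigma = sqrt(pa$fit$sig2),
    occupancy = occupancy,
    spatial_used = spatial_used,
    years = sort(unique(d$year)),
    envelope = list(lon = range(d$lon), lat = range(d$lat),
                    depth = range(d$depth)),
    n = nrow(d), n_positive = sum(d$presence)),
    class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat(sprintf("<delta_fit> %s: %d hauls, %d positive (occupancy %.2f)\n",
              x$species, x$n, x$n_positive, x$occupancy))
  if (is.null(x$po_fit)) {
    cat("  presence: skipped (occupancy ~ 1), PO = 1\n")
  } else {
    cat("  presence terms:", paste(x$po_terms, collapse = " + "), "\n")
  }
  cat("  positive-CPUE terms:", paste(x$pa_terms, collapse = " + "), "\n")
  invisible(x)
}

#' Predict absolute density on the prediction grid
#'
#' Multiplies predicted probability of occurrence and back-transformed
#' positive CPUE per grid cell: \eqn{D = PO \times PA}. The log-scale
#' positive component is back-transformed with the lognormal mean
#' \eqn{\exp(\hat\mu + \hat\sigma^2/2)} by default (set
#' \code{bias_correct = FALSE} for the naive \eqn{\exp(\hat\mu)}). Cells
#' outside the surveyed longitude/latitude/depth envelope are excluded; the
#' same mask is used for every year, so the cell count per species is
#' constant across years.
#'
#' @param fit a [fit_delta_model()] result.
#' @param frame a [make_spatial_frame()] grid.
#' @param years years to predict; must be among the fitted years unless
#'   \code{allow_extrapolation}.
#' @param temperature_fun \code{function(lon, lat, year)} supplying bottom
#'   temperature per cell when the fit uses temperature.
#' @param bias_correct lognormal back-transform correction (default TRUE).
#' @param allow_extrapolation permit years outside the fit (default FALSE).
#' @return Data frame (species, year, cell, lon, lat, stat_area, subregion,
#'   assessment, D).
#' @export
predict_density_grid <- function(fit, frame, years = NULL,
                                 temperature_fun = NULL,
                                 bias_correct = TRUE,
                                 allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "delta_fit"), inherits(frame, "spatial_frame"))
  years <- years %||% fit$years
  outside <- setdiff(years, fit$years)
  if (length(outside) && !allow_extrapolation) {
    stop("years not covered by the fit: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  env <- fit$envelope
  cells <- frame$cells
  cells <- cells[cells$lon >= env$lon[1] & cells$lon <= env$lon[2] &
                   cells$lat >= env$lat[1] & cells$lat <= env$lat[2] &
                   cells$depth >= env$depth[1] & cells$depth <= env$depth[2], ]
  if (!nrow(cells)) stop("no grid cells inside the surveyed envelope",
                         call. = FALSE)
  uses_temp <- any(c(!is.null(fit$po_terms) &&
                       "temperature" %in% fit$po_terms,
                     "temperature" %in% fit$pa_terms))
  if (uses_temp && is.null(temperature_fun)) {
    stop("fit uses temperature; supply temperature_fun(lon, lat, year)",
         call. = FALSE)
  }
  out <- lapply(years, function(yr) {
    nd <- cells
    nd$year <- yr
    if (uses_temp) nd$temperature <- temperature_fun(nd$lon, nd$lat, yr)
    po <- if (is.null(fit$po_fit)) 1 else
      as.numeric(predict(fit$po_fit, newdata = nd, type = "response"))
    mu <- as.numeric(predict(fit$pa_fit, newdata = nd))
    pa <- if (bias_correct) exp(mu + fit$sigma^2 / 2) else exp(mu)
    data.frame(species = fit$species, year = yr, cell = nd$cell,
               lon = nd$lon, lat = nd$lat, stat_area = nd$stat_area,
               subregion = nd$subregion, assessment = nd$assessment,
               D = po * pa)
  })
  dplyr::bind_rows(out)
}

#' Normalize densities to relative densities per species-year
#'
#' \eqn{rD_{s,i,g} = D_{s,i,g} / \sum_g D_{s,i,g}}, a simplex over grid
#' cells within each species-year. Species-years requested in \code{years}
#' but absent from \code{field} are filled with the cellwise mean of the
#' available years' relative densities, renormalized and flagged (used for
#' a survey that did not operate in early years).
#'
#' @param field density data frame from [predict_density_grid()].
#' @param years optional full set of survey years to cover.
#' @return \code{field} with \code{rD} and \code{imputed} columns.
#' @export
relative_density <- function(field, years = NULL) {
  stopifnot(all(c("species", "year", "cell", "D") %in% names(field)))
  if (any(field$D < 0)) stop("densities must be nonnegative", call. = FALSE)
  field <- field %>%
    dplyr::group_by(.data$species, .data$year) %>%
    dplyr::mutate(rD = {
      tot <- sum(.data$D)
      if (tot <= 0) stop("all-zero density field cannot be normalized",
                         call. = FALSE)
      .data$D / tot
    }) %>%
    dplyr::ungroup()
  field$imputed <- FALSE
  years <- years %||% unique(field$year)
  filled <- lapply(unique(field$species), function(sp) {
    have <- field[field$species == sp, ]
    miss <- setdiff(years, unique(have$year))
    if (!length(miss)) return(have)
    cell_mean <- have %>%
      dplyr::group_by(dplyr::across(dplyr::any_of(
        c("species", "cell", "lon", "lat", "stat_area", "subregion",
          "assessment")))) %>%
      dplyr::summarise(D = mean(.data$D), rD = mean(.data$rD),
                       .groups = "drop")
    cell_mean$rD <- cell_mean$rD / sum(cell_mean$rD)
    extra <- lapply(miss, function(yr) {
      x <- cell_mean; x$year <- yr; x$imputed <- TRUE; x
    })
    dplyr::bind_rows(c(list(have), extra))
  })
  out <- dplyr::bind_rows(filled)
  dplyr::arrange(as.data.frame(out), .data$species, .data$year, .data$cell)
}

#' Aggregate relative densities to coarser spatial scales
#'
#' Sums cell-level relative densities within statistical areas, subregions,
#' the assessment area, or the whole basin. When coverage is complete the
#' area values of any scale sum to the basin total of 1 per species-year.
#'
#' @param field output of [relative_density()].
#' @param scale one of \code{"stat_area"}, \code{"subregion"},
#'   \code{"assessment"}, \code{"basin"}.
#' @return Data frame (species, year, area, rD, imputed).
#' @export
aggregate_density <- function(field,
                              scale = c("stat_area", "subregion",
                                        "assessment", "basin")) {
  scale <- match.arg(scale)
  f <- field
  f$area <- switch(scale,
    stat_area = f$stat_area,
    subregion = f$subregion,
    assessment = ifelse(f$assessment, "assessment", NA_character_),
    basin = "basin")
  f <- f[!is.na(f$area), ]
  f %>%
    dplyr::group_by(.data$species, .data$year, .data$area) %>%
    dplyr::summarise(rD = sum(.data$rD), imputed = any(.data$imputed),
                     .groups = "drop") %>%
    as.data.frame()
}
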