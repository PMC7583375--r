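#' Fork-length weighting factors for size-structured stomach subsampling
#'
#' Fish selected for stomach analysis are not length-representative of the
#' catch. For each predator, haul, and 10-cm fork-length bin b the weighting
#' factor is \eqn{WF_L = P_T / P_F}, the ratio of the bin's proportion in
#' the total catch to its proportion in the stomach subsample. Bins present
#' in the catch but absent from the subsample carry no factor (there are no
#' stomachs to weight).
#'
#' @param catch_lengths data frame (haul, species, length_cm, count) of all
#'   measured fish.
#' @param stomach_lengths data frame (haul, species, length_cm) of fish
#'   subsampled for stomachs (one row per stomach).
#' @param bin_width fork-length bin width in cm (default 10).
#' @return Data frame (species, haul, bin, P_T, P_F, WF_L) for bins with
#'   subsampled fish.
#' @export
#' @examples
#' # over-represented bin: P_T 0.27 vs P_F 0.35 -> WF_L ~ 0.77 (down-weight)
length_weighting_factors <- function(catch_lengths, stomach_lengths,
                                     bin_width = 10) {
  stopifnot(all(c("haul", "species", "length_cm") %in% names(catch_lengths)),
            all(c("haul", "species", "length_cm") %in%
                  names(stomach_lengths)))
  if (!"count" %in% names(catch_lengths)) catch_lengths$count <- 1
  catch_lengths$bin <- length_bin(catch_lengths$length_cm, bin_width)
  stomach_lengths$bin <- length_bin(stomach_lengths$length_cm, bin_width)

  pt <- catch_lengths %>%
    dplyr::group_by(.data$species, .data$haul, .data$bin) %>%
    dplyr::summarise(n = sum(.data$count), .groups = "drop_last") %>%
    dplyr::mutate(P_T = .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::select("species", "haul", "bin", "P_T")
  pf <- stomach_lengths %>%
    dplyr::group_by(.data$species, .data$haul, .data$bin) %>%
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") %>%
    dplyr::mutate(P_F = .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::select("species", "haul", "bin", "P_F")

  wf <- dplyr::inner_join(pf, pt, by = c("species", "haul", "bin"))
  if (nrow(wf) < nrow(pf)) {
    stop("stomach subsample contains haul/bin combinations absent from ",
         "the catch length table (join error)", call. = FALSE)
  }
  wf$WF_L <- wf$P_T / wf$P_F
  as.data.frame(wf[, c("species", "haul", "bin", "P_T", "P_F", "WF_L")])
}

#' Biomass weighting factors from predicted densities
#'
#' Survey effort is not proportional to predator biomass, so stomachs from
#' cells where the species is dense are up-weighted:
#' \eqn{WF_B = D_{s,i,g} / \bar{D}_{s,i}}. The mean of \eqn{WF_B} over a
#' species-year's cells is 1 by construction.
#'
#' @param field density data frame with columns species, year, cell, D.
#' @return Data frame (species, year, cell, WF_B).
#' @export
biomass_weighting_factors <- function(field) {
  stopifnot(all(c("species", "year", "cell", "D") %in% names(field)))
  out <- field %>%
    dplyr::group_by(.data$species, .data$year) %>%
    dplyr::mutate(WF_B = {
      m <- mean(.data$D)
      if (m <= 0) stop("zero mean density; cannot form biomass weights",
                       call. = FALSE)
      .data$D / m
    }) %>%
    dplyr::ungroup()
  as.data.frame(out[, c("species", "year", "cell", "WF_B")])
}

#' Weighted gravimetric prey proportions
#'
#' Applies fork-length and biomass weighting to prey masses,
#' \eqn{ww_{q,r} = w_{q,r} \times WF_L \times WF_B}, then forms the
#' gravimetric proportion of each prey taxon per predator species, year and
#' area:
#' \deqn{p_q = \sum_r ww_{q,r} / \sum_r \sum_q ww_{q,r}.}
#' Empty stomachs count towards the number of stomachs examined but
#' contribute no mass. Species-years with no stomachs in an area are
#' imputed with the mean proportion of that species and area over the other
#' years, flagged.
#'
#' @param stomachs data frame with one row per prey item: \code{stomach_id},
#'   \code{species}, \code{haul}, \code{year}, \code{area},
#'   \code{pred_length_cm}, \code{prey_taxon}, \code{prey_mass_g}. Empty
#'   stomachs are rows with \code{prey_taxon = NA} and mass 0.
#' @param wf_l output of [length_weighting_factors()]; NULL for unit
#'   length weights.
#' @param wf_b output of [biomass_weighting_factors()]; NULL for unit
#'   biomass weights. Requires a \code{cell} column on \code{stomachs}.
#' @param target_taxon taxon whose share is reported as \code{p_target}
#'   (default \code{"pollock"}).
#' @param years optional full year set for imputation of missing years.
#' @param unbinned one of \code{"drop"} (default; drop stomachs whose
#'   length bin carries no factor, with a warning) or \code{"error"}.
#' @param bin_width fork-length bin width (cm).
#' @param surveyed optional data frame (year, area) of surveyed area-years;
#'   cells in unsurveyed area-years are left out rather than imputed (they
#'   are survey gaps). Default: every year-area combination.
#' @return List with \code{proportions} (species, year, area, prey_taxon,
#'   p, n_stomachs, imputed) and \code{target} (species, year, area,
#'   p_target, n_stomachs, imputed).
#' @export
prey_proportions <- function(stomachs, wf_l = NULL, wf_b = NULL,
                             target_taxon = "pollock", years = NULL,
                             unbinned = c("drop", "error"),
                             bin_width = 10, surveyed = NULL) {
  unbinned <- match.arg(unbinned)
  needed <- c("stomach_id", "species", "haul", "year", "area",
              "pred_length_cm", "prey_taxon", "prey_mass_g")
  stopifnot(all(needed %in% names(stomachs)))
  s <- stomachs
  s$bin <- length_bin(s$pred_length_cm, bin_width)

  if (!is.null(wf_l)) {
    s <- dplyr::left_join(s, wf_l[, c("species", "haul", "bin", "WF_L")],
                          by = c("species", "haul", "bin"))
    if (anyNA(s$WF_L)) {
      n_bad <- length(unique(s$stomach_id[is.na(s$WF_L)]))
      if (unbinned == "error") {
        stop(n_bad, " stomachs fall in length bins with no weighting factor",
             call. = FALSE)
      }
      warning("dropping ", n_bad,
              " stomachs in length bins with no weighting factor",
              call. = FALSE)
      s <- s[!is.na(s$WF_L), ]
    }
  } else {
    s$WF_L <- 1
  }
  if (!is.null(wf_b)) {
    stopifnot("cell" %in% names(s))
    s <- dplyr::left_join(s, wf_b, by = c("species", "year", "cell"))
    if (anyNA(s$WF_B)) {
      stop("stomachs in cells with no biomass weighting factor",
           call. = FALSE)
    }
  } else {
    s$WF_B <- 1
  }
  s$ww <- ifelse(is.na(s$prey_mass_g), 0, s$prey_mass_g) * s$WF_L * s$WF_B

  counts <- s %>%
    dplyr::group_by(.data$species, .data$year, .data$area) %>%
    dplyr::summarise(n_stomachs = dplyr::n_distinct(.data$stomach_id),
                     .groups = "drop")
  mass <- s[!is.na(s$prey_taxon), ] %>%
    dplyr::group_by(.data$species, .data$year, .data$area,
                    .data$prey_taxon) %>%
    dplyr::summarise(ww = sum(.data$ww), .groups = "drop_last") %>%
    dplyr::mutate(p = .data$ww / sum(.data$ww)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"ww")
  props <- dplyr::left_join(mass, counts,
                            by = c("species", "year", "area"))
  props$imputed <- FALSE

  years <- years %||% sort(unique(stomachs$year))
  filled <- lapply(split(props, props$species), function(d) {
    sp <- d$species[1]
    grid <- expand.grid(year = years, area = unique(d$area),
                        stringsAsFactors = FALSE)
    if (!is.null(surveyed)) {
      grid <- dplyr::semi_join(grid, surveyed, by = c("year", "area"))
    }
    have <- unique(d[, c("year", "area")])
    miss <- dplyr::anti_join(grid, have, by = c("year", "area"))
    if (!nrow(miss)) return(d)
    extra <- lapply(seq_len(nrow(miss)), function(k) {
      donor <- d[d$area == miss$area[k], ]
      if (!nrow(donor)) return(NULL)  # area never sampled: genuine gap
      m <- donor %>%
        dplyr::group_by(.data$prey_taxon) %>%
        dplyr::summarise(p = mean(.data$p), .groups = "drop")
      m$p <- m$p / sum(m$p)
      data.frame(species = sp, year = miss$year[k], area = miss$area[k],
                 prey_taxon = m$prey_taxon, p = m$p, n_stomachs = 0L,
                 imputed = TRUE)
    })
    dplyr::bind_rows(c(list(d), Filter(Negate(is.null), extra)))
  })
  props <- as.data.frame(dplyr::bind_rows(filled))

  target <- props %>%
    dplyr::group_by(.data$species, .data$year, .data$area) %>%
    dplyr::summarise(
      p_target = sum(.data$p[.data$prey_taxon == target_taxon]),
      n_stomachs = .data$n_stomachs[1], imputed = .data$imputed[1],
      .groups = "drop") %>%
    as.data.frame()
  list(proportions = props, target = target)
}
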