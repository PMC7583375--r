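#' Default INPFC-style statistical-area boundaries
#'
#' Longitude breaks (deg W as negative numbers) splitting the study domain
#' into the Shumagin (610), Chirikof (620), Kodiak (630), Yakutat (640) and
#' Southeastern (650) statistical areas.
#'
#' @return Named list with \code{breaks} (4 interior boundaries) and
#'   \code{labels} (5 area names, west to east).
#' @export
default_area_breaks <- function() {
  list(breaks = c(-159, -154, -147, -140),
       labels = c("610", "620", "630", "640", "650"))
}

#' Map longitudes to statistical areas
#'
#' @param lon numeric longitudes (decimal degrees, negative west).
#' @param areas boundary definition as from [default_area_breaks()].
#' @return Character vector of area labels.
#' @export
assign_stat_area <- function(lon, areas = default_area_breaks()) {
  idx <- findInterval(lon, areas$breaks) + 1L
  areas$labels[idx]
}

# subregion rollup: Shumagin is western, Chirikof+Kodiak central,
# Yakutat+Southeastern eastern
default_subregion_map <- function() {
  c("610" = "W", "620" = "C", "630" = "C", "640" = "E", "650" = "E")
}

#' Build a uniform prediction grid over the study domain
#'
#' Constructs a regular grid of approximately \code{cell_km} x
#' \code{cell_km} cells over a longitude/latitude box, using a local
#' equirectangular (equal-area at the central latitude) approximation for
#' cell spacing. Each cell is labeled with its statistical area (by cell
#' center), subregion, and whether it lies in the prey stock-assessment area
#' (west of the easternmost area boundary, i.e. 140 deg W by default).
#'
#' @param lon_range,lat_range numeric length-2 extents in decimal degrees.
#' @param cell_km nominal cell size (km), default 50.
#' @param areas statistical-area boundaries ([default_area_breaks()]).
#' @param subregion_map named character vector mapping area label to
#'   subregion code; default \code{610 -> W, 620/630 -> C, 640/650 -> E}.
#' @param depth_fun optional \code{function(lon, lat)} returning bottom
#'   depth (m) per cell; default a smooth shelf deepening offshore.
#' @param assessment_lon_max eastern limit (deg) of the assessment area.
#' @return An object of class \code{spatial_frame}: list with \code{cells}
#'   data frame (cell, lon, lat, depth, stat_area, subregion, assessment)
#'   and the construction parameters.
#' @export
make_spatial_frame <- function(lon_range = c(-170, -132),
                               lat_range = c(52, 60),
                               cell_km = 50,
                               areas = default_area_breaks(),
                               subregion_map = default_subregion_map(),
                               depth_fun = NULL,
                               assessment_lon_max = -140) {
  stopifnot(diff(lon_range) > 0, diff(lat_range) > 0, cell_km > 0)
  km_per_deg <- 111.2
  lat_mid <- mean(lat_range)
  dlat <- cell_km / km_per_deg
  dlon <- cell_km / (km_per_deg * cos(lat_mid * pi / 180))
  lon_c <- seq(lon_range[1] + dlon / 2, lon_range[2], by = dlon)
  lat_c <- seq(lat_range[1] + dlat / 2, lat_range[2], by = dlat)
  cells <- expand.grid(lon = lon_c, lat = lat_c, KEEP.OUT.ATTRS = FALSE)
  cells$cell <- seq_len(nrow(cells))
  depth_fun <- depth_fun %||% function(lon, lat) {
    # generic shelf: deepens away from the coast (higher latitude shallower)
    150 + 250 * (lat_range[2] - lat) / diff(lat_range)
  }
  cells$depth <- depth_fun(cells$lon, cells$lat)
  cells$stat_area <- assign_stat_area(cells$lon, areas)
  cells$subregion <- unname(subregion_map[cells$stat_area])
  if (anyNA(cells$subregion)) {
    stop("subregion_map does not cover all statistical areas", call. = FALSE)
  }
  cells$assessment <- cells$lon < assessment_lon_max
  cells <- cells[, c("cell", "lon", "lat", "depth", "stat_area",
                     "subregion", "assessment")]
  structure(list(cells = cells, lon_range = lon_range,
                 lat_range = lat_range, cell_km = cell_km, areas = areas,
                 subregion_map = subregion_map,
                 assessment_lon_max = assessment_lon_max),
            class = "spatial_frame")
}

#' @export
print.spatial_frame <- function(x, ...) {
  cat(sprintf("<spatial_frame> %d cells (%g km), lon [%g, %g], lat [%g, %g]\n",
              nrow(x$cells), x$cell_km, x$lon_range[1], x$lon_range[2],
              x$lat_range[1], x$lat_range[2]))
  print(table(x$cells$stat_area))
  invisible(x)
}

# locate the frame cell containing each point (by nearest cell center,
# which for a regular grid equals the containing cell)
frame_cell_at <- function(frame, lon, lat) {
  cells <- frame$cells
  vapply(seq_along(lon), function(k) {
    d2 <- (cells$lon - lon[k])^2 + (cells$lat - lat[k])^2
    cells$cell[which.min(d2)]
  }, integer(1))
}
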