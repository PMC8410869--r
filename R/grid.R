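#' Define a regular longitude-latitude grid
#'
#' All gridded objects in the package (climatologies, suitability cubes,
#' change fields) live on a single regular grid described by a `grid_spec`.
#' Cell membership is half-open, `[west, east)` in longitude and
#' `[south, north)` in latitude, with longitudes normalised to
#' `[lon_min, lon_min + 360)` for global grids so that records at 180
#' degrees east wrap onto the -180 degrees cell rather than falling off
#' the grid.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid bounds in degrees.
#' @param cell_size Cell edge length in degrees. Both spans must be integer
#'   multiples of `cell_size`.
#' @param months Integer vector of months covered by monthly fields.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(cell_size = 10)
#' nrow(grid_cells(spec)) # 36 x 18 cells
#' @export
grid_spec <- function(lon_min = -180, lon_max = 180,
                      lat_min = -90, lat_max = 90,
                      cell_size = 10, months = 1:12) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.")
  }
  if (lon_max <= lon_min || lat_max <= lat_min) {
    abort("Grid bounds must satisfy lon_min < lon_max and lat_min < lat_max.")
  }
  n_lon <- (lon_max - lon_min) / cell_size
  n_lat <- (lat_max - lat_min) / cell_size
  if (abs(n_lon - round(n_lon)) > 1e-9 || abs(n_lat - round(n_lat)) > 1e-9) {
    abort("Grid spans must be integer multiples of `cell_size`.")
  }
  if (!all(months %in% 1:12) || length(months) < 1) {
    abort("`months` must be a subset of 1:12.")
  }
  structure(
    list(
      lon_min = lon_min, lon_max = lon_max,
      lat_min = lat_min, lat_max = lat_max,
      cell_size = cell_size,
      n_lon = as.integer(round(n_lon)), n_lat = as.integer(round(n_lat)),
      months = as.integer(months)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %g deg cells, lon [%g, %g), lat [%g, %g), %d x %d cells, %d months\n",
    x$cell_size, x$lon_min, x$lon_max, x$lat_min, x$lat_max,
    x$n_lon, x$n_lat, length(x$months)
  ))
  invisible(x)
}

#' Cell centres of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `cell` (integer id, row-major from the
#'   south-west corner), `lon` and `lat` (cell-centre coordinates).
#' @export
grid_cells <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  lon <- spec$lon_min + spec$cell_size / 2 + spec$cell_size * (seq_len(spec$n_lon) - 1)
  lat <- spec$lat_min + spec$cell_size / 2 + spec$cell_size * (seq_len(spec$n_lat) - 1)
  g <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  tibble(cell = seq_len(nrow(g)), lon = g$lon, lat = g$lat)
}

#' Map coordinates onto grid cells
#'
#' Longitude is wrapped into the grid's span when the grid is global
#' (360-degree span); latitude is not wrapped. Coordinates falling outside
#' the half-open latitude range return `NA`.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @return Integer vector of cell ids (`NA` for out-of-bounds points).
#' @export
cell_of <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"))
  span <- spec$lon_max - spec$lon_min
  if (abs(span - 360) < 1e-9) {
    lon <- ((lon - spec$lon_min) %% 360) + spec$lon_min
  }
  i <- floor((lon - spec$lon_min) / spec$cell_size)
  j <- floor((lat - spec$lat_min) / spec$cell_size)
  ok <- !is.na(i) & !is.na(j) &
    i >= 0 & i < spec$n_lon & j >= 0 & j < spec$n_lat
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer(j[ok] * spec$n_lon + i[ok] + 1L)
  out
}

# Attach/retrieve the grid a tibble of fields lives on.
set_grid <- function(x, spec) {
  attr(x, "grid_spec") <- spec
  x
}

#' Retrieve the grid specification attached to a gridded tibble
#' @param x A gridded tibble produced by this package.
#' @return The `grid_spec`, or `NULL` when none is attached.
#' @export
get_grid <- function(x) attr(x, "grid_spec")

as_clim_stack <- function(x, spec) {
  x <- set_grid(as_tibble(x), spec)
  class(x) <- unique(c("clim_stack", class(x)))
  x
}
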