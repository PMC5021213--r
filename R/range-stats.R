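# Range ("climate space") change statistics: occupied-cell counts, percent
# change, centroids, great-circle displacement with bearing, and two-sample
# t-tests on the coordinates of occupied cells.

#' Number of occupied cells in a presence grid
#' @param pg a [presence_grid()].
#' @return Integer count of cells at or above the presence threshold.
#' @export
count_cells <- function(pg) {
  stopifnot(inherits(pg, "presence_grid"))
  sum(pg$presence == 1L)
}

#' Percent change in occupied-cell count
#'
#' `100 * (n_pred - n_orig) / n_orig`; linear in `n_pred` and zero at
#' `n_pred = n_orig`. Report tables round to 2 decimals.
#'
#' @param n_orig baseline cell count (> 0).
#' @param n_pred predicted cell count.
#' @return Percent change (unrounded).
#' @export
percent_change <- function(n_orig, n_pred) {
  if (any(n_orig <= 0)) stop_invalid("percent change undefined for n_orig <= 0")
  100 * (n_pred - n_orig) / n_orig
}

#' Centroid of a set of occupied cells
#'
#' Arithmetic mean of longitudes and latitudes — the point about which the
#' vector displacements of the occupied cells sum to zero.
#'
#' @param cells data frame (or `presence_grid`) with `lon` and `lat`; for a
#'   `presence_grid` only occupied cells contribute.
#' @return A `centroid`: list with `lon` and `lat`.
#' @export
centroid <- function(cells) {
  if (inherits(cells, "presence_grid")) {
    cells <- cells[cells$presence == 1L, , drop = FALSE]
  }
  stopifnot(all(c("lon", "lat") %in% names(cells)))
  if (nrow(cells) == 0L) stop_invalid("no cells: centroid undefined")
  structure(list(lon = mean(cells$lon), lat = mean(cells$lat)),
            class = "centroid")
}

#' Great-circle displacement between two centroids
#'
#' Haversine distance on a sphere of radius 6371 km, plus the initial bearing
#' from `c0` to `c1` (0 degrees = north, clockwise, in `[0, 360)`).
#'
#' @param c0,c1 [centroid()]s (or lists with `lon`, `lat` in decimal degrees).
#' @return A `displacement`: list with `distance_km` and `bearing_deg`.
#' @export
displacement <- function(c0, c1) {
  rad <- pi / 180
  phi1 <- c0$lat * rad; phi2 <- c1$lat * rad
  dphi <- (c1$lat - c0$lat) * rad
  dlam <- (c1$lon - c0$lon) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  d <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  theta <- atan2(sin(dlam) * cos(phi2),
                 cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam))
  structure(list(distance_km = d,
                 bearing_deg = (theta / rad) %% 360),
            class = "displacement")
}

#' Coordinate-shift t-tests between two cell sets
#'
#' Two-sample t-tests comparing the latitudes, and the longitudes, of the
#' baseline occupied cells against the projected ones. The statistic is
#' signed as `(mean original - mean projected) / SE`, so a northward shift
#' gives a negative latitude t. Welch's unequal-variance form is the default;
#' the pooled-variance Student form is available via `var_equal = TRUE`.
#'
#' @param cells_orig,cells_pred data frames (or `presence_grid`s) with `lon`
#'   and `lat`; each must contribute at least 2 cells.
#' @param var_equal use the pooled-variance form.
#' @return A `shift_test`: `t_lat`, `t_lon`, `df_lat`, `df_lon`, `p_lat`,
#'   `p_lon`.
#' @export
coordinate_shift_test <- function(cells_orig, cells_pred, var_equal = FALSE) {
  pick <- function(x) {
    if (inherits(x, "presence_grid")) x <- x[x$presence == 1L, , drop = FALSE]
    stopifnot(all(c("lon", "lat") %in% names(x)))
    x
  }
  a <- pick(cells_orig); b <- pick(cells_pred)
  if (nrow(a) < 2L || nrow(b) < 2L) stop_invalid("each cell set needs >= 2 cells")
  one <- function(xa, xb) {
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      stop_invalid("zero variance in both samples: t undefined")
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }
  lat <- one(a$lat, b$lat); lon <- one(a$lon, b$lon)
  structure(
    list(t_lat = lat$t, t_lon = lon$t, df_lat = lat$df, df_lon = lon$df,
         p_lat = lat$p, p_lon = lon$p),
    class = "shift_test"
  )
}

#' Range-shift summary for one scenario
#'
#' Collates the occupied-cell count, percent change, centroid, displacement
#' and coordinate t-tests of a scenario presence grid against the baseline
#' grid into one summary row.
#'
#' @param pg_baseline,pg_scenario [presence_grid()]s.
#' @return One-row data frame mirroring the count/centroid/displacement
#'   summary-table columns.
#' @export
range_shift_summary <- function(pg_baseline, pg_scenario) {
  n0 <- count_cells(pg_baseline); n1 <- count_cells(pg_scenario)
  c0 <- centroid(pg_baseline); c1 <- centroid(pg_scenario)
  disp <- displacement(c0, c1)
  st <- coordinate_shift_test(pg_baseline, pg_scenario)
  data.frame(
    species = attr(pg_scenario, "species") %||% "species",
    scenario = attr(pg_scenario, "scenario_name") %||% "scenario",
    n_cells_orig = n0, n_cells = n1,
    pct_change = round(percent_change(n0, n1), 2),
    centroid_lon = c1$lon, centroid_lat = c1$lat,
    distance_km = disp$distance_km, bearing_deg = disp$bearing_deg,
    t_lat = st$t_lat, t_lon = st$t_lon,
    p_lat = st$p_lat, p_lon = st$p_lon,
    stringsAsFactors = FALSE
  )
}
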