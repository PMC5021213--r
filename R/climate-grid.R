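#' Climate grid container
#'
#' A climate grid is a data frame with one row per grid cell: a unique
#' `cell_id`, cell-centre coordinates `lon` and `lat` (WGS84 decimal degrees),
#' and one numeric column per climate variable. The scenario the grid belongs
#' to is carried as the `scenario_name` attribute (`"baseline"` for the
#' reference climate).
#'
#' @param cells data frame with columns `cell_id`, `lon`, `lat` and at least
#'   one numeric climate-variable column.
#' @param scenario_name text label of the climate scenario.
#' @return An object of class `climate_grid` (a validated data frame).
#' @export
climate_grid <- function(cells, scenario_name = "baseline") {
  stopifnot(is.data.frame(cells))
  need <- c("cell_id", "lon", "lat")
  if (!all(need %in% names(cells))) {
    stop_invalid("climate grid needs columns: ", paste(need, collapse = ", "))
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) stop_invalid("cell ids must be unique")
  vars <- setdiff(names(cells), need)
  if (length(vars) < 1L) stop_invalid("climate grid has no climate variables")
  for (v in vars) {
    if (!is.numeric(cells[[v]])) stop_invalid("variable '", v, "' is not numeric")
    if (any(!is.finite(cells[[v]]))) stop_invalid("variable '", v, "' has non-finite values")
  }
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scenario_name") <- as.character(scenario_name)
  class(out) <- c("climate_grid", "data.frame")
  out
}

#' Names of the climate variables held by a grid
#' @param grid a `climate_grid`.
#' @return character vector of variable names.
#' @export
climate_variables <- function(grid) {
  setdiff(names(grid), c("cell_id", "lon", "lat"))
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf(
    "<climate_grid> scenario '%s': %d cells, %d variables (%s)\n",
    attr(x, "scenario_name") %||% "?", nrow(x),
    length(climate_variables(x)), paste(climate_variables(x), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a climate grid as long-format CSV
#'
#' Long format: `scenario, cell_id, lon, lat, variable, value` — one row per
#' cell x variable, round-trippable with [read_climate_grid()].
#'
#' @param grid a `climate_grid`.
#' @param path file path of the CSV.
#' @return `path`, invisibly (writer); a `climate_grid` (reader).
#' @export
write_climate_grid <- function(grid, path) {
  vars <- climate_variables(grid)
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(
      scenario = attr(grid, "scenario_name") %||% "baseline",
      cell_id = grid$cell_id, lon = grid$lon, lat = grid$lat,
      variable = v, value = grid[[v]], stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_grid
#' @export
read_climate_grid <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  scen <- unique(long$scenario)
  if (length(scen) != 1L) stop_invalid("climate grid CSV must hold one scenario")
  wide <- stats::reshape(
    long[, c("cell_id", "lon", "lat", "variable", "value")],
    idvar = c("cell_id", "lon", "lat"), timevar = "variable", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  climate_grid(wide, scenario_name = scen)
}
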