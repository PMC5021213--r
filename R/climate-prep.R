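#' Reduce candidate climate variables by pairwise correlation
#'
#' Greedy scan in `candidate_order`: a variable is retained iff its absolute
#' Pearson correlation (across grid cells) with every already-retained
#' variable is at or below `threshold`. Which member of a correlated pair
#' survives is therefore decided by the caller-supplied priority order; given
#' the canonical ordering (the six variables the analysis retains first) the
#' canonical set comes out. Zero-variance candidates are excluded with a
#' warning since their correlation is undefined.
#'
#' @param grid a [climate_grid()] (correlations are computed on this —
#'   baseline — grid only).
#' @param candidate_order ordered character vector of variables to scan;
#'   default is every variable in grid-column order.
#' @param threshold absolute-correlation cutoff (default 0.70).
#' @return Character vector of retained variables, in input order.
#' @export
reduce_variables <- function(grid, candidate_order = climate_variables(grid),
                             threshold = 0.70) {
  stopifnot(inherits(grid, "climate_grid"))
  if (length(candidate_order) < 2L) stop_invalid("need >= 2 candidate variables")
  miss <- setdiff(candidate_order, climate_variables(grid))
  if (length(miss)) {
    stop_invalid("candidates not in grid: ", paste(miss, collapse = ", "))
  }
  retained <- character(0)
  for (v in candidate_order) {
    x <- grid[[v]]
    if (stats::sd(x) == 0) {
      warning("variable '", v, "' has zero variance; excluded", call. = FALSE)
      next
    }
    r <- vapply(retained, function(w) stats::cor(x, grid[[w]]), numeric(1))
    if (all(abs(r) <= threshold)) retained <- c(retained, v)
  }
  retained
}

#' Restrict a climate grid to a set of cells
#'
#' @param grid a [climate_grid()].
#' @param cell_mask nonempty set of cell ids defining the study region.
#' @return The grid restricted to the masked cells (variables untouched).
#' @export
clip_to_region <- function(grid, cell_mask) {
  stopifnot(inherits(grid, "climate_grid"))
  cell_mask <- as.character(cell_mask)
  if (length(cell_mask) == 0L) stop_invalid("cell mask is empty")
  keep <- grid$cell_id %in% cell_mask
  if (!any(keep)) stop_invalid("cell mask does not intersect the grid")
  climate_grid(as.data.frame(grid)[keep, , drop = FALSE],
               scenario_name = attr(grid, "scenario_name") %||% "baseline")
}
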