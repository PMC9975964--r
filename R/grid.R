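#' Define the study grid
#'
#' The analysis domain is a regular rectangular grid of square cells, indexed
#' row-major and 0-based with cell `(0, 0)` at the southwest corner. The
#' default cell area of 4.2 km^2 matches the resolution of the
#' chemical-transport model output the pipeline emulates.
#'
#' @param n_rows,n_cols Number of grid rows and columns (>= 1).
#' @param cell_area Cell area in km^2.
#' @param origin_lon,origin_lat Longitude/latitude (degrees) of the southwest
#'   cell centre. Defaults are a west-Indian urban domain; they only matter
#'   for serialized coordinates, not for any computation.
#' @param cell_size_deg Cell edge length in degrees, used to derive cell
#'   centre coordinates.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(4, 4)
#' @export
grid_spec <- function(n_rows = 32L, n_cols = 32L, cell_area = 4.2,
                      origin_lon = 72.4, origin_lat = 22.9,
                      cell_size_deg = 0.0185) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    abort("invalid grid: n_rows and n_cols must be >= 1", class = "aqhia_invalid_grid")
  }
  if (!is.numeric(cell_area) || cell_area <= 0) {
    abort("invalid grid: cell_area must be > 0", class = "aqhia_invalid_grid")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_area = cell_area,
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size_deg = cell_size_deg),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.1f km^2 each\n",
              x$n_rows, x$n_cols, x$cell_area))
  invisible(x)
}

#' All cell indices of a grid as a tibble
#'
#' @param grid A [grid_spec()].
#' @return A tibble with 0-based `row`, `col` and cell-centre `lon`, `lat`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- tidyr::expand_grid(row = 0:(grid$n_rows - 1L),
                              col = 0:(grid$n_cols - 1L))
  cells %>%
    mutate(lon = grid$origin_lon + .data$col * grid$cell_size_deg,
           lat = grid$origin_lat + .data$row * grid$cell_size_deg)
}

## Attach/recover the grid attribute on tabular fields. dplyr verbs can drop
## bespoke attributes, so every consumer goes through field_grid(), which
## falls back to inferring the extent from the indices.
set_grid <- function(df, grid) {
  attr(df, "grid") <- grid
  df
}

#' Retrieve the grid specification carried by a gridded tibble
#'
#' Falls back to inferring a grid from the maximum row/col index when the
#' attribute was dropped by an intermediate transformation.
#'
#' @param x A gridded tibble produced by the package.
#' @return A `grid_spec`.
#' @export
field_grid <- function(x) {
  g <- attr(x, "grid", exact = TRUE)
  if (inherits(g, "grid_spec")) return(g)
  if (!all(c("row", "col") %in% names(x))) {
    abort("cannot infer a grid: no row/col columns present")
  }
  grid_spec(max(x$row) + 1L, max(x$col) + 1L)
}

check_same_grid <- function(a, b) {
  ga <- field_grid(a); gb <- field_grid(b)
  if (ga$n_rows != gb$n_rows || ga$n_cols != gb$n_cols) {
    abort(sprintf("grid mismatch: %dx%d vs %dx%d",
                  ga$n_rows, ga$n_cols, gb$n_rows, gb$n_cols),
          class = "aqhia_grid_mismatch")
  }
  invisible(TRUE)
}

#' Write / read a gridded field in long CSV format
#'
#' Long format columns: `row`, `col`, `lon`, `lat`, `month` (absent for
#' annual surfaces), `value`.
#'
#' @param field A monthly concentration field or annual surface tibble.
#' @param path File path.
#' @return `write_field_csv()` returns `field` invisibly; `read_field_csv()`
#'   returns the field tibble with its grid attribute restored.
#' @export
write_field_csv <- function(field, path) {
  grid <- field_grid(field)
  out <- field %>%
    left_join(grid_cells(grid), by = c("row", "col")) %>%
    select(dplyr::any_of(c("row", "col", "lon", "lat", "month", "value")))
  readr::write_csv(out, path)
  invisible(field)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  keep <- intersect(c("row", "col", "month", "value"), names(df))
  df <- as_tibble(df[keep])
  set_grid(df, grid_spec(max(df$row) + 1L, max(df$col) + 1L))
}
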