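#' Read and write gridded climatology stacks as CSV
#'
#' Gridded fields travel as plain wide CSV (one row per cell x month, one
#' column per field); the grid specification is stored in a small JSON
#' sidecar (`<path>.grid.json`) and re-attached on read.
#'
#' @param stack A `clim_stack` / `predictor_stack`.
#' @param path CSV file path.
#' @return `write_stack_csv` returns `path` invisibly; `read_stack_csv`
#'   returns the stack.
#' @export
write_stack_csv <- function(stack, path) {
  readr::write_csv(as_tibble(stack), path)
  spec <- get_grid(stack)
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".grid.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_stack_csv
#' @param spec Optional [grid_spec()] when no sidecar exists.
#' @export
read_stack_csv <- function(path, spec = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".grid.json")
  if (is.null(spec) && file.exists(side)) {
    g <- jsonlite::read_json(side, simplifyVector = TRUE)
    spec <- grid_spec(g$lon_min, g$lon_max, g$lat_min, g$lat_max,
                      g$cell_size, g$months)
  }
  as_clim_stack(x, spec)
}

#' Read and write occurrence tables as CSV
#' @param occ An occurrence tibble with the standard column set.
#' @param path CSV file path.
#' @export
write_occurrences_csv <- function(occ, path) {
  check_occ_schema(occ)
  readr::write_csv(occ, path)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  check_occ_schema(occ)
  occ
}

#' Write a QC filter report as JSON
#' @param filtered An [filter_occurrences()] result.
#' @param path JSON file path.
#' @export
write_filter_report <- function(filtered, path) {
  stopifnot(inherits(filtered, "occ_filter"))
  jsonlite::write_json(
    list(removed = setNames(as.list(filtered$report$removed),
                            filtered$report$step),
         retained = filtered$n_retained),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
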