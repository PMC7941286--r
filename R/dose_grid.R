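#' @title Voxelized dose grids
#' @description Depth-integrated dose scores on a lateral (x) by vertical
#'   (y) voxel grid with per-voxel standard errors. Voxels are half-open
#'   bins; positions are bin centres in sample-plane coordinates.
#' @name dose_grid
NULL

#' Construct a dose grid
#'
#' @param x_mm ascending voxel-centre positions, horizontal, mm.
#' @param y_mm ascending voxel-centre positions, vertical, mm.
#' @param values matrix `length(x_mm) x length(y_mm)` of non-negative dose
#'   scores.
#' @param stderr matrix of per-voxel standard errors (same shape).
#' @param units character description of the value units.
#' @param meta list of provenance (seed, histories, configuration).
#' @export
dose_grid <- function(x_mm, y_mm, values, stderr = NULL,
                      units = "arbitrary", meta = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x_mm), ncol(values) == length(y_mm),
            !is.unsorted(x_mm), !is.unsorted(y_mm))
  if (any(values < 0)) stop("dose values must be non-negative")
  if (is.null(stderr)) stderr <- matrix(0, nrow(values), ncol(values))
  stderr <- as.matrix(stderr)
  stopifnot(all(dim(stderr) == dim(values)), all(stderr >= 0))
  structure(list(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 values = values, stderr = stderr, units = units,
                 meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d voxels, x: [%.3f, %.3f] mm, y: [%.3f, %.3f] mm\n",
              length(x$x_mm), length(x$y_mm), min(x$x_mm), max(x$x_mm),
              min(x$y_mm), max(x$y_mm)))
  cat(sprintf("  units: %s; max value: %.4g\n", x$units, max(x$values)))
  invisible(x)
}

#' Scoring-grid geometry
#'
#' @param x_pitch_um horizontal voxel pitch, micrometres (the
#'   microbeam-modulated, resolution-critical axis).
#' @param y_pitch_um vertical voxel pitch, micrometres.
#' @param x_half_mm half-extent of the scored field in x, mm.
#' @param y_half_mm half-extent in y, mm.
#' @export
grid_spec <- function(x_pitch_um = 5, y_pitch_um = 100,
                      x_half_mm = 4.6, y_half_mm = 8) {
  stopifnot(x_pitch_um > 0, y_pitch_um > 0, x_half_mm > 0, y_half_mm > 0)
  structure(list(x_pitch_um = x_pitch_um, y_pitch_um = y_pitch_um,
                 x_half_mm = x_half_mm, y_half_mm = y_half_mm),
            class = "grid_spec")
}

grid_axes <- function(gs) {
  px <- gs$x_pitch_um / 1000
  py <- gs$y_pitch_um / 1000
  nx <- 2 * round(gs$x_half_mm / px)
  ny <- 2 * round(gs$y_half_mm / py)
  list(x = (seq_len(nx) - (nx + 1) / 2) * px,
       y = (seq_len(ny) - (ny + 1) / 2) * py,
       px = px, py = py, nx = nx, ny = ny)
}

#' Serialize a dose grid as delimited text (x_mm, y_mm, dose, stderr)
#'
#' @param grid a [dose_grid()].
#' @param path output path; a JSON sidecar `<path>.json` records shape,
#'   pitch, units and provenance.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  df <- data.frame(x_mm = rep(grid$x_mm, times = length(grid$y_mm)),
                   y_mm = rep(grid$y_mm, each = length(grid$x_mm)),
                   dose = as.vector(grid$values),
                   stderr = as.vector(grid$stderr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_out <- grid$meta
  meta_out$batch_profiles <- NULL  # bulky run-time diagnostics
  jsonlite::write_json(
    list(nx = length(grid$x_mm), ny = length(grid$y_mm),
         units = grid$units, meta = meta_out),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Read a dose grid written by [write_dose_grid()]
#' @param path path to the delimited text file.
#' @export
read_dose_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  x <- sort(unique(df$x_mm))
  y <- sort(unique(df$y_mm))
  o <- order(df$y_mm, df$x_mm)
  meta <- list()
  units <- "arbitrary"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- side$meta
    if (!is.null(side$units)) units <- side$units
  }
  dose_grid(x, y, matrix(df$dose[o], length(x), length(y)),
            matrix(df$stderr[o], length(x), length(y)),
            units = units, meta = meta)
}
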