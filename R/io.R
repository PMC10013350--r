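#' Read an image stack from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @return List with one element per page: grayscale matrices or RGB
#'   arrays, values in `[0, 1]`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "woundfield_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Write an image stack to a multi-page TIFF
#'
#' Grayscale stacks are written 16-bit, RGB stacks 8-bit; either round-trips
#' bit-identically through [read_stack()] once quantised.
#'
#' @param stack List of matrices (grayscale) or `h x w x 3` arrays (RGB),
#'   values in `[0, 1]`.
#' @param path Output path.
#' @param bits_per_sample 16 for grayscale, 8 for RGB by default.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = NULL) {
  if (!is.list(stack) || length(stack) == 0) {
    abort("stack must be a non-empty list of frames",
          class = "woundfield_io_error")
  }
  is_rgb <- length(dim(stack[[1]])) == 3
  bps <- bits_per_sample %||% if (is_rgb) 8L else 16L
  q <- (2^bps - 1)
  stack <- lapply(stack, function(fr) round(pmin(pmax(fr, 0), 1) * q) / q)
  tiff::writeTIFF(stack, path, bits.per.sample = bps)
  invisible(path)
}

#' Write a single float map as a TIFF (for inspection)
#'
#' @param m Numeric matrix (any range; stored as 32-bit float).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(m, path) {
  stopifnot(is.matrix(m))
  tiff::writeTIFF(m, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a cell-track table
#'
#' Enforces the track CSV schema `frame:int, cell_id:int, x:float,
#' y:float` and validates that frames increase strictly within each track.
#'
#' @param path CSV file path.
#' @return Tibble with the four columns, typed.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "woundfield_io_error")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "cell_id", "x", "y")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0) {
    abort(sprintf("track table missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "woundfield_schema_error")
  }
  d <- tibble(frame = as.integer(d$frame), cell_id = as.integer(d$cell_id),
              x = as.numeric(d$x), y = as.numeric(d$y))
  if (anyNA(d)) {
    abort("track table contains non-numeric or missing values",
          class = "woundfield_schema_error")
  }
  # frames must increase strictly within each track, in file order
  ok <- vapply(split(d$frame, d$cell_id),
               function(f) length(f) < 2 || all(diff(f) > 0), logical(1))
  if (any(!ok)) {
    abort(sprintf("non-monotone frames within track(s): %s",
                  paste(names(ok)[!ok], collapse = ", ")),
          class = "woundfield_validation_error")
  }
  d
}

#' Write a cell-track table
#'
#' @param tracks Data frame with `frame`, `cell_id`, `x`, `y`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("frame", "cell_id", "x", "y") %in% names(tracks)))
  utils::write.csv(tracks[, c("frame", "cell_id", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a JSON analysis report
#'
#' @param report Named list of scalars/vectors/tibbles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
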