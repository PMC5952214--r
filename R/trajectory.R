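#' Construct a centroid trajectory series
#'
#' The common currency between simulation, imaging and entropy: a
#' time-ordered series of group-centroid positions, one row per frame, in
#' pixel coordinates of the 640 x 480 image (or z-scored units when
#' `normalized`).
#'
#' @param frame contiguous 1-based frame indices.
#' @param x,y centroid coordinates per frame.
#' @param source one of `"naive"`, `"kmeans"`, `"synthetic"`, `"file"`.
#' @param normalized logical; `TRUE` after [zscore()].
#' @return A tibble of class `trajectory_series` with attributes `source`
#'   and `normalized`.
#' @export
trajectory_series <- function(frame, x, y, source = "file",
                              normalized = FALSE) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  out <- tibble::tibble(frame = as.integer(frame), x = as.numeric(x),
                        y = as.numeric(y))
  attr(out, "source") <- source
  attr(out, "normalized") <- normalized
  class(out) <- c("trajectory_series", class(out))
  out
}

is_normalized <- function(series) isTRUE(attr(series, "normalized"))

#' Z-score normalize a trajectory
#'
#' Transforms each axis to `(v - mean(v)) / sd(v)` (sample sd). Raw and
#' normalized trajectories carry the same information for histogram entropy
#' with matched bin counts (the transform is monotone affine), so the default
#' pipeline analyzes raw pixel trajectories; normalization is available for
#' scale-free downstream use.
#'
#' @param series a [trajectory_series()].
#' @return The normalized series, `normalized` flag set.
#' @export
zscore <- function(series) {
  stopifnot(inherits(series, "trajectory_series"))
  sx <- stats::sd(series$x)
  sy <- stats::sd(series$y)
  if (!is.finite(sx) || sx < 1e-12) {
    stop("x axis has zero variance (degenerate frozen trajectory)",
         call. = FALSE)
  }
  if (!is.finite(sy) || sy < 1e-12) {
    stop("y axis has zero variance (degenerate frozen trajectory)",
         call. = FALSE)
  }
  trajectory_series(series$frame,
                    (series$x - mean(series$x)) / sx,
                    (series$y - mean(series$y)) / sy,
                    source = attr(series, "source"), normalized = TRUE)
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV has columns `frame, x, y`; the sidecar (`<path>.json`) records
#' `source`, `normalized` and any extra metadata (e.g. seed, k, threshold),
#' so every artifact is reproducible from inputs + config + seed.
#'
#' @param series a [trajectory_series()].
#' @param path CSV file path.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(series, path, meta = list()) {
  utils::write.csv(as.data.frame(series)[, c("frame", "x", "y")], path,
                   row.names = FALSE)
  side <- c(list(source = attr(series, "source"),
                 normalized = is_normalized(series)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame", "x", "y") %in% names(d)))
  side_path <- paste0(path, ".json")
  src <- "file"; norm <- FALSE
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$source)) src <- side$source
    if (!is.null(side$normalized)) norm <- isTRUE(side$normalized)
  }
  trajectory_series(d$frame, d$x, d$y, source = src, normalized = norm)
}
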