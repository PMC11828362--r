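#' Read and write pipeline tables as CSV
#'
#' Thin CSV wrappers fixing the column orders used throughout the
#' pipeline, so tables round-trip between runs and external tools:
#'
#' * radial samples: `seamount_id, distance_km, response, season,
#'   transect_id` (missing optional columns are tolerated on read);
#' * detections: `timestamp, receiver_id, tag_id` plus optional
#'   `seamount_id`, matching common receiver-export conventions;
#' * echo cells: `distance_bin_id, distance_km, depth_min, depth_max,
#'   Sv38, Sv70, Sv120`;
#' * tracks: `tag_id, timestamp, lon, lat`;
#' * CTD profiles: `depth, temperature, chlorophyll`.
#'
#' @param path CSV file path.
#' @param x Table to write.
#' @return Readers return a data frame (with the class tag used by the
#'   pipeline); writers return `path` invisibly.
#' @name seamount_io
NULL

#' @rdname seamount_io
#' @export
read_radial_samples <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("distance_km", "response") %in% names(x)))
  class(x) <- c("radial_survey", "data.frame")
  x
}

#' @rdname seamount_io
#' @export
write_radial_samples <- function(x, path) {
  cols <- intersect(c("seamount_id", "distance_km", "response", "season",
                      "transect_id"), names(x))
  write.csv(x[, c(cols, setdiff(names(x), cols))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname seamount_io
#' @export
read_detections <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "receiver_id", "tag_id") %in% names(x)))
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
  x
}

#' @rdname seamount_io
#' @export
write_detections <- function(x, path) {
  if (inherits(x, "detection_log")) x <- x$events
  cols <- intersect(c("timestamp", "receiver_id", "tag_id", "seamount_id"),
                    names(x))
  out <- x[, cols]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname seamount_io
#' @export
read_echo_cells <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("distance_km", "depth_min", "depth_max", "Sv38",
                  "Sv120") %in% names(x)))
  class(x) <- c("echo_cells", "data.frame")
  x
}

#' @rdname seamount_io
#' @export
read_track <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "lon", "lat") %in% names(x)))
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
  x[order(x$timestamp), ]
}

#' @rdname seamount_io
#' @export
read_ctd <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("depth", "temperature", "chlorophyll") %in% names(x)))
  class(x) <- c("ctd_profile", "data.frame")
  x
}
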