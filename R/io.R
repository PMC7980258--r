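# Plain-format I/O: trajectory and FLS record CSVs, FRAP trace CSVs,
# multi-page 16-bit TIFF stacks, and JSON ground-truth sidecars.

#' Write a trajectory set to CSV
#'
#' Long format, one row per (trajectory, time point):
#' `trajectory_id`, `t_min`, `length_um`, `velocity_um_per_min`.
#'
#' @param scene A trajectory-set scene from [gen_trajectory_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(scene, path) {
  stopifnot(scene$kind == "trajectory_set")
  n <- nrow(scene$lengths)
  df <- data.frame(
    trajectory_id = rep(seq_len(n), each = length(scene$times)),
    t_min = rep(scene$times, n),
    length_um = as.vector(t(scene$lengths)),
    velocity_um_per_min = as.vector(t(scene$velocities))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectories_csv()].
#' @return data.frame in the same long format.
#' @export
read_trajectories_csv <- function(path) utils::read.csv(path)

#' Read/write FLS record tables
#'
#' Standard snapshot-table format: `fov`, `structure_id`, `frame`,
#' `x_um`, `y_um`, `base_area_um2`, `length_um`, `straightness` plus one
#' `intensity_<channel>` column per channel.
#'
#' @param records FLS record data.frame.
#' @param path File path.
#' @return `read_fls_csv` the data.frame; `write_fls_csv` the path,
#'   invisibly.
#' @export
write_fls_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fls_csv
#' @export
read_fls_csv <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(fls_required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("not an FLS record table; missing: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read/write a FRAP trace CSV
#'
#' Columns `time_s`, `bleached_fls`, `unbleached_fls`, `bleached_bg`,
#' `unbleached_bg`.
#'
#' @param trace A [frap_trace()].
#' @param path File path.
#' @return `read_frap_csv` a `frap_trace`; `write_frap_csv` the path,
#'   invisibly.
#' @export
write_frap_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  do.call(frap_trace, df[c("time_s", "bleached_fls", "unbleached_fls",
                           "bleached_bg", "unbleached_bg")])
}

#' Write an image stack or movie as multi-page 16-bit grayscale TIFF
#'
#' Intensities are rescaled to the full 16-bit range.
#'
#' @param stack 3D array (rows x cols x planes/frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  rng <- range(stack)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(z)
    (stack[, , z] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF into a 3D array
#'
#' @param path TIFF path.
#' @return Array (rows x cols x pages), intensities as stored (0-1 for
#'   integer TIFFs).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  simplify2array(pages)
}

#' Write a ground-truth JSON sidecar for a synthetic scene
#'
#' @param scene A `synthetic_scene`.
#' @param path Output path (conventionally `<data>.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(scene, path) {
  gt <- scene$ground_truth
  gt$kind <- scene$kind
  gt$seed <- scene$seed
  keep <- !vapply(gt, is.function, logical(1))
  jsonlite::write_json(gt[keep], path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
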