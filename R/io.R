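## Artifact plumbing: 8-bit multi-page TIFF frames and CSV tables
## (ground truth, detections, tracks) with 6-decimal fixed-point coordinates.

#' Read and write video frames as multi-page TIFF
#'
#' Frames are stored as 8-bit grayscale, one page per frame; the round trip
#' is lossless.
#'
#' @param frames List of integer gray-level matrices (0-255), or a
#'   `casa_scene` (its frames are written).
#' @param path TIFF file path.
#' @return `write_video()`: `path`, invisibly.  `read_video()`: list of
#'   integer matrices.
#' @export
write_video <- function(frames, path) {
  if (inherits(frames, "casa_scene")) frames <- frames$frames
  if (!is.list(frames) || length(frames) == 0L) {
    abort("`frames` must be a non-empty list of gray-level matrices.")
  }
  tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_video
#' @export
read_video <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round_half_up(p * 255)
  })
}

write_table_6dp <- function(df, path, coord_cols) {
  out <- df
  for (cc in coord_cols) out[[cc]] <- sprintf("%.6f", df[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, required, numeric_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Malformed table '%s': missing column(s) %s.",
                  path, paste(missing, collapse = ", ")))
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0) {
      abort(sprintf("Malformed table '%s': non-numeric '%s' at data line %d.",
                    path, cc, bad[1]))
    }
    df[[cc]] <- v
  }
  tibble::as_tibble(df[required])
}

#' Read and write ground-truth tables
#'
#' CSV with header `frame,cell_id,x,y,mode`; coordinates are written with 6
#' decimal places.
#'
#' @param truth Ground-truth tibble (or a `casa_scene`).
#' @param path CSV file path.
#' @return `write_truth()`: `path`, invisibly.  `read_truth()`: tibble.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "casa_scene")) truth <- truth$truth
  write_table_6dp(truth[c("frame", "cell_id", "x", "y", "mode")], path,
                  c("x", "y"))
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_table_checked(path, c("frame", "cell_id", "x", "y", "mode"),
                     c("frame", "cell_id", "x", "y"))
}

#' Read and write detection tables
#'
#' CSV with header `frame,x,y,area`.
#'
#' @param detections Detection tibble.
#' @param path CSV file path.
#' @return `write_detections()`: `path`, invisibly.  `read_detections()`:
#'   tibble.
#' @export
write_detections <- function(detections, path) {
  write_table_6dp(detections[c("frame", "x", "y", "area")], path, c("x", "y"))
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  read_table_checked(path, c("frame", "x", "y", "area"),
                     c("frame", "x", "y", "area"))
}

#' Read and write track tables
#'
#' CSV with header `track_id,frame,x,y`.
#'
#' @param tracks Track tibble.
#' @param path CSV file path.
#' @return `write_tracks()`: `path`, invisibly.  `read_tracks()`: tibble.
#' @export
write_tracks <- function(tracks, path) {
  write_table_6dp(tracks[c("track_id", "frame", "x", "y")], path, c("x", "y"))
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read_table_checked(path, c("track_id", "frame", "x", "y"),
                     c("track_id", "frame", "x", "y"))
}
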