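# File I/O: 16-bit TIFF images and volumes, CSV record tables, JSON
# sidecars with the generating spec and seed.

#' Write a two-channel field as a 16-bit TIFF
#'
#' Channels become pages of a multi-page TIFF; intensities are stored on
#' the 16-bit scale. A JSON sidecar (`<path>.json`) records the
#' generating spec and seed when one is supplied.
#'
#' @param image H x W x 2 numeric array on the 0..65535 scale.
#' @param path output TIFF path.
#' @param spec optional `puncta_field_spec` for the sidecar.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path, spec = NULL) {
  pages <- lapply(seq_len(dim(image)[3]),
                  function(ch) image[, , ch] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(spec)) write_spec_sidecar(spec, path)
  invisible(path)
}

#' Read a field TIFF written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @return H x W x n numeric array on the 0..65535 scale.
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (ch in seq_along(pages)) {
    p <- pages[[ch]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , ch] <- round(p * 65535)
  }
  arr
}

#' Write a labeled volume as a multi-page 16-bit TIFF plus label map
#'
#' Each z-slice becomes one TIFF page with integer labels on the 16-bit
#' scale; the label map (synapse id to pre/post component labels and
#' type) is written as JSON next to the volume.
#'
#' @param volume integer array (x, y, z) of component labels.
#' @param label_map data.frame `id`, `type`, `pre_label`, `post_label`.
#' @param path output TIFF path; the label map goes to `<path>.labels.json`.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, label_map, path) {
  if (max(volume) > 65535L)
    stopf("labels exceed the 16-bit range; write fewer objects per volume")
  pages <- lapply(seq_len(dim(volume)[3]),
                  function(z) t(volume[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(label_map, paste0(path, ".labels.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Read a labeled volume written by [write_volume_tiff()]
#'
#' @param path TIFF path.
#' @return list with `volume` (integer array x, y, z) and `label_map`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vol <- array(0L, dim = c(d[2], d[1], length(pages)))
  for (z in seq_along(pages))
    vol[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  lm_path <- paste0(path, ".labels.json")
  label_map <- if (file.exists(lm_path))
    jsonlite::fromJSON(lm_path) else NULL
  list(volume = vol, label_map = label_map)
}

write_spec_sidecar <- function(spec, path) {
  jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write punctum records to CSV
#'
#' One row per punctum with the documented column order: `channel`, `x`,
#' `y`, `n_pixels`, `mean_intensity`, `size`, `skewness`, `kurtosis`,
#' `circularity`, `aspect_ratio`. The mask list-column is dropped.
#'
#' @param records punctum record data.frame (a `channel` column is added
#'   when absent).
#' @param path output CSV.
#' @param channel channel id used when `records` lacks the column.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(records, path, channel = 1L) {
  if (!"channel" %in% names(records)) records$channel <- channel
  cols <- c("channel", "x", "y", "n_pixels", "mean_intensity", "size",
            "skewness", "kurtosis", "circularity", "aspect_ratio")
  cols <- cols[cols %in% names(records)]
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
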