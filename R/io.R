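#' Read an ultrasound cine clip from disk
#'
#' Supported inputs: a multi-page TIFF stack, or a directory of equally sized
#' PNG frames (sorted by filename). Physical calibration is mandatory and is
#' never guessed: a YAML sidecar must accompany the stack (same path with
#' `.yaml`/`.yml` extension for a TIFF, `sidecar.yaml` inside a frame
#' directory) and provide `spacing_cm` (lateral, depth cm per pixel) and
#' `frame_period_s`.
#'
#' @param path path to a `.tif`/`.tiff` stack or a directory of `.png`
#'   frames.
#' @return A [cine_clip()] with frames on a common [0, 1] intensity scale.
#' @export
read_cine <- function(path) {
  if (dir.exists(path)) {
    sidecar <- file.path(path, "sidecar.yaml")
    if (!file.exists(sidecar)) sidecar <- file.path(path, "sidecar.yml")
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2) stop("frame directory must hold at least 2 PNG frames")
    frames <- lapply(seq_along(files), function(i) {
      fr <- tryCatch(png::readPNG(files[i]),
                     error = function(e) stop(sprintf(
                       "corrupt frame %d (%s): %s", i, basename(files[i]),
                       conditionMessage(e)), call. = FALSE))
      if (length(dim(fr)) == 3) fr <- fr[, , 1] # grayscale written as RGB
      fr
    })
  } else {
    if (!file.exists(path)) stop("input path does not exist: ", path)
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop("unsupported cine format (expected multi-page TIFF or PNG directory): ",
           path)
    sidecar <- sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE)
    if (!file.exists(sidecar)) sidecar <- sub("\\.yaml$", ".yml", sidecar)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  }
  if (!file.exists(sidecar))
    stop("missing spacing metadata: no YAML sidecar found for ", path,
         " (physical calibration is never guessed)")
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$spacing_cm))
    stop("missing spacing metadata: sidecar lacks `spacing_cm`")
  if (is.null(meta$frame_period_s))
    stop("missing frame period: sidecar lacks `frame_period_s`")
  cine_clip(frames, spacing = as.numeric(meta$spacing_cm),
            frame_period = as.numeric(meta$frame_period_s),
            id = meta$id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a cine clip as a TIFF stack with YAML sidecar
#'
#' @param clip a [cine_clip()].
#' @param path output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cine <- function(clip, path) {
  stopifnot(inherits(clip, "cine_clip"))
  tiff::writeTIFF(clip$frames, path, bits.per.sample = 32L) # float, lossless
  yaml::write_yaml(
    list(id = clip$id, spacing_cm = clip$spacing,
         frame_period_s = clip$frame_period),
    sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE)
  )
  invisible(path)
}

#' Read / write diaphragm contour annotations (JSON)
#'
#' Contours are stored in physical cm coordinates (never pixels, so
#' annotations survive resampling) as a JSON array of objects
#' `{frame_index, points: [[x_cm, y_cm], ...], extrapolated: [bool, ...],
#' spacing_cm: [dx, dy]}`.
#'
#' @param path JSON file path.
#' @param contours list of [dia_contour()] objects.
#' @return `read_contours`: a list of `dia_contour`; `write_contours`:
#'   `path`, invisibly.
#' @export
read_contours <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    pts <- do.call(rbind, lapply(r$points, function(p)
      as.numeric(unlist(p))))
    dia_contour(pts, frame_index = r$frame_index,
                spacing = as.numeric(unlist(r$spacing_cm %||% c(0.05, 0.05))),
                extrapolated = if (is.null(r$extrapolated)) NULL else
                  as.logical(unlist(r$extrapolated)))
  })
}

#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  out <- lapply(contours, function(ct) list(
    frame_index = ct$frame_index,
    points = ct$points,
    extrapolated = ct$extrapolated,
    spacing_cm = ct$spacing
  ))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write the paired study table (CSV)
#'
#' Columns: `subject_id`, `breath_id`, `method`, `value`, `units`,
#' `volume_l`. Every physical quantity carries its unit (`units` column,
#' `_l` suffix); unit-less measurement columns are never written.
#'
#' @param table study table data.frame.
#' @param path CSV path.
#' @return `read_study_table`: the data.frame; `write_study_table`: `path`,
#'   invisibly.
#' @export
read_study_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "breath_id", "method", "value", "units", "volume_l")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("study table lacks required columns: ", paste(miss, collapse = ", "))
  if (any(tab$volume_l < 0)) stop("expired volumes must be non-negative")
  if (anyDuplicated(tab[c("subject_id", "breath_id", "method")]))
    stop("duplicate (subject, breath, method) records")
  tab
}

#' @rdname read_study_table
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# Measurement results CSV: one row per clip and method.
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

# Run manifest: records the seed and configuration of every run so outputs
# are reproducible byte-for-byte.
write_manifest <- function(path, ...) {
  yaml::write_yaml(list(...), path)
  invisible(path)
}
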