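#' Read a multi-frame grayscale TIFF stack
#'
#' Loads an image stack into a `movie_stack` (frame x row x column array of
#' non-negative intensities). Acquisition metadata is never inferred from
#' TIFF tags: the frame rate comes from a JSON sidecar written by
#' [write_stack()] (same path plus `.json`), or from the `frame_rate_hz`
#' argument.
#'
#' @param path Path to a multi-frame grayscale TIFF.
#' @param frame_rate_hz Frame rate in Hz; overrides (and is required in the
#'   absence of) the sidecar.
#' @return A `movie_stack` object with fields `frames` (3-D array),
#'   `frame_rate_hz` and `frame_count`.
#' @export
read_stack <- function(path, frame_rate_hz = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("format error: single-frame TIFF (", length(pages),
         " page); a movie stack needs >= 2 frames")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("format error: non-grayscale TIFF (multi-channel pages found)")
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(frame_rate_hz))
    stop("frame rate unknown: no sidecar ", basename(sidecar),
         " and no frame_rate_hz given")
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), nr, nc))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  movie_stack(frames, frame_rate_hz)
}

#' Construct a movie stack from an array
#'
#' @param frames 3-D numeric array (frame x row x column) of finite,
#'   non-negative intensities in arbitrary camera units.
#' @param frame_rate_hz Positive frame rate in Hz.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(frames, frame_rate_hz = 5) {
  if (length(dim(frames)) != 3L)
    stop("frames must be a 3-D array (frame x row x column)")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive")
  structure(list(frames = frames, frame_rate_hz = as.numeric(frame_rate_hz),
                 frame_count = dim(frames)[1]),
            class = "movie_stack")
}

#' Write a movie stack as a multi-frame grayscale TIFF
#'
#' Integer-valued stacks up to 65535 counts (the native range of a 16-bit
#' EMCCD readout) are stored losslessly at 16 bits per sample. Other stacks
#' are stored at 32 bits with a scale factor recorded in the sidecar, exact
#' to about 2^-32 of the full intensity range. The sidecar JSON
#' (`<path>.json`) carries the frame rate and the intensity scale.
#'
#' @param stack A `movie_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  fr <- stack$frames
  integral <- all(fr == round(fr)) && max(fr) <= 65535
  if (integral) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(fr, 1e-12)
    bits <- 32L
  }
  pages <- lapply(seq_len(stack$frame_count),
                  function(i) fr[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(frame_rate_hz = stack$frame_rate_hz,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Region-of-interest mask
#'
#' A labelled 2-D boolean mask matching the spatial shape of the stack it
#' is applied to -- typically one mask drawn around each antenna.
#'
#' @param mask Logical matrix; `TRUE` pixels belong to the ROI.
#' @param label ROI label (fly/antenna identifier).
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(mask, label = "roi1") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask has no TRUE pixel")
  structure(list(label = as.character(label), mask = mask),
            class = "roi_mask")
}

#' Read ROI definitions from a label TIFF or a polygon JSON
#'
#' Two interchangeable on-disk forms are accepted; the pixel mask is
#' canonical. A label image encodes ROI k as pixels with integer value k. A
#' polygon JSON is a list of objects `{label, x, y}` with vertex
#' coordinates in pixel units (1-based, x = column, y = row); pixels whose
#' centers fall inside (or on) the polygon belong to the ROI.
#'
#' @param path Path to `.tif`/`.tiff` (label image) or `.json` (polygons).
#' @param shape For polygon input, the `c(rows, cols)` spatial shape of the
#'   stack the masks will be applied to.
#' @return A list of `roi_mask` objects.
#' @export
read_rois <- function(path, shape = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) stop("label image must be single-plane grayscale")
    labels <- sort(unique(as.vector(img)))
    labels <- labels[labels > 0]
    if (!length(labels)) stop("label image contains no ROI (no pixel > 0)")
    lapply(labels, function(k) roi_mask(img == k, label = paste0("roi", k)))
  } else if (ext == "json") {
    if (is.null(shape)) stop("polygon ROIs need the target stack shape")
    polys <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(polys)) polys <- split(polys, seq_len(nrow(polys)))
    lapply(polys, function(p) {
      px <- unlist(p$x); py <- unlist(p$y)
      grid <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
      inside <- pracma::inpolygon(grid$col, grid$row, px, py,
                                  boundary = TRUE)
      roi_mask(matrix(inside, shape[1], shape[2]),
               label = as.character(p$label))
    })
  } else stop("unsupported ROI format: .", ext)
}

#' Extract the per-frame mean-fluorescence trace of one ROI
#'
#' For every frame, averages the intensities of the pixels inside the ROI,
#' yielding the raw trace that all downstream quantification operates on.
#'
#' @param stack A `movie_stack`.
#' @param roi A `roi_mask` whose shape matches the stack's spatial shape.
#' @param ... Recording metadata forwarded to [recording()] (stimulus
#'   identity, windows, dose, flags). `fly_id` defaults to the ROI label.
#' @return A `tci_recording`.
#' @export
extract_trace <- function(stack, roi, ...) {
  stopifnot(inherits(stack, "movie_stack"), inherits(roi, "roi_mask"))
  sp <- dim(stack$frames)[2:3]
  if (!identical(dim(roi$mask), as.integer(sp)) &&
      !identical(dim(roi$mask), sp))
    stop("ROI shape (", paste(dim(roi$mask), collapse = "x"),
         ") does not match stack (", paste(sp, collapse = "x"), ")")
  idx <- which(roi$mask)
  npx <- length(idx)
  flat <- matrix(stack$frames, nrow = stack$frame_count)
  trace <- rowSums(flat[, idx, drop = FALSE]) / npx
  args <- list(...)
  if (is.null(args$fly_id)) args$fly_id <- roi$label
  do.call(recording, c(list(trace = trace,
                            frame_rate_hz = stack$frame_rate_hz), args))
}

#' Write recordings as a long-format trace CSV plus a metadata CSV
#'
#' The trace table has one row per (recording, frame):
#' `recording_id, frame, F`. The metadata table has one row per recording:
#' `recording_id, fly_id, stimulus_id, dose_ug, is_solvent, is_blank,
#' repeat_index, frame_rate_hz, stimulus_onset_frame,
#' stimulus_offset_frame`.
#'
#' @param recordings List of `tci_recording`.
#' @param traces_path Output CSV for traces.
#' @param meta_path Output CSV for metadata; defaults to
#'   `<traces_path minus .csv>_meta.csv`.
#' @return Invisible list with both paths.
#' @export
write_traces <- function(recordings, traces_path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.csv$", "", traces_path), "_meta.csv")
  traces <- do.call(rbind, lapply(recordings, function(r)
    data.frame(recording_id = r$recording_id,
               frame = seq_len(r$frame_count),
               F = r$trace)))
  meta <- do.call(rbind, lapply(recordings, function(r)
    data.frame(recording_id = r$recording_id, fly_id = r$fly_id,
               stimulus_id = r$stimulus_id, dose_ug = r$dose_ug,
               is_solvent = r$is_solvent, is_blank = r$is_blank,
               repeat_index = r$repeat_index,
               frame_rate_hz = r$frame_rate_hz,
               stimulus_onset_frame = r$stimulus_onset_frame,
               stimulus_offset_frame = r$stimulus_offset_frame)))
  utils::write.csv(traces, traces_path, row.names = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(list(traces = traces_path, meta = meta_path))
}

#' Read recordings from a long-format trace CSV plus a metadata CSV
#'
#' Inverse of [write_traces()]. Validates that each recording's frame
#' indices are contiguous `1..frame_count` with no duplicates, naming the
#' offending recording and frame otherwise.
#'
#' @param traces_path Trace CSV (`recording_id, frame, F`).
#' @param meta_path Metadata CSV; same default naming as [write_traces()].
#' @return A list of `tci_recording`.
#' @export
read_traces <- function(traces_path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.csv$", "", traces_path), "_meta.csv")
  traces <- utils::read.csv(traces_path)
  meta <- utils::read.csv(meta_path)
  need <- c("recording_id", "frame", "F")
  if (!all(need %in% names(traces)))
    stop("trace table must have columns ", paste(need, collapse = ", "))
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    tr <- traces[traces$recording_id == m$recording_id, ]
    if (!nrow(tr)) stop("no trace rows for recording ", m$recording_id)
    if (anyDuplicated(tr$frame)) {
      dup <- tr$frame[duplicated(tr$frame)][1]
      stop("duplicate frame ", dup, " in recording ", m$recording_id)
    }
    tr <- tr[order(tr$frame), ]
    expected <- seq_len(max(tr$frame))
    miss <- setdiff(expected, tr$frame)
    if (length(miss))
      stop("recording ", m$recording_id, " is missing frame ", miss[1])
    recording(trace = tr$F, frame_rate_hz = m$frame_rate_hz,
              stimulus_onset_frame = m$stimulus_onset_frame,
              stimulus_offset_frame = m$stimulus_offset_frame,
              stimulus_id = as.character(m$stimulus_id),
              dose_ug = m$dose_ug, is_solvent = isTRUE(m$is_solvent),
              is_blank = isTRUE(m$is_blank), fly_id = m$fly_id,
              recording_id = m$recording_id,
              repeat_index = m$repeat_index)
  })
  names(recs) <- meta$recording_id
  recs
}
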