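#' Write and read kick fixtures
#'
#' A fixture is a directory holding a ground-truth trajectory
#' (`truth.csv`, columns `frame,time_s,hip_x,hip_y,knee_x,knee_y,ankle_x,
#' ankle_y,contact,deflection_mm`), the rendered frames (`frames.tif`
#' multi-page float TIFF or `frames.nii.gz` NIfTI, by `backend`), and a
#' `meta.json` sidecar preserving pixel size, frame interval, image origin
#' and the generating scenario.  The round trip is lossless to floating
#' precision for the trajectory and to 32-bit float for the frames.
#'
#' @param truth A `kick_truth` trajectory.
#' @param sequence An `image_sequence`.
#' @param path Directory to create/write into.
#' @param backend `"tiff"` or `"nifti"` frame storage.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(truth, sequence, path, backend = c("tiff", "nifti")) {
  backend <- match.arg(backend)
  stopifnot(inherits(truth, "kick_truth"), inherits(sequence, "image_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) fk_config_error(sprintf("cannot create fixture directory %s", path))

  tr <- as.data.frame(truth)
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], function(v) sprintf("%.17g", v))
  utils::write.csv(tr, file.path(path, "truth.csv"), row.names = FALSE, quote = FALSE)

  if (backend == "tiff") {
    ## TIFF stores [0, 1]; rescale with factors preserved in the sidecar
    rng <- range(unlist(lapply(sequence$frames, range)))
    span <- max(rng[2] - rng[1], 1e-12)
    tiff::writeTIFF(lapply(sequence$frames, function(f) (f - rng[1]) / span),
                    file.path(path, "frames.tif"),
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
    tiff_scale <- list(offset = rng[1], span = span)
  } else {
    tiff_scale <- NULL
    arr <- simplify2array(sequence$frames)  # ny x nx x n
    storage.mode(arr) <- "double"
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::writeNifti(img, file.path(path, "frames.nii.gz"))
  }

  sc <- attr(truth, "scenario")
  meta <- list(tiff_scale = tiff_scale,
               pixel_size = sequence$pixel_size,
               frame_interval = sequence$frame_interval,
               origin = sequence$origin,
               backend = backend,
               scenario = if (!is.null(sc)) unclass(sc) else NULL)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixture
#' @return `read_fixture`: list with elements `truth` and `sequence`.
#' @export
read_fixture <- function(path) {
  meta_path <- file.path(path, "meta.json")
  csv_path <- file.path(path, "truth.csv")
  if (!file.exists(meta_path)) fk_parse_error(sprintf("missing meta.json in %s", path))
  if (!file.exists(csv_path)) fk_parse_error(sprintf("missing truth.csv in %s", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("pixel_size", "frame_interval", "origin", "backend"))
    if (is.null(meta[[f]])) fk_parse_error(sprintf("meta.json missing field '%s'", f))

  tr <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  cols <- c("frame", "time_s", "hip_x", "hip_y", "knee_x", "knee_y",
            "ankle_x", "ankle_y", "contact", "deflection_mm")
  miss <- setdiff(cols, names(tr))
  if (length(miss))
    fk_parse_error(sprintf("truth.csv missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyNA(tr[setdiff(cols, "contact")]))
    fk_parse_error("truth.csv contains missing or non-numeric values")
  tr$contact <- as.logical(tr$contact)

  frames <- if (meta$backend == "tiff") {
    f <- tiff::readTIFF(file.path(path, "frames.tif"), all = TRUE)
    if (!is.list(f)) f <- list(f)
    lapply(f, function(fr) fr * meta$tiff_scale$span + meta$tiff_scale$offset)
  } else {
    arr <- RNifti::readNifti(file.path(path, "frames.nii.gz"))
    arr <- as.array(arr)
    lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  }
  if (length(frames) != nrow(tr))
    fk_parse_error(sprintf("frame count (%d) does not match truth rows (%d)",
                           length(frames), nrow(tr)))

  sc <- meta$scenario
  if (!is.null(sc)) {
    sc <- lapply(sc, function(v) if (is.list(v)) unlist(v) else v)
    class(sc) <- "kick_scenario"
    attr(tr, "scenario") <- sc
  }
  class(tr) <- c("kick_truth", "data.frame")
  seq_out <- structure(list(frames = frames, pixel_size = meta$pixel_size,
                            frame_interval = meta$frame_interval,
                            origin = as.numeric(meta$origin)),
                       class = "image_sequence")
  list(truth = tr, sequence = seq_out)
}
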