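# File-format glue: multi-page TIFF stacks with sidecar metadata CSV,
# surface/biometry CSV serialization.

#' Write a B-scan stack as multi-page TIFF with sidecar metadata
#'
#' Intensities are stored as 32-bit float TIFF pages scaled to [0, 1]; the
#' common scale factor and per-frame metadata (index, timestamp, phase,
#' pitches) go to the sidecar CSV so the stack round-trips exactly.
#'
#' @param frames list of [BScanImage-class].
#' @param tiffPath output TIFF path.
#' @param metaPath sidecar CSV path; default replaces the extension.
#' @return Invisibly, \code{c(tiffPath, metaPath)}.
#' @export
writeBScanStack <- function(frames, tiffPath,
                            metaPath = sub("\\.tiff?$", "_meta.csv", tiffPath)) {
  stopifnot(length(frames) >= 1)
  scale <- max(vapply(frames, function(f) max(imageData(f)), numeric(1)), 1e-12)
  pages <- lapply(frames, function(f) imageData(f) / scale)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32, reduce = FALSE)
  meta <- data.frame(frame = seq_along(frames),
                     time = vapply(frames, frameTime, numeric(1)),
                     phase = vapply(frames, framePhase, character(1)),
                     axialPitch = vapply(frames, axialPitch, numeric(1)),
                     lateralPitch = vapply(frames, lateralPitch, numeric(1)),
                     intensityScale = scale)
  utils::write.csv(meta, metaPath, row.names = FALSE)
  invisible(c(tiffPath, metaPath))
}

#' Read a B-scan stack written by [writeBScanStack()]
#'
#' @param tiffPath TIFF path.
#' @param metaPath sidecar CSV path.
#' @return list of [BScanImage-class].
#' @export
readBScanStack <- function(tiffPath,
                           metaPath = sub("\\.tiff?$", "_meta.csv", tiffPath)) {
  if (!file.exists(tiffPath)) stop("TIFF stack not found: ", tiffPath)
  if (!file.exists(metaPath)) stop("metadata CSV not found: ", metaPath)
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  if (nrow(meta) != length(pages))
    stop("metadata rows (", nrow(meta), ") do not match TIFF pages (",
         length(pages), ")")
  lapply(seq_along(pages), function(i) {
    img <- pages[[i]]
    if (length(dim(img)) == 3) img <- img[, , 1]
    new("BScanImage", image = img * meta$intensityScale[i],
        axialPitch = meta$axialPitch[i], lateralPitch = meta$lateralPitch[i],
        timestamp = meta$time[i], phase = meta$phase[i])
  })
}

#' Serialize / read surface traces as CSV (label, x, z)
#'
#' @param surfaces a [SurfaceSet-class] or [CorrectedSurfaceSet-class].
#' @param path CSV path.
#' @return [writeSurfaceSet()] invisibly returns \code{path};
#'   [readSurfaceSet()] returns a data.frame (label, x, z), usable as
#'   segmentation seeds.
#' @export
writeSurfaceSet <- function(surfaces, path) {
  utils::write.csv(surfaceTraces(surfaces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurfaceSet
#' @export
readSurfaceSet <- function(path) {
  if (!file.exists(path)) stop("surface CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "z") %in% names(df)))
  df
}
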