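#' Read an image volume or mask
#'
#' Reads a 3-D volume from NIfTI (\code{.nii}/\code{.nii.gz}), a multi-page or
#' per-slice TIFF stack, or a PNG slice directory, and normalizes it to the
#' internal (z, y, x) axis order. Voxel spacing is taken from the NIfTI header
#' (default 1 x 1 x 1 mm when absent). TIFF/PNG intensities are stored
#' normalized to [0, 1] on disk and rescaled to the nominal 0--255 gray range
#' on read.
#'
#' @param path file (NIfTI, multi-page TIFF) or directory (per-slice TIFF/PNG
#'   stack, slices sorted by file name).
#' @param format one of \code{"nifti"}, \code{"tiff_stack"}, \code{"png_stack"};
#'   \code{"auto"} guesses from the extension. \code{"dicom_series"} is
#'   recognized but not supported (no DICOM reader is available).
#' @param mask if TRUE the result is binarized (value > 0 -> 1) and returned
#'   as a [BinaryMask-class].
#' @return a [VolumeImage-class] or [BinaryMask-class]
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(VolumeImage(array(0, c(4, 8, 8))), f)
#' readVolume(f)
#' @export
readVolume <- function(path, format = c("auto", "nifti", "tiff_stack",
                                        "png_stack", "dicom_series"),
                       mask = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file or directory not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guessFormat(path)
  vol <- switch(format,
    nifti = .readNiftiVolume(path),
    tiff_stack = .readTiffStack(path),
    png_stack = .readPngStack(path),
    dicom_series = stop("DICOM series reading is not supported in this build;",
                        " convert the series to NIfTI first", call. = FALSE))
  if (mask) asBinaryMask(vol) else vol
}

#' Write an image volume
#'
#' NIfTI round-trips data and spacing exactly. TIFF (multi-page, or per-slice
#' with zero-padded slice indices when \code{path} is an existing directory or
#' carries no extension) and PNG slices store intensities scaled by 1/255 into
#' [0, 1]; values outside [0, 255] are clipped on write.
#'
#' @param vol a [VolumeImage-class] or [BinaryMask-class]
#' @param path output file (or directory for per-slice stacks)
#' @param format \code{"auto"}, \code{"nifti"}, \code{"tiff_stack"} or
#'   \code{"png_stack"}
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(vol, path, format = c("auto", "nifti", "tiff_stack",
                                              "png_stack")) {
  stopifnot(is(vol, "VolumeImage"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    nifti = .writeNiftiVolume(vol, path),
    tiff_stack = .writeTiffStack(vol, path),
    png_stack = .writePngStack(vol, path))
  invisible(path)
}

.guessFormat <- function(path) {
  if (dir.exists(path)) {
    if (length(list.files(path, pattern = "\\.png$", ignore.case = TRUE)))
      return("png_stack")
    return("tiff_stack")
  }
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(tif|tiff)$", low)) return("tiff_stack")
  if (grepl("\\.png$", low)) return("png_stack")
  if (grepl("\\.(dcm|ima)$", low)) return("dicom_series")
  "nifti"
}

# internal (z, y, x) <-> NIfTI (x, y, z)
.readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  .stopIfNot3D(a, "NIfTI content")
  pd <- RNifti::pixdim(img)
  spacing <- if (length(pd) >= 3 && all(is.finite(pd[1:3])) && all(pd[1:3] > 0))
    rev(pd[1:3]) else c(1, 1, 1)
  VolumeImage(aperm(a, c(3L, 2L, 1L)), spacing)
}

.writeNiftiVolume <- function(vol, path) {
  a <- aperm(vol@data, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rev(vol@spacing)
  RNifti::writeNifti(img, path, datatype = "double")
}

.readTiffStack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices in ", path, call. = FALSE)
    slices <- lapply(files, function(f) tiff::readTIFF(f))
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  .stackSlices(slices)
}

.writeTiffStack <- function(vol, path) {
  slices <- .sliceList(vol)
  if (dir.exists(path) || !grepl("\\.tiff?$", tolower(path))) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    n <- length(slices)
    width <- max(3L, nchar(as.character(n)))
    for (z in seq_len(n)) {
      f <- file.path(path, sprintf(paste0("slice_%0", width, "d.tif"), z))
      tiff::writeTIFF(slices[[z]], f, bits.per.sample = 32)
    }
  } else {
    tiff::writeTIFF(slices, path, bits.per.sample = 32)
  }
}

.readPngStack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no PNG slices in ", path, call. = FALSE)
    slices <- lapply(files, function(f) {
      s <- png::readPNG(f)
      if (length(dim(s)) == 3L) s <- s[, , 1]   # collapse gray-encoded RGB
      s
    })
  } else {
    s <- png::readPNG(path)
    if (length(dim(s)) == 3L) s <- s[, , 1]
    slices <- list(s)
  }
  .stackSlices(slices)
}

.writePngStack <- function(vol, path) {
  slices <- .sliceList(vol)
  if (length(slices) == 1L && grepl("\\.png$", tolower(path))) {
    png::writePNG(slices[[1]], path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    width <- max(3L, nchar(as.character(length(slices))))
    for (z in seq_along(slices))
      png::writePNG(slices[[z]],
                    file.path(path, sprintf(paste0("slice_%0", width, "d.png"), z)))
  }
}

# slices normalized to [0,1] on disk; nominal range 0-255 in memory
.sliceList <- function(vol) {
  d <- dim(vol@data)
  lapply(seq_len(d[1]), function(z)
    pmin(pmax(vol@data[z, , , drop = TRUE] / 255, 0), 1))
}

.stackSlices <- function(slices) {
  d2 <- dim(slices[[1]])
  for (s in slices)
    if (!all(dim(s) == d2))
      stop("inconsistent slice geometry in stack", call. = FALSE)
  a <- array(0, c(length(slices), d2))
  for (z in seq_along(slices)) a[z, , ] <- slices[[z]] * 255
  VolumeImage(a)
}

#' Export a slice as a PNG figure
#'
#' Intensities are min-max scaled to the display range.
#'
#' @param vol a [VolumeImage-class]
#' @param z slice index (1-based)
#' @param path output PNG path
#' @return \code{path}, invisibly
#' @export
exportSlicePNG <- function(vol, z, path) {
  s <- vol@data[z, , , drop = TRUE]
  rng <- range(s)
  s <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s * 0
  png::writePNG(s, path)
  invisible(path)
}
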