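#' Construct a CBCT volume object
#'
#' A `cbct_volume` is a 3D scalar grid indexed `(x, y, z)` where `z` is the
#' axial slice index (increasing from mandible to maxilla), together with the
#' physical voxel spacing in millimetres and the physical coordinate of voxel
#' `(0, 0, 0)`. Voxel indices are 0-based throughout the geometric code:
#' physical position = `origin + index * spacing`.
#'
#' @param data numeric 3D array, all values finite, each dimension >= 2.
#' @param spacing numeric length-3, mm per voxel along x, y, z; all > 0.
#' @param origin numeric length-3, mm position of voxel (0,0,0).
#' @return an object of class `cbct_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
cbct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("all three volume dimensions must be >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(data)) - 1L
    stop(sprintf("non-finite intensity at voxel (%d, %d, %d)",
                 idx[1L], idx[2L], idx[3L]))
  }
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "cbct_volume")
}

#' @export
print.cbct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cbct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a 2D image object
#'
#' @param data numeric matrix indexed `(x, y)`; finite values.
#' @param spacing mm per pixel (length 2, recycled from length 1).
#' @param provenance free-text tag: `"mip"`, `"section"`, `"panoramic"`, ...
#' @return object of class `cbct_image`.
#' @export
cbct_image <- function(data, spacing = c(1, 1), provenance = "image") {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (any(dim(data) < 1L)) stop("image dimensions must be >= 1")
  if (any(!is.finite(data))) stop("image contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  structure(list(data = data, spacing = spacing, provenance = provenance),
            class = "cbct_image")
}

#' @export
print.cbct_image <- function(x, ...) {
  cat(sprintf("<cbct_image:%s> %d x %d px, range [%.4g, %.4g]\n",
              x$provenance, nrow(x$data), ncol(x$data),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Load a CBCT volume from disk
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, read with RNifti) and raw
#' binary with a YAML sidecar (`<path>.yaml` or a `sidecar` argument) holding
#' `dims`, `dtype` (one of `float32`, `float64`, `int16`, `uint16`, `uint8`)
#' and `spacing_mm`. DICOM series are not supported and raise an error.
#'
#' @param path file path.
#' @param format_hint optional, one of `"nifti"`, `"raw"`, `"dicom_dir"`;
#'   guessed from the file extension when missing.
#' @param sidecar optional path to the YAML sidecar for raw volumes.
#' @return a [cbct_volume].
#' @export
load_volume <- function(path, format_hint = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
           else if (dir.exists(path)) "dicom_dir" else "raw"
  }
  fmt <- match.arg(fmt, c("nifti", "raw", "dicom_dir"))
  if (fmt == "dicom_dir")
    stop("DICOM series input is not supported; convert to NIfTI first ",
         "(e.g. with dcm2niix) or supply raw binary + YAML sidecar")
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[seq_len(3L)]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("NIfTI file carries no usable voxel spacing: ", path)
    if (abs(sp[1] - sp[2]) > 1e-6 * max(sp))
      warning("anisotropic axial in-plane spacing: ",
              paste(signif(sp, 4), collapse = " x "))
    arr <- array(as.numeric(img), dim = dim(img)[seq_len(3L)])
    return(cbct_volume(arr, spacing = sp))
  }
  ## raw + sidecar
  if (is.null(sidecar)) sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("raw volume needs a YAML sidecar with dims/dtype/spacing_mm: ",
         sidecar, " not found")
  meta <- yaml::read_yaml(sidecar)
  need <- c("dims", "dtype", "spacing_mm")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sidecar missing fields: ", paste(miss, collapse = ", "))
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(path, "rb"); on.exit(close(con))
  raw_read <- switch(meta$dtype,
    float32 = readBin(con, "numeric",  n, size = 4),
    float64 = readBin(con, "numeric",  n, size = 8),
    int16   = readBin(con, "integer",  n, size = 2, signed = TRUE),
    uint16  = readBin(con, "integer",  n, size = 2, signed = FALSE),
    uint8   = as.integer(readBin(con, "raw", n)),
    stop("unsupported dtype: ", meta$dtype))
  if (length(raw_read) != n)
    stop("raw file holds ", length(raw_read), " values, expected ", n)
  cbct_volume(array(as.numeric(raw_read), dim = dims),
              spacing = as.numeric(meta$spacing_mm))
}

#' Write a CBCT volume to NIfTI
#'
#' @param vol a [cbct_volume].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cbct_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Axial maximum-intensity projection
#'
#' Projects the volume along the axial (z) axis, keeping the maximum gray
#' value along each vertical ray. Because enamel is the densest tissue in the
#' head, teeth dominate this projection, which is what makes the arch-curve
#' segmentation possible.
#'
#' @param vol a [cbct_volume].
#' @param z_band optional length-2 fractions `(z_min, z_max)` in `[0, 1]`
#'   restricting the projection to an axial sub-band; default full range.
#' @return a [cbct_image] with provenance `"mip"`.
#' @export
mip_axial <- function(vol, z_band = NULL) {
  stopifnot(inherits(vol, "cbct_volume"))
  nz <- dim(vol$data)[3L]
  zi <- seq_len(nz)
  if (!is.null(z_band)) {
    stopifnot(length(z_band) == 2L, z_band[1] < z_band[2])
    lo <- max(1L, 1L + floor(z_band[1] * (nz - 1L)))
    hi <- min(nz, 1L + ceiling(z_band[2] * (nz - 1L)))
    zi <- lo:hi
  }
  m <- apply(vol$data[, , zi, drop = FALSE], c(1L, 2L), max)
  cbct_image(m, spacing = vol$spacing[1:2], provenance = "mip")
}

#' Window an image for display
#'
#' Linearly maps `[level - width/2, level + width/2]` onto `[0, 1]`, clipping
#' outside. Display-only: pipeline math always runs on raw gray values.
#'
#' @param img a [cbct_image].
#' @param width window width, intensity units; > 0.
#' @param level window level (centre), intensity units.
#' @return windowed [cbct_image] with values in `[0, 1]`.
#' @export
apply_window <- function(img, width, level) {
  stopifnot(inherits(img, "cbct_image"), width > 0)
  v <- (img$data - (level - width / 2)) / width
  v[v < 0] <- 0
  v[v > 1] <- 1
  cbct_image(v, spacing = img$spacing, provenance = img$provenance)
}

#' Save a 2D image as PNG (8-bit) or TIFF (16-bit)
#'
#' Intensities are rescaled linearly from `[min, max]` of the image to the
#' full integer range; the rescale parameters are recorded in a JSON sidecar
#' (`<path>.json`) so original values are recoverable. 16-bit is the default
#' elsewhere in the pipeline because enamel/dentine/pulp contrast does not
#' survive 8-bit quantisation.
#'
#' @param img a [cbct_image].
#' @param path output path (`.png` for 8-bit, `.tif`/`.tiff` for 16-bit).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bit_depth = 16) {
  stopifnot(inherits(img, "cbct_image"), bit_depth %in% c(8, 16))
  lo <- min(img$data); hi <- max(img$data)
  scaled <- if (hi > lo) (img$data - lo) / (hi - lo) else img$data * 0
  ## data is (x, y); raster writers want rows = y
  m <- t(scaled)
  if (bit_depth == 8) {
    png::writePNG(m, target = path)
  } else {
    tiff::writeTIFF(m, where = path, bits.per.sample = 16L)
  }
  jsonlite::write_json(
    list(min = lo, max = hi, bit_depth = bit_depth,
         width = nrow(img$data), height = ncol(img$data),
         provenance = img$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an image written by [save_image]
#'
#' Uses the JSON sidecar to undo the rescale, recovering original intensities
#' up to quantisation.
#'
#' @param path path previously given to [save_image].
#' @return a [cbct_image].
#' @export
load_image <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing rescale sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- if (meta$bit_depth == 8) png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  v <- t(m) * (meta$max - meta$min) + meta$min
  cbct_image(v, provenance = meta$provenance)
}
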