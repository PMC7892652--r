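# NIfTI-1 volume I/O, sinogram files and YAML experiment configs.
#
# Volumes are written axis-aligned (identity rotation) with the grid spacing
# in pixdim and the physical position of the first voxel centre as the
# qform/sform offset; the affine is right-handed with +x/+y/+z along the
# array axes.

#' Write a volume as NIfTI-1
#'
#' @param x An `image_volume`, `binary_mask`, `attenuation_map`,
#'   `activity_volume` or `label_volume`. Masks and label volumes are stored
#'   with an integer datatype; attenuation maps carry their `method_tag` in
#'   the header `descrip` field.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  data <- switch(class(x)[1],
                 image_volume = x$data,
                 binary_mask = array(as.integer(x$values), dim = dim(x$values)),
                 attenuation_map = x$mu,
                 activity_volume = x$activity,
                 label_volume = x$labels,
                 stop("unsupported type"))
  grid <- x$grid
  datatype <- if (is.integer(data)) "int16" else "float32"
  img <- RNifti::asNifti(data)
  m <- diag(4)
  m[1:3, 4] <- grid$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::pixdim(img) <- grid$spacing
  meta <- list()
  if (inherits(x, "attenuation_map")) meta$descrip <- x$method_tag
  if (!is.null(x$units)) meta$intent_name <- substr(x$units, 1, 15)
  if (length(meta)) img <- RNifti::asNifti(img, reference = meta)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads an axis-aligned volume written by [write_volume()] (or any NIfTI
#' whose rotation is the identity): spacing from pixdim, origin from the
#' affine offset.
#'
#' @param path File path.
#' @return An `image_volume` (with attribute `"descrip"` if the header
#'   carries one).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D volume")
  xf <- RNifti::xform(img)
  grid <- voxel_grid(d, RNifti::pixdim(img)[1:3], xf[1:3, 4])
  out <- image_volume(array(as.numeric(img), dim = d), grid)
  descrip <- RNifti::niftiHeader(img)$descrip
  if (!is.null(descrip) && nzchar(descrip)) attr(out, "descrip") <- descrip
  out
}

#' Read a NIfTI volume as an attenuation map
#'
#' @param path File path.
#' @param method_tag Override for the method tag; default uses the header
#'   `descrip` field.
#' @return An `attenuation_map`.
#' @export
read_attenuation_map <- function(path, method_tag = NULL) {
  v <- read_volume(path)
  tag <- method_tag %||% attr(v, "descrip") %||% "CT_AC"
  attenuation_map(v$data, v$grid, tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a sinogram
#'
#' The values go into a NIfTI volume (bins x angles x slices); the
#' projection geometry goes into a JSON sidecar next to it.
#'
#' @param sino A `sinogram`.
#' @param path Output path for the values (`.nii`); the sidecar gets the
#'   same name with `.json` appended.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  img <- RNifti::asNifti(sino$values, datatype = "float64")
  RNifti::writeNifti(img, path)
  geom <- list(n_bins = sino$n_bins, n_angles = sino$n_angles,
               n_slices = sino$n_slices, bin_spacing = sino$bin_spacing)
  jsonlite::write_json(geom, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  vals <- RNifti::readNifti(path)
  geom <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = array(as.numeric(vals), dim = dim(vals)),
                 n_angles = geom$n_angles, n_bins = geom$n_bins,
                 n_slices = geom$n_slices, bin_spacing = geom$bin_spacing),
            class = "sinogram")
}
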