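#' Binary lumen voxel mask
#'
#' A CT-like 3-D binary image of the airway lumen: a logical array indexed
#' `[x, y, z]` (x fastest) with voxel spacing and origin in mm.  World
#' coordinates refer to voxel centres: `world = origin + (index - 1) * spacing`.
#'
#' @param data Logical 3-D array.
#' @param spacing_mm Positive length-3 voxel spacing (mm). The default CT
#'   geometry is 0.8 mm in-plane with a 1 mm axial step.
#' @param origin_mm World coordinate of the centre of voxel `[1, 1, 1]`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, spacing_mm = c(0.8, 0.8, 1.0),
                       origin_mm = c(0, 0, 0)) {
  stopifnot(is.logical(data), length(dim(data)) == 3,
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(origin_mm) == 3)
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing_mm), collapse = " x "),
              sum(x$data)))
  invisible(x)
}

#' Euclidean distance transform of a mask
#'
#' Exact distance (mm) from each foreground voxel centre to the nearest
#' background voxel centre; background voxels get 0.  Twice its value at
#' the centreline estimates the local lumen diameter.
#'
#' @param mask A [voxel_mask()].
#' @return A numeric array with the mask's dimensions.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- cpp_edt(as.logical(mask$data), dim(mask$data), mask$spacing_mm)
  array(d, dim(mask$data))
}

#' Write / read a mask as NIfTI
#'
#' Spacing is stored in the header `pixdim`, the origin in the affine.
#'
#' @param mask A [voxel_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the
#'   [voxel_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- array(as.integer(mask$data), dim(mask$data))
  affine <- diag(c(mask$spacing_mm, 1))
  affine[1:3, 4] <- mask$origin_mm
  img <- RNifti::asNifti(arr, datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_mask(array(as.vector(img) != 0, dim(img)),
             spacing_mm = abs(diag(aff)[1:3]),
             origin_mm = aff[1:3, 4])
}

# Voxel-centre world coordinates along one axis.
axis_coords <- function(mask, axis) {
  mask$origin_mm[axis] + (seq_len(dim(mask$data)[axis]) - 1) * mask$spacing_mm[axis]
}

#' Generate a cylindrical tube phantom mask
#'
#' A straight circular cylinder rasterized with the voxel-centre-inside
#' rule and padded with at least two voxels of background: the digital
#' analog of the plastic-tubing phantoms (20, 12, 7 and 3 mm) used to
#' validate segmentation accuracy.
#'
#' @param diameter_mm Tube lumen diameter (must be at least twice the
#'   largest voxel dimension to be resolvable).
#' @param length_mm Tube length (> diameter).
#' @param voxel_mm Voxel spacing, scalar or length 3 (default 0.4 mm
#'   isotropic).
#' @param axis Tube axis direction (need not be unit length).
#' @param pad_voxels Background padding on every side (>= 2).
#' @return A [voxel_mask()].
#' @export
generate_tube_phantom <- function(diameter_mm, length_mm = 60,
                                  voxel_mm = c(0.4, 0.4, 0.4),
                                  axis = c(0, 0, 1), pad_voxels = 2L) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (diameter_mm < 2 * max(voxel_mm))
    stop(sprintf("diameter %.2f mm is below the resolvable limit (2 voxels = %.2f mm)",
                 diameter_mm, 2 * max(voxel_mm)), call. = FALSE)
  stopifnot(length_mm > diameter_mm, pad_voxels >= 2)
  ax <- unitv(axis)
  r <- diameter_mm / 2
  p0 <- c(0, 0, 0)
  p1 <- ax * length_mm

  lo <- pmin(p0, p1) - r - pad_voxels * voxel_mm
  hi <- pmax(p0, p1) + r + pad_voxels * voxel_mm
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / voxel_mm)) + 1L)
  origin <- lo

  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel_mm[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel_mm[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * voxel_mm[3]
  px <- rep(xs, times = dims[2] * dims[3])
  py <- rep(rep(ys, each = dims[1]), times = dims[3])
  pz <- rep(zs, each = dims[1] * dims[2])

  wx <- px - p0[1]; wy <- py - p0[2]; wz <- pz - p0[3]
  t <- wx * ax[1] + wy * ax[2] + wz * ax[3]
  dx <- wx - t * ax[1]; dy <- wy - t * ax[2]; dz <- wz - t * ax[3]
  inside <- (t >= 0) & (t <= length_mm) & (dx^2 + dy^2 + dz^2 <= r^2)

  voxel_mask(array(inside, dims), spacing_mm = voxel_mm, origin_mm = origin)
}
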