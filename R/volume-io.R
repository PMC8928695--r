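# NIfTI I/O, grid compatibility and the shared smoothing primitive.

#' Test whether two volumes live on the same grid
#'
#' Two volumes are grid-compatible when their array dimensions match and
#' their voxel spacings and voxel-to-world affines agree within \code{tol}.
#' Every pairwise operation in the package requires this.
#'
#' @param a,b \linkS4class{VolumeGrid}s.
#' @param tol absolute tolerance on spacing and affine entries.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@affine - b@affine)) <= tol
}

# internal: error out on mismatched grids
stopIfGridMismatch <- function(..., tol = 1e-6) {
  vols <- list(...)
  for (v in vols[-1])
    if (!sameGrid(vols[[1]], v, tol = tol))
      stop("volumes do not share one grid (shape/spacing/affine mismatch)")
  invisible(TRUE)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \linkS4class{VolumeGrid}; data promoted to double, spacing and
#'   affine taken from the header.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  VolumeGrid(array(as.numeric(img), d),
             spacing = RNifti::pixdim(img)[1:3], affine = aff)
}

#' Write a VolumeGrid as NIfTI-1
#'
#' @param v a \linkS4class{VolumeGrid}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param datatype NIfTI datatype; binary masks are typically written as
#'   \code{"uint8"}, everything else as \code{"double"}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path, datatype = "double") {
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  img <- RNifti::`qform<-`(img, structure(v@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Isotropic Gaussian smoothing with FWHM in mm
#'
#' Separable Gaussian convolution used to bring attenuation maps to PET
#' resolution (5 mm FWHM by convention). The kernel is normalized to unit
#' mass; at the array boundary the truncated kernel is renormalized
#' (normalized convolution), so constant fields are preserved exactly
#' while interior mass is conserved. Head volumes are surrounded by air
#' (value 0 in attenuation maps), so the boundary treatment is
#' inconsequential in practice. \code{fwhmMm = 0} is the identity.
#'
#' @param v a \linkS4class{VolumeGrid}.
#' @param fwhmMm full width at half maximum of the kernel, in mm; >= 0.
#' @return Smoothed \linkS4class{VolumeGrid}.
#' @export
gaussianSmooth <- function(v, fwhmMm) {
  if (!is.finite(fwhmMm) || fwhmMm < 0)
    stop("fwhmMm must be a nonnegative finite number")
  if (fwhmMm == 0) return(v)
  sigmaMm <- fwhmMm / (2 * sqrt(2 * log(2)))
  out <- v@data
  for (ax in 1:3) {
    sigmaVox <- sigmaMm / v@spacing[ax]
    r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
    w <- dnorm(seq(-r, r), sd = sigmaVox)
    w <- w / sum(w)
    out <- convolveAxis(out, w, ax)
  }
  withData(v, out)
}

# internal: 1-D convolution along one axis via band-matrix product; rows of
# the band matrix are renormalized where the kernel is truncated
convolveAxis <- function(arr, w, axis) {
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (k in seq_along(w)) {
    off <- k - r - 1L          # out[i] += w[k] * in[i + off]
    idx <- seq_len(n)
    keep <- idx + off >= 1L & idx + off <= n
    K[cbind(idx[keep], idx[keep] + off)] <- w[k]
  }
  K <- K / rowSums(K)
  res <- K %*% matrix(a, nrow = n)
  dim(res) <- d
  aperm(res, order(perm))
}
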