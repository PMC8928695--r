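# Template method: a cuboid mask defined in canonical (MNI-like) space,
# pulled back to subject space through an inverse deformation field.

#' TemplateCuboid: a cuboid mask in canonical space
#'
#' @slot canonicalGrid \linkS4class{VolumeGrid} giving the template grid
#'   (its data array is ignored; spacing/affine/shape define the space).
#' @slot bounds \linkS4class{CuboidRegion} in template voxel coordinates.
#' @export
setClass("TemplateCuboid",
         representation(canonicalGrid = "VolumeGrid",
                        bounds = "CuboidRegion"))

setValidity("TemplateCuboid", function(object) {
  if (any(object@bounds@hi > dim(object@canonicalGrid@data)))
    return("bounds exceed the canonical grid")
  TRUE
})

#' Construct a TemplateCuboid
#' @param canonicalGrid \linkS4class{VolumeGrid} defining template space.
#' @param bounds \linkS4class{CuboidRegion} in template voxel coordinates.
#' @return A \linkS4class{TemplateCuboid}.
#' @export
TemplateCuboid <- function(canonicalGrid, bounds)
  new("TemplateCuboid", canonicalGrid = canonicalGrid, bounds = bounds)

setMethod("show", "TemplateCuboid", function(object) {
  cat("TemplateCuboid in canonical space:\n  ")
  show(object@bounds)
})

#' Pull a template cuboid back to subject space
#'
#' For each voxel of the target grid, its world coordinates plus the
#' displacement stored in the inverse field give a point in template
#' space; the template mask value there is taken by nearest-neighbour
#' lookup (crisp binary output, no fractional membership). The result need
#' not be a cuboid: the field can tilt and morph it arbitrarily. A zero
#' field on an identical grid reproduces the rasterized cuboid exactly.
#'
#' @param template a \linkS4class{TemplateCuboid}.
#' @param invField \linkS4class{DeformationField} on the target grid,
#'   displacements in world mm (pull-back convention).
#' @param targetGrid \linkS4class{VolumeGrid} supplying the subject grid.
#' @return Binary \linkS4class{VolumeGrid} on the target grid.
#' @export
warpMask <- function(template, invField, targetGrid) {
  stopIfGridMismatch(invField@ux, targetGrid)
  d <- dim(targetGrid@data)
  sp <- targetGrid@spacing
  # world coordinates of target voxels (grid-aligned affines assumed; the
  # phantom and the supported NIfTI volumes use diagonal affines)
  wx <- array(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d)
  wy <- array(rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]),
                  times = d[3]), d)
  wz <- array(rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]), d)
  tx <- wx + invField@ux@data
  ty <- wy + invField@uy@data
  tz <- wz + invField@uz@data
  # nearest template voxel
  tsp <- template@canonicalGrid@spacing
  td <- dim(template@canonicalGrid@data)
  vi <- round(tx / tsp[1]) + 1
  vj <- round(ty / tsp[2]) + 1
  vk <- round(tz / tsp[3]) + 1
  b <- template@bounds
  inside <- vi >= b@lo[1] & vi <= b@hi[1] &
    vj >= b@lo[2] & vj <= b@hi[2] &
    vk >= b@lo[3] & vk <= b@hi[3] &
    vi >= 1 & vi <= td[1] & vj >= 1 & vj <= td[2] & vk >= 1 & vk <= td[3]
  maskVolume(targetGrid, inside)
}

#' Default template cuboid for a phantom cohort
#'
#' For phantom work the canonical cuboid is the phantom spec's canonical
#' sinus compartment (the cohort mean of the per-subject jittered boxes).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{TemplateCuboid}.
#' @export
phantomTemplateCuboid <- function(spec) {
  grid <- VolumeGrid(array(0, spec@shape), spacing = rep(spec@spacingMm, 3))
  TemplateCuboid(grid, canonicalSinusBox(spec))
}
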