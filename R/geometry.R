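#' Physical distance to a mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest
#' voxel centre of `mask`, computed with a separable distance transform
#' that accounts for anisotropic spacing. Zero inside the mask.
#'
#' @param mask logical 3D array.
#' @param grid the [ImageGrid-class] supplying the spacing.
#' @return numeric 3D array of distances in mm.
#' @export
maskDistance <- function(mask, grid) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(gridValues(grid))))
    .edt3d(mask, gridSpacing(grid))
}

#' Expand a mask by a physical margin
#'
#' Returns the set of voxels whose Euclidean distance (mm) to the input
#' mask is at most `marginMm`, together with the mask itself — the uniform
#' expansion used to grow an ITV into a PTV. The margin is physical, so
#' anisotropic slices expand by the same number of millimetres, not voxels.
#'
#' @param mask logical 3D array, non-empty.
#' @param marginMm non-negative margin in mm.
#' @param grid the reference [ImageGrid-class].
#' @return logical 3D array, a superset of `mask`.
#' @examples
#' g <- imageGrid(array(0, c(9, 9, 9)), c(1, 1, 1), "HU")
#' m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
#' sum(expandMask(m, 2, g))  # 33 voxels: integer offsets with |x|^2 <= 4
#' @export
expandMask <- function(mask, marginMm, grid) {
    if (!any(mask)) stop("cannot expand an empty mask")
    if (marginMm < 0) stop("marginMm must be >= 0")
    if (marginMm == 0) return(mask)
    d <- maskDistance(mask, grid)
    d <= marginMm + 1e-9 | mask
}

#' Shell structure outside a target
#'
#' The shell of physical thickness `thicknessMm` immediately outside
#' `ptvMask`, clipped to the body contour: voxels within the thickness of
#' the PTV, excluding the PTV itself, intersected with `bodyMask`. For
#' peripheral targets the part of the shell falling outside the patient is
#' discarded, so shell volumes shrink near the body surface.
#'
#' @param ptvMask logical 3D array, non-empty.
#' @param thicknessMm shell thickness in mm, > 0.
#' @param bodyMask logical 3D array clipping the shell.
#' @param grid the reference [ImageGrid-class].
#' @return logical 3D array, disjoint from `ptvMask`.
#' @export
shellMask <- function(ptvMask, thicknessMm, bodyMask, grid) {
    if (!any(ptvMask)) stop("cannot build a shell around an empty mask")
    if (thicknessMm <= 0) stop("thicknessMm must be > 0")
    expandMask(ptvMask, thicknessMm, grid) & !ptvMask & bodyMask
}

#' Voxelwise set difference of two masks
#'
#' `a & !b`; used for the PTV margin structure (PTV minus GTV).
#'
#' @param a,b logical 3D arrays on the same grid.
#' @return logical 3D array.
#' @export
maskDifference <- function(a, b) {
    stopifnot(identical(dim(a), dim(b)))
    a & !b
}

#' Minimum distance from a target to soft tissue
#'
#' The minimum distance (mm) from the GTV to the nearest soft-tissue voxel,
#' the quantitative stand-in for the central-vs-peripheral location label:
#' an island tumour fully surrounded by lung has a large `dminGtv`, one
#' abutting the chest wall or mediastinum has 0. GTV voxels are removed
#' from the soft-tissue set first, so a dense tumour does not trivially
#' yield zero. Because distances are measured between voxel centres, any
#' face-, edge- or corner-contact (centre distance within one voxel
#' diagonal) is reported as 0 mm abutment.
#'
#' @param gtvMask,softTissueMask logical 3D arrays, non-empty.
#' @param grid the reference [ImageGrid-class].
#' @return distance in mm (0 for abutment).
#' @export
dminGtv <- function(gtvMask, softTissueMask, grid) {
    if (!any(gtvMask)) stop("empty GTV mask")
    soft <- softTissueMask & !gtvMask
    if (!any(soft))
        stop("soft-tissue mask is empty after excluding the GTV; ",
             "dmin is undefined")
    d <- maskDistance(gtvMask, grid)
    dstar <- min(d[soft])
    if (dstar <= sqrt(sum(gridSpacing(grid)^2)) + 1e-9) 0 else dstar
}

# Surface voxels of a mask: in-mask voxels with at least one 6-neighbour
# outside the mask (grid edges count as outside).
.surfaceVoxels <- function(mask) {
    d <- dim(mask)
    interior <- array(TRUE, d)
    shift <- function(m, axis, by) {
        out <- array(FALSE, d)
        idx <- lapply(d, seq_len)
        src <- idx; dst <- idx
        n <- d[axis]
        if (by > 0) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
        else        { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
        out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
        out
    }
    for (ax in 1:3) for (by in c(-1, 1))
        interior <- interior & shift(mask, ax, by)
    mask & !interior
}

#' Maximum dimension of a structure
#'
#' The caliper diameter: the maximum pairwise Euclidean distance (mm)
#' between voxel centres of the mask. Computed on surface voxels only,
#' which leaves the maximum unchanged.
#'
#' @param mask logical 3D array, non-empty.
#' @param grid the reference [ImageGrid-class].
#' @return distance in mm (0 for a single voxel).
#' @export
maxDiameter <- function(mask, grid) {
    if (!any(mask)) stop("empty mask")
    surf <- .surfaceVoxels(mask)
    idx <- which(surf, arr.ind = TRUE)
    sp <- gridSpacing(grid)
    pts <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2],
                 (idx[, 3] - 1) * sp[3])
    .maxPairDist(pts)
}

#' Structure volume in cubic centimetres
#'
#' Voxel count times physical voxel volume, in cm^3.
#'
#' @param mask logical 3D array.
#' @param grid the reference [ImageGrid-class].
#' @return volume in cm^3.
#' @export
volumeCm3 <- function(mask, grid) {
    sum(mask) * prod(gridSpacing(grid)) / 1000
}
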