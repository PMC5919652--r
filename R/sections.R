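#' Cut a binary volume into a histology-like section stack
#'
#' Resamples a voxel mask into an ordered stack of binary sections of the
#' given thickness along the cutting axis (coronal by default, the third
#' grid axis). Each section takes the voxel plane containing its center.
#' A partial terminal section is included iff its residual extent is at
#' least half the thickness (symmetric rounding).
#'
#' @param mask logical 3D array.
#' @param thickness section thickness, \eqn{\mu m}.
#' @param voxelSize voxel edge lengths of the mask grid, mm.
#' @param axis cutting axis (1, 2 or 3; default 3).
#' @return A [SectionStack-class].
#' @examples
#' m <- array(TRUE, c(4, 4, 6))
#' length(sections(sliceSections(m, 500, c(0.25, 0.25, 0.5))))  # 6 planes
#' @export
sliceSections <- function(mask, thickness, voxelSize, axis = 3L) {
    if (!is.array(mask) || length(dim(mask)) != 3 || !is.logical(mask))
        stop("mask must be a logical 3D array")
    if (!is.numeric(thickness) || thickness <= 0)
        stop("section thickness must be positive")
    stopifnot(length(voxelSize) == 3, all(voxelSize > 0), axis %in% 1:3)
    if (axis != 3L) {
        perm <- switch(axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2))
        mask <- aperm(mask, perm)
        voxelSize <- voxelSize[perm]
    }
    dims <- dim(mask)
    voxUm <- voxelSize[3] * 1000
    extent <- dims[3] * voxUm
    nFull <- floor(extent / thickness)
    rem <- extent - nFull * thickness
    n <- nFull + as.integer(rem >= thickness / 2)
    if (n < 1) stop("section thickness exceeds the volume extent")
    centers <- (seq_len(n) - 0.5) * thickness
    planes <- pmin(floor(centers / voxUm) + 1, dims[3])
    secs <- lapply(planes, function(p) mask[, , p])
    new("SectionStack", sections = secs, pixelSize = voxelSize[1:2],
        thickness = thickness, spacing = thickness)
}

#' Section stack accessors
#'
#' @param stack a [SectionStack-class].
#' @return \code{sections}: the list of binary section matrices;
#'   \code{sectionPixelSize}: in-plane pixel size (mm);
#'   \code{sectionThickness}: thickness t (\eqn{\mu m}).
#' @export
sections <- function(stack) {
    stopifnot(is(stack, "SectionStack"))
    stack@sections
}

#' @rdname sections
#' @export
sectionPixelSize <- function(stack) {
    stopifnot(is(stack, "SectionStack"))
    stack@pixelSize
}

#' @rdname sections
#' @export
sectionThickness <- function(stack) {
    stopifnot(is(stack, "SectionStack"))
    stack@thickness
}

#' Exact raster area of a binary section
#'
#' @param section logical matrix.
#' @param pixelSize in-plane pixel size, mm.
#' @return Foreground area in mm^2 (pixel count times pixel area).
#' @export
sectionArea <- function(section, pixelSize) {
    stopifnot(is.logical(section), length(pixelSize) == 2,
              all(pixelSize > 0))
    sum(section) * prod(pixelSize)
}

#' @describeIn SectionStack-class compact display
#' @param object a SectionStack
#' @export
setMethod("show", "SectionStack", function(object) {
    cat(sprintf(
        "SectionStack: %d sections of %s px (%s mm/px), t = %s um, spacing %s um\n",
        length(object@sections),
        paste(dim(object@sections[[1]]), collapse = "x"),
        paste(format(object@pixelSize), collapse = "x"),
        format(object@thickness), format(object@spacing)))
})
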