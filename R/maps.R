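#' Fit MD and MKT parametric maps from a 19-volume series
#'
#' Applies the closed-form 1-9-9 estimators voxelwise (vectorized; voxels
#' are independent). Voxels outside the mask carry NA and the OUTSIDE_MASK
#' flag; degenerate voxels inside the mask are flagged, never dropped, and
#' no input raises an exception.
#'
#' @param series a [DkiSeries-class], or a 4D array (x, y, z, 19) in scheme
#'   order (b = 0 volume first).
#' @param scheme an [AcquisitionScheme-class]; taken from \code{series} when
#'   it is a DkiSeries.
#' @param mask logical array of voxels to fit (default: all).
#' @param config a [dkiConfig()].
#' @param voxelSize voxel size in mm for array input.
#' @return A list with [ParametricMap-class] elements \code{md}
#'   (\eqn{\mu m^2/ms}) and \code{mkt} (dimensionless).
#' @examples
#' truth <- generatePhantom(phantomSpec())
#' series <- simulateAcquisition(truth, make199Scheme(1, 2.5), snr = Inf)
#' maps <- fitMaps(series, mask = phantomMasks(truth)$brain)
#' @export
fitMaps <- function(series, scheme = NULL, mask = NULL,
                    config = dkiConfig(), voxelSize = NULL) {
    if (is(series, "DkiSeries")) {
        scheme <- series@scheme
        voxelSize <- series@voxelSize
        data <- series@data
    } else {
        if (is.null(scheme))
            stop("scheme is required for array input")
        if (is.null(voxelSize)) voxelSize <- c(1, 1, 1)
        data <- series
    }
    stopifnot(is(scheme, "AcquisitionScheme"))
    dims <- dim(data)
    if (length(dims) != 4 || dims[4] != nVolumes(scheme))
        stop("series volume count does not match the scheme")
    gridDim <- dims[1:3]
    if (is.null(mask)) mask <- array(TRUE, gridDim)
    if (!identical(dim(mask), gridDim))
        stop("mask geometry does not match the series")
    nvox <- prod(gridDim)
    S <- data
    dim(S) <- c(nvox, dims[4])
    vox <- which(mask)

    b1 <- scheme@bvalues[2]; b2 <- scheme@bvalues[3]
    w <- scheme@weights
    md <- rep(NA_real_, nvox)
    mkt <- rep(NA_real_, nvox)
    flags <- rep(.FLAG_BITS[["OUTSIDE_MASK"]], nvox)

    if (length(vox)) {
        s0 <- S[vox, 1]
        dead <- !is.finite(s0) | s0 <= config$signalFloor
        fl <- integer(length(vox))
        live <- which(!dead)
        if (length(live)) {
            lv <- vox[live]
            s0l <- s0[live]
            floorv <- config$signalFloor * s0l
            S1 <- S[lv, 2:10, drop = FALSE]
            S2 <- S[lv, 11:19, drop = FALSE]
            clamped <- rowSums(S1 <= floorv) > 0 | rowSums(S2 <= floorv) > 0
            A1 <- drop((log(pmax(S1, floorv)) - log(s0l)) %*% w)
            A2 <- drop((log(pmax(S2, floorv)) - log(s0l)) %*% w)
            mdv <- (b1^2 * A2 - b2^2 * A1) / (b1 * b2^2 - b1^2 * b2)
            den <- A1 * b2^2 - A2 * b1^2
            degen <- abs(den) < config$degeneracyFloor
            mktv <- rep(config$sentinel, length(lv))
            ok <- !degen
            mktv[ok] <- 6 * b1 * b2 * (A1[ok] * b2 - A2[ok] * b1) *
                (b1 - b2) / den[ok]^2
            f <- integer(length(lv))
            f <- f + .FLAG_BITS[["NONPOSITIVE_SIGNAL"]] * clamped
            f <- f + .FLAG_BITS[["DEGENERATE_DENOMINATOR"]] * degen
            f <- f + .FLAG_BITS[["MD_OUT_OF_RANGE"]] *
                (mdv < config$mdRange[1] | mdv > config$mdRange[2])
            mktOut <- !degen & (mktv < config$mktRange[1] |
                                mktv > config$mktRange[2])
            f <- f + .FLAG_BITS[["MKT_OUT_OF_RANGE"]] * mktOut
            md[lv] <- mdv
            mkt[lv] <- mktv
            fl[live] <- f
        }
        if (any(dead)) {
            fl[dead] <- sum(.FLAG_BITS[c("NONPOSITIVE_SIGNAL",
                                         "DEGENERATE_DENOMINATOR",
                                         "MD_OUT_OF_RANGE",
                                         "MKT_OUT_OF_RANGE")])
            md[vox[dead]] <- config$sentinel
            mkt[vox[dead]] <- config$sentinel
        }
        flags[vox] <- fl
    }
    dim(md) <- gridDim; dim(mkt) <- gridDim; dim(flags) <- gridDim
    list(md = new("ParametricMap", values = md, flags = flags,
                  voxelSize = voxelSize, units = "um^2/ms"),
         mkt = new("ParametricMap", values = mkt, flags = flags,
                   voxelSize = voxelSize, units = ""))
}

#' Parametric map accessors
#'
#' @param map a [ParametricMap-class].
#' @return \code{mapValues}: the numeric value array; \code{mapFlags}: the
#'   integer flag array (decode with [flagNames()]).
#' @export
mapValues <- function(map) {
    stopifnot(is(map, "ParametricMap"))
    map@values
}

#' @rdname mapValues
#' @export
mapFlags <- function(map) {
    stopifnot(is(map, "ParametricMap"))
    map@flags
}

#' Phantom truth accessors
#'
#' @param truth a [PhantomTruth-class].
#' @return \code{phantomMasks}: named list of logical mask arrays;
#'   \code{truthMaps}: list with the md and mkt truth arrays.
#' @export
phantomMasks <- function(truth) {
    stopifnot(is(truth, "PhantomTruth"))
    truth@masks
}

#' @rdname phantomMasks
#' @export
truthMaps <- function(truth) {
    stopifnot(is(truth, "PhantomTruth"))
    list(md = truth@md, mkt = truth@mkt)
}

## neighbourhood offsets for 3D connectivity 6/18/26
.neighbourOffsets <- function(connectivity = 26) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    r <- abs(g$dx) + abs(g$dy) + abs(g$dz)
    keep <- switch(as.character(connectivity),
                   "6" = r == 1, "18" = r <= 2, "26" = rep(TRUE, nrow(g)),
                   stop("connectivity must be 6, 18 or 26"))
    as.matrix(g[keep, ])
}

#' Label connected components of a 3D binary mask
#'
#' Flood-fill labeling with 26- (default), 18- or 6-neighbourhood
#' connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background), with
#'   attribute \code{"sizes"} giving voxel counts per label.
#' @export
labelComponents <- function(mask, connectivity = 26) {
    stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
    dims <- dim(mask)
    idx <- which(mask)
    labels <- integer(length(idx))
    out <- array(0L, dims)
    if (!length(idx)) return(structure(out, sizes = integer(0)))
    pos <- integer(prod(dims))
    pos[idx] <- seq_along(idx)
    ix <- ((idx - 1L) %% dims[1]) + 1L
    iy <- (((idx - 1L) %/% dims[1]) %% dims[2]) + 1L
    iz <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
    off <- .neighbourOffsets(connectivity)
    comp <- 0L
    for (seed in seq_along(idx)) {
        if (labels[seed] != 0L) next
        comp <- comp + 1L
        labels[seed] <- comp
        frontier <- seed
        while (length(frontier)) {
            nxt <- integer(0)
            for (o in seq_len(nrow(off))) {
                nx <- ix[frontier] + off[o, 1]
                ny <- iy[frontier] + off[o, 2]
                nz <- iz[frontier] + off[o, 3]
                ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
                      nz >= 1L & nz <= dims[3]
                if (!any(ok)) next
                ni <- (nz[ok] - 1L) * dims[1] * dims[2] +
                      (ny[ok] - 1L) * dims[1] + nx[ok]
                np <- pos[ni]
                np <- np[np > 0L]
                np <- np[labels[np] == 0L]
                if (length(np)) {
                    labels[np] <- comp
                    nxt <- c(nxt, np)
                }
            }
            frontier <- unique(nxt)
        }
    }
    out[idx] <- labels
    structure(out, sizes = tabulate(labels, comp))
}

#' Keep the largest connected component of a binary mask
#'
#' @inheritParams labelComponents
#' @return Logical array containing only the largest component (all-FALSE
#'   input is returned unchanged).
#' @export
largestComponent <- function(mask, connectivity = 26) {
    lab <- labelComponents(mask, connectivity)
    sizes <- attr(lab, "sizes")
    if (!length(sizes)) return(mask & FALSE)
    lab == which.max(sizes)
}

#' Threshold-based lesion segmentation against the contralateral hemisphere
#'
#' Objective stand-in for manual lesion delineation: computes the mean and
#' SD of the (unflagged) map values in the contralateral mask and selects
#' voxels below mean - k*SD (\code{mode = "md_low"}, diffusivity drop) or
#' above mean + k*SD (\code{mode = "mkt_high"}, kurtosis elevation) within
#' the brain mask, then keeps the largest connected component
#' (26-neighbourhood by default).
#'
#' @param map a [ParametricMap-class].
#' @param brainMask logical array restricting the search.
#' @param contralateralMask logical array of reference (unaffected) tissue;
#'   must be nonempty and should be disjoint from the expected lesion.
#' @param mode "md_low" or "mkt_high".
#' @param k SD multiplier (default 2).
#' @param connectivity component connectivity (default 26).
#' @return Logical lesion mask with attributes \code{threshold},
#'   \code{mode}, \code{k} and \code{provenance = "threshold"}.
#' @export
segmentLesion <- function(map, brainMask, contralateralMask,
                          mode = c("md_low", "mkt_high"), k = 2,
                          connectivity = 26) {
    stopifnot(is(map, "ParametricMap"))
    mode <- match.arg(mode)
    v <- map@values
    if (!identical(dim(v), dim(brainMask)) ||
        !identical(dim(v), dim(contralateralMask)))
        stop("mask geometry does not match the map")
    usable <- is.finite(v) & map@flags == 0L
    ref <- v[contralateralMask & usable]
    if (!length(ref))
        stop("contralateral mask contains no usable voxels")
    mu <- mean(ref); sdev <- stats::sd(ref)
    if (is.na(sdev)) sdev <- 0
    thr <- if (mode == "md_low") mu - k * sdev else mu + k * sdev
    ## guard band breaks 1-ulp ties when the reference tissue is exactly
    ## uniform (noiseless data), where sd = 0 puts the threshold on top of
    ## the reference value itself
    guard <- 1e-9 * max(1, abs(mu))
    cand <- brainMask & usable &
        (if (mode == "md_low") v < thr - guard else v > thr + guard)
    lesion <- largestComponent(cand, connectivity)
    structure(lesion, threshold = thr, mode = mode, k = k,
              provenance = "threshold")
}

#' Split a brain mask into hemispheres at the mid-sagittal plane
#'
#' Uses the center of the brain-mask bounding box along the given axis;
#' explicit hemisphere masks should be preferred when available.
#'
#' @param brainMask logical 3D array.
#' @param axis left-right axis (default 1).
#' @return List of logical arrays \code{left} and \code{right}; their union
#'   is the brain mask and they are disjoint.
#' @export
hemisphereMasks <- function(brainMask, axis = 1L) {
    stopifnot(is.array(brainMask), length(dim(brainMask)) == 3,
              axis %in% 1:3)
    any1 <- apply(brainMask, axis, any)
    if (!any(any1)) stop("brain mask is empty")
    lo <- min(which(any1)); hi <- max(which(any1))
    mid <- (lo + hi) / 2
    planeIdx <- slice.index(brainMask, axis)
    left <- brainMask & (planeIdx <= mid)
    list(left = left, right = brainMask & !left)
}

#' Mask-based volume
#'
#' Volume = voxel count x voxel volume, reported in cm^3 (exact integer
#' count times a constant).
#'
#' @param mask logical (or 0/1) array.
#' @param voxelSize voxel edge lengths, mm.
#' @return Volume in cm^3.
#' @examples
#' volumeFromMask(array(TRUE, c(10, 1, 1)), c(0.25, 0.25, 0.5))  # 3.125e-4
#' @export
volumeFromMask <- function(mask, voxelSize) {
    if (!all(mask %in% c(TRUE, FALSE)))
        stop("mask must be binary")
    stopifnot(length(voxelSize) == 3, all(voxelSize > 0))
    sum(mask) * prod(voxelSize) / 1000
}

#' Percentage excess of the MKT lesion volume over the MD lesion volume
#'
#' @param vMkt,vMd lesion volumes in a common unit; vMd must be positive.
#' @return 100 * (vMkt - vMd) / vMd, percent.
#' @examples
#' mismatchPercent(0.304, 0.232)  # ~31
#' @export
mismatchPercent <- function(vMkt, vMd) {
    if (!is.numeric(vMd) || any(vMd <= 0))
        stop("vMd must be positive")
    100 * (vMkt - vMd) / vMd
}

#' @describeIn ParametricMap-class compact display
#' @param object a ParametricMap
#' @export
setMethod("show", "ParametricMap", function(object) {
    v <- object@values[object@flags == 0L]
    cat(sprintf("ParametricMap %s: %s voxels at %s mm\n",
                if (nzchar(object@units)) paste0("(", object@units, ")") else
                    "(dimensionless)",
                paste(dim(object@values), collapse = "x"),
                paste(format(object@voxelSize), collapse = "x")))
    if (length(v))
        cat(sprintf("  unflagged voxels: %d, median value %s\n",
                    length(v), format(stats::median(v), digits = 4)))
})
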