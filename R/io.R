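#' Write and read FSL-style bvals/bvecs for a 1-9-9 scheme
#'
#' The bvals file holds one row of 19 b-values; the bvecs file holds three
#' rows (x, y, z components), one column per volume, with a zero vector for
#' the b = 0 volume. Volume order is the scheme order.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param bvalFile,bvecFile output paths.
#' @return Invisibly, the two paths.
#' @export
writeBvalBvec <- function(scheme, bvalFile, bvecFile) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    b <- scheme@bvalues
    bvals <- c(0, rep(b[2], 9), rep(b[3], 9))
    vecs <- rbind(0, scheme@directions, scheme@directions)
    writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvalFile)
    writeLines(apply(t(vecs), 1, function(r)
        paste(format(r, trim = TRUE, digits = 15), collapse = " ")),
        bvecFile)
    invisible(c(bvalFile, bvecFile))
}

#' @rdname writeBvalBvec
#' @return \code{readBvalBvec}: list with \code{bvals} (numeric(19)) and
#'   \code{bvecs} (19 x 3 matrix, rows per volume).
#' @export
readBvalBvec <- function(bvalFile, bvecFile) {
    bvals <- scan(bvalFile, quiet = TRUE)
    rows <- lapply(readLines(bvecFile), function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(rows) != 3)
        stop("bvecs file must contain three rows (x, y, z components)")
    bvecs <- t(do.call(rbind, rows))
    if (nrow(bvecs) != length(bvals))
        stop("bvals and bvecs disagree on the number of volumes")
    list(bvals = bvals, bvecs = bvecs)
}

#' Reconstruct a 1-9-9 scheme from bvals/bvecs
#'
#' Expects exactly one b = 0 volume (first) and two shells of nine matching
#' directions each; certifies the recovered direction set against the trace
#' identity. The axis/bisector partition is inferred from the direction
#' weights needed for certification: the first three directions are taken
#' as axes; use a JSON scheme descriptor when an explicit partition must be
#' preserved.
#'
#' @param bvals numeric(19).
#' @param bvecs 19 x 3 matrix of unit rows (zero row for b = 0).
#' @param tol matching tolerance for b-values and directions.
#' @return An [AcquisitionScheme-class].
#' @export
schemeFromBvalBvec <- function(bvals, bvecs, tol = 1e-6) {
    if (length(bvals) != 19 || !identical(dim(as.matrix(bvecs)),
                                          c(19L, 3L)))
        stop("expected 19 volumes (1 + 9 + 9)")
    if (abs(bvals[1]) > tol)
        stop("the first volume must be the b = 0 image")
    shells <- sort(unique(round(bvals[-1] / tol) * tol))
    if (length(shells) != 2)
        stop("expected exactly two nonzero shells")
    i1 <- which(abs(bvals - shells[1]) <= tol)
    i2 <- which(abs(bvals - shells[2]) <= tol)
    if (length(i1) != 9 || length(i2) != 9)
        stop("each shell must contain nine volumes")
    d1 <- as.matrix(bvecs)[i1, , drop = FALSE]
    d2 <- as.matrix(bvecs)[i2, , drop = FALSE]
    if (max(abs(d1 - d2)) > tol)
        stop("the two shells must share the same nine directions in order")
    make199Scheme(shells[1], shells[2], directions = d1)
}

#' Write and read a JSON scheme descriptor
#'
#' The JSON descriptor carries the b-values, the explicit direction table
#' with the axis/bisector partition and weights, and the delta/Delta
#' metadata, so a scheme round-trips exactly.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param path JSON file path.
#' @return \code{writeSchemeJson}: the path, invisibly;
#'   \code{readSchemeJson}: the [AcquisitionScheme-class].
#' @export
writeSchemeJson <- function(scheme, path) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    jsonlite::write_json(list(
        bvalues = scheme@bvalues,
        directions = unname(apply(scheme@directions, 1, as.numeric,
                                  simplify = FALSE)),
        weights = scheme@weights,
        partition = scheme@partition,
        timings = as.list(scheme@timings)),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeSchemeJson
#' @export
readSchemeJson <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    dirs <- if (is.matrix(j$directions)) j$directions else
        do.call(rbind, lapply(j$directions, as.numeric))
    new("AcquisitionScheme",
        bvalues = as.numeric(j$bvalues),
        directions = dirs,
        weights = as.numeric(j$weights),
        partition = as.character(j$partition),
        timings = c(delta = as.numeric(j$timings$delta %||% NA),
                    Delta = as.numeric(j$timings$Delta %||% NA)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' NIfTI I/O for series, maps and masks
#'
#' Thin wrappers around RNifti carrying the voxel geometry. A
#' [DkiSeries-class] is written as a 4D NIfTI plus bvals/bvecs;
#' [ParametricMap-class] values and flags as 3D volumes; masks as 0/1
#' volumes.
#'
#' @param series a [DkiSeries-class].
#' @param prefix output path prefix; writes \code{<prefix>.nii.gz},
#'   \code{<prefix>.bval}, \code{<prefix>.bvec}.
#' @return \code{writeSeriesNifti}: the image path invisibly;
#'   \code{readSeriesNifti}: a [DkiSeries-class].
#' @export
writeSeriesNifti <- function(series, prefix) {
    stopifnot(is(series, "DkiSeries"))
    img <- RNifti::asNifti(series@data)
    RNifti::pixdim(img) <- c(series@voxelSize, 1)
    path <- paste0(prefix, ".nii.gz")
    RNifti::writeNifti(img, path)
    writeBvalBvec(series@scheme, paste0(prefix, ".bval"),
                  paste0(prefix, ".bvec"))
    invisible(path)
}

#' @rdname writeSeriesNifti
#' @param path path of a 4D NIfTI series.
#' @param bvalFile,bvecFile acquisition description files.
#' @export
readSeriesNifti <- function(path, bvalFile, bvecFile) {
    img <- RNifti::readNifti(path)
    bb <- readBvalBvec(bvalFile, bvecFile)
    scheme <- schemeFromBvalBvec(bb$bvals, bb$bvecs)
    vs <- RNifti::pixdim(img)[1:3]
    data <- array(as.numeric(img), dim = dim(img))
    new("DkiSeries", data = data, scheme = scheme, voxelSize = vs,
        s0Level = stats::median(data[, , , 1][data[, , , 1] > 0]),
        sigma = NA_real_)
}

#' @rdname writeSeriesNifti
#' @param map a [ParametricMap-class].
#' @param mapPrefix output prefix; writes \code{<mapPrefix>.nii.gz} and
#'   \code{<mapPrefix>_flags.nii.gz}.
#' @export
writeMapNifti <- function(map, mapPrefix) {
    stopifnot(is(map, "ParametricMap"))
    p1 <- paste0(mapPrefix, ".nii.gz")
    vimg <- RNifti::asNifti(map@values)
    RNifti::pixdim(vimg) <- map@voxelSize
    RNifti::writeNifti(vimg, p1)
    fimg <- RNifti::asNifti(map@flags + 0)
    RNifti::pixdim(fimg) <- map@voxelSize
    RNifti::writeNifti(fimg, paste0(mapPrefix, "_flags.nii.gz"))
    invisible(p1)
}

#' @rdname writeSeriesNifti
#' @param mask logical array.
#' @param voxelSize voxel size, mm.
#' @export
writeMaskNifti <- function(mask, voxelSize, path) {
    img <- RNifti::asNifti(mask + 0)
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname writeSeriesNifti
#' @export
readMaskNifti <- function(path) {
    img <- RNifti::readNifti(path)
    m <- array(as.numeric(img) != 0, dim = dim(img))
    structure(m, voxelSize = RNifti::pixdim(img)[seq_len(min(3,
        length(dim(img))))])
}

#' Check that two NIfTI images share a voxel grid
#'
#' Compares the xform (affine) matrices; a mismatch beyond the tolerance
#' (in mm) means masks and series do not live on the same grid.
#'
#' @param path1,path2 NIfTI paths.
#' @param tol largest tolerated absolute affine difference, mm.
#' @return TRUE invisibly; errors on mismatch.
#' @export
checkSameGrid <- function(path1, path2, tol = 1e-4) {
    x1 <- RNifti::xform(RNifti::readNifti(path1))
    x2 <- RNifti::xform(RNifti::readNifti(path2))
    if (max(abs(x1 - x2)) > tol)
        stop("images are not on the same voxel grid (affines differ by ",
             format(max(abs(x1 - x2))), " mm)")
    invisible(TRUE)
}

#' Write the phantom manifest and section-stack artifacts
#'
#' \code{writePhantomManifest} records the phantom specification as YAML.
#' \code{writeSectionAreasCsv} writes per-section raster areas of a
#' [SectionStack-class] as CSV. \code{writeSectionStackTiff} writes the
#' binary sections as a multi-page TIFF (requires the tiff package).
#'
#' @param spec a [PhantomSpec-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePhantomManifest <- function(spec, path) {
    stopifnot(is(spec, "PhantomSpec"))
    yaml::write_yaml(list(
        grid = list(dim = as.integer(spec@dim),
                    voxel_size_mm = spec@voxelSize),
        brain = list(center_mm = spec@brainCenter,
                     radii_mm = spec@brainRadii),
        lesion = list(center_mm = spec@lesionCenter,
                      core_radii_mm = spec@coreRadii,
                      mkt_excess = spec@mktExcess),
        tissue = spec@tissue,
        acquisition = list(snr = spec@snr, s0 = spec@s0, fa = spec@fa,
                           seed = spec@seed)), path)
    invisible(path)
}

#' @rdname writePhantomManifest
#' @export
readPhantomManifest <- function(path) {
    y <- yaml::read_yaml(path)
    phantomSpec(dim = as.integer(y$grid$dim),
                voxelSize = as.numeric(y$grid$voxel_size_mm),
                brainCenter = as.numeric(y$brain$center_mm),
                brainRadii = as.numeric(y$brain$radii_mm),
                lesionCenter = as.numeric(y$lesion$center_mm),
                coreRadii = as.numeric(y$lesion$core_radii_mm),
                mktExcess = y$lesion$mkt_excess,
                tissue = y$tissue,
                snr = y$acquisition$snr, s0 = y$acquisition$s0,
                fa = y$acquisition$fa, seed = y$acquisition$seed)
}

#' @rdname writePhantomManifest
#' @param stack a [SectionStack-class].
#' @export
writeSectionAreasCsv <- function(stack, path) {
    stopifnot(is(stack, "SectionStack"))
    areas <- vapply(stack@sections, sectionArea, 0,
                    pixelSize = stack@pixelSize)
    utils::write.csv(data.frame(section = seq_along(areas),
                                area_mm2 = areas), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writePhantomManifest
#' @export
writeSectionStackTiff <- function(stack, path) {
    stopifnot(is(stack, "SectionStack"))
    if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to write section stacks")
    pages <- lapply(stack@sections, function(s) {
        storage.mode(s) <- "double"
        s
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
    invisible(path)
}
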