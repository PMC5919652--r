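#' @import methods
NULL

#' DiffusionTensor: symmetric positive semidefinite rank-2 tensor
#'
#' Holds the diffusion tensor D (units \eqn{\mu m^2/ms}) as a symmetric 3x3
#' matrix. Validity enforces exact symmetry, positive semidefiniteness (all
#' eigenvalues >= -1e-12) and a nonnegative mean diffusivity Tr(D)/3.
#'
#' @slot tensor symmetric 3x3 numeric matrix, \eqn{\mu m^2/ms}.
#' @seealso [diffusionTensor()], [meanDiffusivity()]
#' @export
setClass("DiffusionTensor", representation(tensor = "matrix"))

setValidity("DiffusionTensor", function(object) {
    m <- object@tensor
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
        return("tensor must be a numeric 3x3 matrix")
    if (any(!is.finite(m)))
        return("tensor components must be finite")
    if (!identical(m, t(m)))
        return("tensor must be exactly symmetric (D_ij = D_ji)")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-12))
        return("tensor must be positive semidefinite (eigenvalues >= -1e-12)")
    if (sum(diag(m)) / 3 < 0)
        return("mean diffusivity Tr(D)/3 must be nonnegative")
    TRUE
})

#' KurtosisTensor: fully symmetric rank-4 kurtosis tensor W
#'
#' Holds the dimensionless kurtosis tensor W as a 3x3x3x3 array that is fully
#' symmetric under any permutation of its indices, so it has 15 unique
#' components. The mean of the kurtosis tensor (MKT) is its spherical average,
#' equal to (1/5)Tr(W); see [mktTrace()].
#'
#' @slot tensor numeric array of dimension c(3,3,3,3), fully symmetric.
#' @seealso [kurtosisTensor()], [isotropicKurtosisTensor()], [mktTrace()],
#'   [apparentKurtosis()]
#' @export
setClass("KurtosisTensor", representation(tensor = "array"))

setValidity("KurtosisTensor", function(object) {
    a <- object@tensor
    if (!is.numeric(a) || !identical(dim(a), c(3L, 3L, 3L, 3L)))
        return("tensor must be a numeric 3x3x3x3 array")
    if (any(!is.finite(a)))
        return("tensor components must be finite")
    ## full symmetry: transposing any pair of indices leaves the array intact
    perms <- list(c(2, 1, 3, 4), c(1, 3, 2, 4), c(1, 2, 4, 3))
    for (p in perms)
        if (max(abs(a - aperm(a, p))) > 1e-12 * max(1, max(abs(a))))
            return("tensor must be fully symmetric under index permutations")
    TRUE
})

#' AcquisitionScheme: the 1-9-9 fast-kurtosis protocol
#'
#' Describes the 19-volume fast-DKI acquisition: one b = 0 volume for signal
#' normalization plus the same nine unit directions at two nonzero shells b1
#' and b2. The nine directions split into 3 "axis" directions with weight 1/15
#' and 6 "bisector" directions with weight 2/15, so the weights sum to 1 and
#' the weighted direction average of any fully symmetric rank-4 tensor equals
#' its spherical mean (1/5)Tr(W). Diffusion timings delta/Delta are carried as
#' metadata only; the closed-form estimators depend only on b.
#'
#' @slot bvalues numeric(3): c(0, b1, b2) in \eqn{ms/\mu m^2}.
#' @slot directions 9x3 numeric matrix of unit row vectors.
#' @slot weights numeric(9) direction weights (1/15 axes, 2/15 bisectors).
#' @slot partition character(9), "axis" or "bisector" per direction.
#' @slot timings named numeric(2) c(delta, Delta) in ms (may be NA).
#' @seealso [make199Scheme()], [certifyScheme()]
#' @export
setClass("AcquisitionScheme",
         representation(bvalues = "numeric", directions = "matrix",
                        weights = "numeric", partition = "character",
                        timings = "numeric"))

setValidity("AcquisitionScheme", function(object) {
    b <- object@bvalues
    if (length(b) != 3 || b[1] != 0)
        return("bvalues must be c(0, b1, b2)")
    if (!(b[2] > 0 && b[3] > 0 && b[2] < b[3]))
        return("shells must satisfy 0 < b1 < b2")
    d <- object@directions
    if (!identical(dim(d), c(9L, 3L)))
        return("directions must be a 9x3 matrix")
    if (any(abs(sqrt(rowSums(d^2)) - 1) > 1e-9))
        return("directions must be unit vectors (norm 1 within 1e-9)")
    if (length(object@weights) != 9)
        return("weights must have length 9")
    if (abs(sum(object@weights) - 1) > 1e-12)
        return("direction weights must sum to 1")
    if (length(object@partition) != 9 ||
        !all(object@partition %in% c("axis", "bisector")))
        return("partition must label each direction 'axis' or 'bisector'")
    if (sum(object@partition == "axis") != 3)
        return("partition must contain 3 axis and 6 bisector directions")
    TRUE
})

#' DkiSeries: a 19-volume diffusion-weighted image series
#'
#' A 4D signal array (x, y, z, volume) together with the acquisition scheme
#' that produced it. Volume order is the scheme order: b = 0 first, then the
#' nine directions at b1, then the nine directions at b2. Stored magnitudes
#' are nonnegative (magnitude MRI).
#'
#' @slot data 4D numeric array, arbitrary signal units.
#' @slot scheme an [AcquisitionScheme-class].
#' @slot voxelSize numeric(3), mm.
#' @slot s0Level nominal noise-free b = 0 tissue signal (a.u.).
#' @slot sigma Gaussian noise level per channel (a.u.; 0 for noiseless).
#' @seealso [simulateAcquisition()], [fitMaps()]
#' @export
setClass("DkiSeries",
         representation(data = "array", scheme = "AcquisitionScheme",
                        voxelSize = "numeric", s0Level = "numeric",
                        sigma = "numeric"))

setValidity("DkiSeries", function(object) {
    if (length(dim(object@data)) != 4)
        return("data must be a 4D array (x, y, z, volume)")
    if (dim(object@data)[4] != 19)
        return("a 1-9-9 series must contain 19 volumes")
    if (any(object@data < 0, na.rm = TRUE))
        return("magnitude signals must be nonnegative")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
        return("voxelSize must be 3 positive lengths (mm)")
    TRUE
})

#' PhantomSpec: parameters of the synthetic stroke phantom
#'
#' Describes a two-hemisphere brain phantom: an ellipsoidal "brain" split at
#' the mid-sagittal plane, with an MD-hypointense lesion core nested inside a
#' larger MKT-hyperintense lesion (core + confocal ring). Geometry is given in
#' mm in the grid's world frame (voxel centers at (i - 1/2) * voxelSize).
#'
#' @slot dim integer(3) grid shape in voxels.
#' @slot voxelSize numeric(3) voxel edge lengths, mm.
#' @slot brainCenter,brainRadii numeric(3) brain ellipsoid center/semi-axes, mm.
#' @slot lesionCenter numeric(3) lesion center, mm.
#' @slot coreRadii numeric(3) semi-axes of the MD lesion core, mm.
#' @slot mktExcess designed fractional excess of the MKT lesion volume over
#'   the MD lesion volume; ring semi-axes are coreRadii * (1 + mktExcess)^(1/3).
#' @slot tissue named list of per-region parameters, each list(md, mkt):
#'   regions "normal", "core", "ring"; md in \eqn{\mu m^2/ms}.
#' @slot snr signal-to-noise ratio of the b = 0 tissue signal (sigma = s0/snr).
#' @slot s0 noise-free b = 0 tissue signal (a.u.).
#' @slot fa fractional anisotropy of the (axially symmetric, z-axis) diffusion
#'   tensor; 0 gives isotropic tensors.
#' @slot seed default RNG seed for [simulateAcquisition()].
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", voxelSize = "numeric",
                        brainCenter = "numeric", brainRadii = "numeric",
                        lesionCenter = "numeric", coreRadii = "numeric",
                        mktExcess = "numeric", tissue = "list",
                        snr = "numeric", s0 = "numeric", fa = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@dim) != 3 || any(object@dim < 1))
        return("dim must be 3 positive integers")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
        return("voxelSize must be 3 positive lengths (mm)")
    need <- c("normal", "core", "ring")
    if (!all(need %in% names(object@tissue)))
        return("tissue must define regions 'normal', 'core' and 'ring'")
    for (r in need) {
        p <- object@tissue[[r]]
        if (!all(c("md", "mkt") %in% names(p)))
            return(sprintf("tissue$%s must contain md and mkt", r))
        if (p$md <= 0)
            return("all region mean diffusivities must be positive")
    }
    if (any(object@coreRadii < 0))
        return("coreRadii must be nonnegative")
    if (object@mktExcess < 0)
        return("mktExcess must be nonnegative (core strictly inside ring)")
    if (object@snr <= 0)
        return("snr must be positive (use Inf for noiseless)")
    if (object@s0 <= 0)
        return("s0 must be positive")
    if (object@fa < 0 || object@fa >= 1)
        return("fa must lie in [0, 1)")
    TRUE
})

#' PhantomTruth: ground-truth maps and masks of the phantom
#'
#' @slot md,mkt numeric arrays of the true parameter maps (MD in
#'   \eqn{\mu m^2/ms}, MKT dimensionless; 0 outside the brain).
#' @slot masks named list of logical arrays: brain, left, right, lesion_md,
#'   lesion_mkt. Nesting invariant: lesion_md within lesion_mkt within one
#'   hemisphere within brain; left/right partition the brain.
#' @slot voxelSize numeric(3), mm.
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomTruth",
         representation(md = "array", mkt = "array", masks = "list",
                        voxelSize = "numeric"))

setValidity("PhantomTruth", function(object) {
    need <- c("brain", "left", "right", "lesion_md", "lesion_mkt")
    if (!all(need %in% names(object@masks)))
        return("masks must contain brain, left, right, lesion_md, lesion_mkt")
    m <- object@masks
    if (any(m$lesion_md & !m$lesion_mkt))
        return("lesion_md must be a subset of lesion_mkt")
    if (any(m$lesion_mkt & !m$brain))
        return("lesion_mkt must be a subset of the brain mask")
    if (any(m$left & m$right))
        return("hemisphere masks must be disjoint")
    if (!identical(m$left | m$right, m$brain))
        return("left and right hemispheres must partition the brain mask")
    TRUE
})

#' ParametricMap: a voxelwise parameter map with quality flags
#'
#' @slot values numeric array; NA at voxels carrying the sentinel (outside
#'   the mask or degenerate).
#' @slot flags integer array of bitwise quality flags; see [flagNames()].
#' @slot voxelSize numeric(3), mm.
#' @slot units unit label ("um^2/ms" for MD, "" for MKT).
#' @seealso [fitMaps()], [segmentLesion()]
#' @export
setClass("ParametricMap",
         representation(values = "array", flags = "array",
                        voxelSize = "numeric", units = "character"))

setValidity("ParametricMap", function(object) {
    if (!identical(dim(object@values), dim(object@flags)))
        return("values and flags must share geometry")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
        return("voxelSize must be 3 positive lengths (mm)")
    TRUE
})

#' SectionStack: an ordered stack of binary histology-like sections
#'
#' @slot sections list of logical matrices, all the same shape, ordered along
#'   the cutting axis.
#' @slot pixelSize numeric(2) in-plane pixel size, mm.
#' @slot thickness section thickness t, \eqn{\mu m}.
#' @slot spacing center-to-center distance between consecutive stored
#'   sections, \eqn{\mu m} (equals thickness for an exhaustive stack,
#'   thickness/ssf after systematic sampling).
#' @seealso [sliceSections()], [systematicSample()], [cavalieriVolume()]
#' @export
setClass("SectionStack",
         representation(sections = "list", pixelSize = "numeric",
                        thickness = "numeric", spacing = "numeric"))

setValidity("SectionStack", function(object) {
    if (length(object@sections) == 0)
        return("stack must contain at least one section")
    dims <- unique(lapply(object@sections, dim))
    if (length(dims) != 1)
        return("all sections must share pixel geometry")
    if (!all(vapply(object@sections, is.logical, TRUE)))
        return("sections must be logical (binary) matrices")
    if (length(object@pixelSize) != 2 || any(object@pixelSize <= 0))
        return("pixelSize must be 2 positive lengths (mm)")
    if (object@thickness <= 0)
        return("section thickness must be positive")
    TRUE
})

#' CavalieriEstimate: a stereological volume estimate
#'
#' V = t * (1/SSF) * sum(a_i), with t the section thickness, SSF the section
#' sampling fraction and a_i the sampled cross-sectional areas.
#'
#' @slot volume estimated volume, cm^3.
#' @slot areas sampled section areas, mm^2.
#' @slot ssf section sampling fraction.
#' @slot thickness section thickness, \eqn{\mu m}.
#' @slot start sampling start offset (0-based; NA if not applicable).
#' @seealso [cavalieriVolume()]
#' @export
setClass("CavalieriEstimate",
         representation(volume = "numeric", areas = "numeric",
                        ssf = "numeric", thickness = "numeric",
                        start = "numeric"))

setValidity("CavalieriEstimate", function(object) {
    expected <- object@thickness * sum(object@areas) / object@ssf * 1e-6
    if (abs(object@volume - expected) > 1e-12 * max(1, expected))
        return("volume must equal t * (1/ssf) * sum(areas) exactly")
    TRUE
})
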