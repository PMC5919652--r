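#' Specify the synthetic two-hemisphere stroke phantom
#'
#' Default geometry emulates an ex-vivo rodent acquisition: a 64 x 64 x 32
#' grid of 0.25 x 0.25 x 0.5 mm voxels holding an ellipsoidal brain, split
#' into hemispheres at the mid-sagittal plane, with a spherical MD-lesion
#' core (reduced mean diffusivity) nested inside a confocal MKT lesion
#' (elevated kurtosis extending beyond the core). Ring semi-axes are
#' \code{coreRadii * (1 + mktExcess)^(1/3)}, so the designed MKT lesion
#' volume exceeds the MD lesion volume by \code{mktExcess} (31 percent by
#' default) up to voxel discretization.
#'
#' Default tissue parameters (\eqn{\mu m^2/ms} for MD, dimensionless MKT):
#' normal md = 0.5, mkt = 0.8; core md = 0.35, mkt = 1.3; ring md = 0.5,
#' mkt = 1.3 — an MD drop confined to the core with the kurtosis elevation
#' extending into the ring, magnitudes typical of fixed ischemic tissue.
#'
#' @param dim grid shape, voxels.
#' @param voxelSize voxel edge lengths, mm.
#' @param brainCenter,brainRadii brain ellipsoid center and semi-axes, mm
#'   (defaults: grid center; c(7, 6.5, 6.5)).
#' @param lesionCenter lesion center, mm (default: brain center + 3.4 mm
#'   along x, inside the right hemisphere).
#' @param coreRadii semi-axes of the MD lesion core, mm.
#' @param mktExcess designed fractional MKT-over-MD lesion volume excess.
#' @param tissue per-region parameters; see Details.
#' @param snr b = 0 signal-to-noise ratio (sigma = s0/snr; Inf = noiseless).
#' @param s0 noise-free b = 0 tissue signal, a.u.
#' @param fa fractional anisotropy of the axially symmetric diffusion
#'   tensor (0 = isotropic).
#' @param seed default acquisition-noise seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec()
#' truth <- generatePhantom(spec)
#' @export
phantomSpec <- function(dim = c(64L, 64L, 32L),
                        voxelSize = c(0.25, 0.25, 0.5),
                        brainCenter = dim * voxelSize / 2,
                        brainRadii = c(7, 6.5, 6.5),
                        lesionCenter = brainCenter + c(3.4, 0, 0),
                        coreRadii = c(3, 3, 3),
                        mktExcess = 0.31,
                        tissue = list(
                            normal = list(md = 0.5, mkt = 0.8),
                            core   = list(md = 0.35, mkt = 1.3),
                            ring   = list(md = 0.5, mkt = 1.3)),
                        snr = 50, s0 = 1, fa = 0, seed = 1L) {
    new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize,
        brainCenter = brainCenter, brainRadii = brainRadii,
        lesionCenter = lesionCenter, coreRadii = coreRadii,
        mktExcess = mktExcess, tissue = tissue,
        snr = snr, s0 = s0, fa = fa, seed = as.integer(seed))
}

## voxel-center coordinate arrays (mm) for a grid
.voxelCoords <- function(dim, voxelSize) {
    cx <- (seq_len(dim[1]) - 0.5) * voxelSize[1]
    cy <- (seq_len(dim[2]) - 0.5) * voxelSize[2]
    cz <- (seq_len(dim[3]) - 0.5) * voxelSize[3]
    list(x = array(rep(cx, times = dim[2] * dim[3]), dim),
         y = array(rep(rep(cy, each = dim[1]), times = dim[3]), dim),
         z = array(rep(cz, each = dim[1] * dim[2]), dim))
}

.insideEllipsoid <- function(co, center, radii) {
    if (any(radii <= 0)) {
        r <- array(FALSE, dim(co$x))
        return(r)
    }
    ((co$x - center[1]) / radii[1])^2 +
    ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

#' Generate the phantom ground truth
#'
#' Deterministic (purely geometric): each voxel center is assigned the
#' parameters of the innermost region containing it (core over ring over
#' normal tissue); voxels outside the brain carry zero signal. Also builds
#' the brain, hemisphere and nested lesion masks.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomTruth-class].
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    co <- .voxelCoords(spec@dim, spec@voxelSize)
    brain <- .insideEllipsoid(co, spec@brainCenter, spec@brainRadii)
    ringRadii <- spec@coreRadii * (1 + spec@mktExcess)^(1 / 3)
    core <- .insideEllipsoid(co, spec@lesionCenter, spec@coreRadii)
    mktLesion <- .insideEllipsoid(co, spec@lesionCenter, ringRadii)
    if (any(mktLesion & !brain))
        stop("lesion is not contained in the brain; adjust the geometry")
    left <- brain & (co$x < spec@brainCenter[1])
    right <- brain & !left
    md <- array(0, spec@dim)
    mkt <- array(0, spec@dim)
    md[brain] <- spec@tissue$normal$md
    mkt[brain] <- spec@tissue$normal$mkt
    md[mktLesion & !core] <- spec@tissue$ring$md
    mkt[mktLesion & !core] <- spec@tissue$ring$mkt
    md[core] <- spec@tissue$core$md
    mkt[core] <- spec@tissue$core$mkt
    new("PhantomTruth", md = md, mkt = mkt,
        masks = list(brain = brain, left = left, right = right,
                     lesion_md = core, lesion_mkt = mktLesion),
        voxelSize = spec@voxelSize)
}

## eigenvalue asymmetry delta of an axially symmetric tensor with given FA:
## lambda_par = md(1 + 2 delta), lambda_perp = md(1 - delta),
## FA = 3 delta / sqrt(3 + 6 delta^2)  =>  delta = FA sqrt(3/(9 - 6 FA^2))
.faDelta <- function(fa) {
    if (fa == 0) return(0)
    fa * sqrt(3 / (9 - 6 * fa^2))
}

#' Simulate the 19-volume acquisition of a phantom
#'
#' Evaluates the two-term cumulant forward model voxelwise from the truth
#' maps (isotropic tensors by default: D = MD * I, W = MKT times the
#' isotropic rank-4 tensor; with \code{fa > 0} the diffusion tensor is
#' axially symmetric about z with the requested fractional anisotropy and
#' unchanged mean diffusivity) and corrupts the magnitudes with Rician
#' noise: \eqn{S_{noisy} = \sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}} with
#' \eqn{\epsilon_{1,2} \sim N(0, \sigma)}, \eqn{\sigma = s_0/snr}.
#' Gaussian mode adds \eqn{\epsilon_1} only (magnitudes floored at 0) and is
#' meant for estimator-theory experiments. Output is reproducible given the
#' seed.
#'
#' @param truth a [PhantomTruth-class].
#' @param scheme an [AcquisitionScheme-class] (19 volumes).
#' @param snr b = 0 signal-to-noise ratio; Inf disables noise.
#' @param seed integer RNG seed.
#' @param noise "rician", "gaussian" or "none".
#' @param s0 noise-free b = 0 tissue signal.
#' @param fa fractional anisotropy (axially symmetric D, z axis).
#' @return A [DkiSeries-class].
#' @export
simulateAcquisition <- function(truth, scheme, snr = 50, seed = 1L,
                                noise = c("rician", "gaussian", "none"),
                                s0 = 1, fa = 0) {
    stopifnot(is(truth, "PhantomTruth"), is(scheme, "AcquisitionScheme"))
    noise <- match.arg(noise)
    if (!is.finite(snr)) noise <- "none" else if (snr <= 0)
        stop("snr must be positive")
    dims <- dim(truth@md)
    nvol <- nVolumes(scheme)
    b <- scheme@bvalues
    dirs <- scheme@directions
    delta <- .faDelta(fa)
    md <- truth@md
    mkt <- truth@mkt
    brain <- truth@masks$brain
    clean <- array(0, c(dims, nvol))
    bvol <- c(0, rep(b[2], 9), rep(b[3], 9))
    nz2 <- c(0, dirs[, 3]^2, dirs[, 3]^2)  # direction z-component squared
    for (v in seq_len(nvol)) {
        ## n'Dn for axially symmetric D: md(1 - delta) + 3 delta md nz^2;
        ## isotropic W: apparent kurtosis = mkt along every direction
        quad <- md * (1 - delta) + 3 * delta * md * nz2[v]
        logS <- -bvol[v] * quad + bvol[v]^2 / 6 * md^2 * mkt
        vol <- s0 * exp(logS)
        vol[!brain] <- 0
        clean[, , , v] <- vol
    }
    sigma <- 0
    if (noise != "none") {
        sigma <- s0 / snr
        set.seed(as.integer(seed))
        n <- length(clean)
        e1 <- array(stats::rnorm(n, 0, sigma), dim(clean))
        if (noise == "rician") {
            e2 <- array(stats::rnorm(n, 0, sigma), dim(clean))
            clean <- sqrt((clean + e1)^2 + e2^2)
        } else {
            clean <- pmax(clean + e1, 0)
        }
    }
    new("DkiSeries", data = clean, scheme = scheme,
        voxelSize = truth@voxelSize, s0Level = s0, sigma = sigma)
}

#' @describeIn PhantomSpec-class compact display
#' @param object a PhantomSpec
#' @export
setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s voxels at %s mm, snr = %s\n",
                paste(object@dim, collapse = "x"),
                paste(format(object@voxelSize), collapse = "x"),
                format(object@snr)))
    cat(sprintf("  core radii %s mm, designed MKT excess %.0f%%\n",
                paste(format(object@coreRadii), collapse = "/"),
                100 * object@mktExcess))
})

#' @describeIn PhantomTruth-class mask voxel counts
#' @param object a PhantomTruth
#' @export
setMethod("show", "PhantomTruth", function(object) {
    counts <- vapply(object@masks, sum, 0L)
    cat("PhantomTruth maps", paste(dim(object@md), collapse = "x"),
        "voxels\n  mask voxel counts:",
        paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
})

#' @describeIn DkiSeries-class compact display
#' @param object a DkiSeries
#' @export
setMethod("show", "DkiSeries", function(object) {
    d <- dim(object@data)
    cat(sprintf("DkiSeries: %s grid, %d volumes, sigma = %s\n",
                paste(d[1:3], collapse = "x"), d[4], format(object@sigma)))
})
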