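## Quality flag bits shared by voxel estimates and parametric maps.
.FLAG_BITS <- c(NONPOSITIVE_SIGNAL    = 1L,
                DEGENERATE_DENOMINATOR = 2L,
                MD_OUT_OF_RANGE       = 4L,
                MKT_OUT_OF_RANGE      = 8L,
                OUTSIDE_MASK          = 16L)

#' Decode quality flag bits
#'
#' Voxel estimates and [ParametricMap-class] flag arrays store quality
#' markers as a bitmask: NONPOSITIVE_SIGNAL (1), DEGENERATE_DENOMINATOR (2),
#' MD_OUT_OF_RANGE (4), MKT_OUT_OF_RANGE (8), OUTSIDE_MASK (16).
#'
#' @param bits integer vector of flag bitmasks.
#' @return A list (one element per input) of character vectors of flag names.
#' @export
flagNames <- function(bits) {
    lapply(as.integer(bits), function(b) {
        names(.FLAG_BITS)[bitwAnd(b, .FLAG_BITS) != 0L]
    })
}

#' Estimation configuration for the 1-9-9 closed forms
#'
#' Numerical guards and plausibility bounds used by [estimateVoxel()] and
#' [fitMaps()]. Signals at or below \code{signalFloor * s0} are clamped to
#' that floor before taking logs (NONPOSITIVE_SIGNAL flag); an MKT
#' denominator \eqn{|A_1 b_2^2 - A_2 b_1^2|} below \code{degeneracyFloor}
#' marks the voxel DEGENERATE_DENOMINATOR and reports \code{sentinel}
#' instead of a diverging value. Estimates outside the plausibility
#' intervals are flagged, never clipped.
#'
#' @param signalFloor relative signal floor epsilon (default 1e-6).
#' @param degeneracyFloor MKT denominator floor (default 1e-12).
#' @param mdRange plausible MD interval, \eqn{\mu m^2/ms}.
#' @param mktRange plausible MKT interval (dimensionless).
#' @param sentinel value reported for degenerate MKT (default NA).
#' @return A list of class \code{dkiConfig}.
#' @export
dkiConfig <- function(signalFloor = 1e-6, degeneracyFloor = 1e-12,
                      mdRange = c(0, 4), mktRange = c(-1, 5),
                      sentinel = NA_real_) {
    stopifnot(signalFloor > 0, degeneracyFloor > 0,
              length(mdRange) == 2, length(mktRange) == 2)
    structure(list(signalFloor = signalFloor,
                   degeneracyFloor = degeneracyFloor,
                   mdRange = sort(mdRange), mktRange = sort(mktRange),
                   sentinel = sentinel),
              class = "dkiConfig")
}

#' Predict the diffusion-weighted signal (two-term cumulant model)
#'
#' Forward model of the signal along a unit direction:
#' \deqn{\log S(b,\hat n) = \log s_0 - b\, n_i n_j D_{ij}
#'   + \frac{b^2}{6}\,\bar D^2\, n_i n_j n_k n_l W_{ijkl},}
#' where \eqn{\bar D = Tr(D)/3} of the supplied tensor.
#'
#' @param s0 positive b = 0 signal (a.u.).
#' @param b diffusion weighting, \eqn{ms/\mu m^2}, nonnegative.
#' @param n unit direction 3-vector.
#' @param D a [DiffusionTensor-class] (or symmetric 3x3 matrix).
#' @param W a [KurtosisTensor-class], or NULL for purely Gaussian diffusion.
#' @return The strictly positive predicted signal.
#' @examples
#' sch <- make199Scheme(1, 2.5)
#' predictSignal(1, 0, c(1, 0, 0), diffusionTensor(0.5))   # == s0
#' @export
predictSignal <- function(s0, b, n, D, W = NULL) {
    if (!is.numeric(s0) || length(s0) != 1 || s0 <= 0)
        stop("s0 must be a positive scalar")
    if (!is.numeric(b) || length(b) != 1 || b < 0)
        stop("b must be a nonnegative scalar")
    n <- as.numeric(n)
    if (length(n) != 3 || abs(sqrt(sum(n^2)) - 1) > 1e-9)
        stop("n must be a unit 3-vector")
    Dm <- if (is(D, "DiffusionTensor")) D@tensor else D
    md <- sum(diag(Dm)) / 3
    logS <- -b * drop(crossprod(n, Dm %*% n))
    if (!is.null(W))
        logS <- logS + b^2 / 6 * md^2 * apparentKurtosis(W, n)
    s0 * exp(logS)
}

#' Weighted log-signal average over one shell (A1 or A2)
#'
#' Computes the 1-9-9 direction-weighted average of the normalized
#' log-signals at a single shell:
#' \deqn{A = \frac{1}{15}\Big(\sum_{axes}\log(S/s_0)
#'   + 2\sum_{bisectors}\log(S/s_0)\Big).}
#' Signals at or below \code{floorEps * s0} are clamped to the floor before
#' the log; the return value then carries \code{attr(, "clamped") = TRUE}
#' so downstream estimates can raise NONPOSITIVE_SIGNAL.
#'
#' @param signals 9 shell signals ordered like the scheme's directions
#'   (3 axes then 6 bisectors).
#' @param s0 positive b = 0 signal.
#' @param scheme an [AcquisitionScheme-class] supplying the weights.
#' @param floorEps relative signal floor (see [dkiConfig()]).
#' @return The dimensionless log-sum average, with attribute "clamped".
#' @export
logSumAverage <- function(signals, s0, scheme, floorEps = 1e-6) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    signals <- as.numeric(signals)
    if (length(signals) != nrow(scheme@directions))
        stop("expected one signal per scheme direction")
    if (!is.numeric(s0) || length(s0) != 1 || s0 <= 0)
        stop("s0 must be a positive scalar")
    floorv <- floorEps * s0
    clamped <- any(signals <= floorv)
    signals <- pmax(signals, floorv)
    structure(sum(scheme@weights * log(signals / s0)), clamped = clamped)
}

#' Closed-form 1-9-9 mean diffusivity
#'
#' \deqn{\bar D_{199} = (b_1^2 A_2 - b_2^2 A_1)/(b_1 b_2^2 - b_1^2 b_2).}
#'
#' @param A1,A2 log-sum averages at shells b1 and b2 (see [logSumAverage()]).
#' @param b1,b2 shell b-values, \eqn{ms/\mu m^2}, distinct and positive.
#' @return MD in \eqn{\mu m^2/ms}.
#' @export
estimateMD199 <- function(A1, A2, b1, b2) {
    if (!(b1 > 0 && b2 > 0) || b1 == b2)
        stop("b1 and b2 must be positive and distinct")
    (b1^2 * A2 - b2^2 * A1) / (b1 * b2^2 - b1^2 * b2)
}

#' Closed-form 1-9-9 mean kurtosis tensor
#'
#' \deqn{\bar W_{199} = 6 b_1 b_2 (A_1 b_2 - A_2 b_1)(b_1 - b_2)
#'   / (A_1 b_2^2 - A_2 b_1^2)^2.}
#' A denominator magnitude below \code{degeneracyFloor} (zero signal decay,
#' e.g. background) yields \code{sentinel} with attribute
#' \code{"degenerate" = TRUE} rather than a diverging value.
#'
#' @inheritParams estimateMD199
#' @param degeneracyFloor,sentinel see [dkiConfig()].
#' @return MKT (dimensionless), with attribute "degenerate".
#' @export
estimateMKT199 <- function(A1, A2, b1, b2, degeneracyFloor = 1e-12,
                           sentinel = NA_real_) {
    if (!(b1 > 0 && b2 > 0) || b1 == b2)
        stop("b1 and b2 must be positive and distinct")
    den <- A1 * b2^2 - A2 * b1^2
    if (abs(den) < degeneracyFloor)
        return(structure(sentinel, degenerate = TRUE))
    structure(6 * b1 * b2 * (A1 * b2 - A2 * b1) * (b1 - b2) / den^2,
              degenerate = FALSE)
}

#' Estimate MD and MKT for one voxel from its 19 signals
#'
#' Composes [logSumAverage()] at both shells with the closed forms
#' [estimateMD199()] and [estimateMKT199()], and applies the plausibility
#' flags of the configuration. Never throws on degenerate data: a b = 0
#' signal at or below the floor returns an all-flagged estimate.
#'
#' @param signals numeric(19) in scheme order: b = 0 first, then the nine
#'   directions at b1, then the nine at b2.
#' @param scheme an [AcquisitionScheme-class].
#' @param config a [dkiConfig()].
#' @return A list with elements \code{md} (\eqn{\mu m^2/ms}), \code{mkt}
#'   (dimensionless) and \code{flags} (character vector, empty when clean).
#' @examples
#' sch <- make199Scheme(1, 2.5)
#' dirs <- schemeDirections(sch)
#' D <- diffusionTensor(0.5); W <- isotropicKurtosisTensor(1)
#' s <- c(1, apply(dirs, 1, function(n) predictSignal(1, 1,   n, D, W)),
#'           apply(dirs, 1, function(n) predictSignal(1, 2.5, n, D, W)))
#' estimateVoxel(s, sch)   # md = 0.5, mkt = 1, no flags
#' @export
estimateVoxel <- function(signals, scheme, config = dkiConfig()) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    signals <- as.numeric(signals)
    if (length(signals) != nVolumes(scheme))
        stop("expected ", nVolumes(scheme), " signals (b = 0 first)")
    b <- scheme@bvalues
    flags <- character(0)
    s0 <- signals[1]
    if (!is.finite(s0) || s0 <= config$signalFloor) {
        ## dead voxel: no usable normalization signal
        return(list(md = config$sentinel, mkt = config$sentinel,
                    flags = names(.FLAG_BITS)[1:4]))
    }
    A1 <- logSumAverage(signals[2:10], s0, scheme, config$signalFloor)
    A2 <- logSumAverage(signals[11:19], s0, scheme, config$signalFloor)
    if (isTRUE(attr(A1, "clamped")) || isTRUE(attr(A2, "clamped")))
        flags <- c(flags, "NONPOSITIVE_SIGNAL")
    md <- estimateMD199(as.numeric(A1), as.numeric(A2), b[2], b[3])
    mkt <- estimateMKT199(as.numeric(A1), as.numeric(A2), b[2], b[3],
                          config$degeneracyFloor, config$sentinel)
    if (isTRUE(attr(mkt, "degenerate")))
        flags <- c(flags, "DEGENERATE_DENOMINATOR")
    if (md < config$mdRange[1] || md > config$mdRange[2])
        flags <- c(flags, "MD_OUT_OF_RANGE")
    if (!isTRUE(attr(mkt, "degenerate")) &&
        (mkt < config$mktRange[1] || mkt > config$mktRange[2]))
        flags <- c(flags, "MKT_OUT_OF_RANGE")
    list(md = md, mkt = as.numeric(mkt), flags = flags)
}
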