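## Default direction table: coordinate axes plus the six in-plane bisectors.
## This set cancels the mixed cross terms exactly, so the 1/15 : 2/15 weighted
## direction average of any fully symmetric rank-4 tensor equals (1/5)Tr(W);
## certifyScheme() checks that property numerically for any candidate set.
.defaultDirections <- function() {
    s <- 1 / sqrt(2)
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
          c(s,  s, 0), c(s, 0,  s), c(0, s,  s),
          c(s, -s, 0), c(s, 0, -s), c(0, s, -s))
}

#' Build the 1-9-9 fast-kurtosis acquisition scheme
#'
#' Returns the 19-volume protocol: one b = 0 volume, then nine directions at
#' b1 and the same nine at b2. The default directions are the three
#' coordinate axes (weight 1/15 each) and the six in-plane bisectors
#' (weight 2/15 each); any rotation of a valid set is accepted through
#' \code{directions}, and validity is certified by [certifyScheme()].
#'
#' @param b1,b2 shell b-values in \eqn{ms/\mu m^2}; must satisfy 0 < b1 < b2.
#' @param directions optional 9x3 matrix of unit directions, rows 1-3 axes
#'   and rows 4-9 bisector pairs.
#' @param delta,Delta gradient duration / separation in ms (metadata only;
#'   the estimators depend only on b).
#' @param certify certify the direction set at construction (100 random
#'   tensors, tolerance 1e-10).
#' @return An [AcquisitionScheme-class].
#' @examples
#' sch <- make199Scheme(1, 2.5)
#' nVolumes(sch)    # 19
#' @export
make199Scheme <- function(b1, b2, directions = NULL,
                          delta = NA_real_, Delta = NA_real_,
                          certify = !is.null(directions)) {
    if (!is.numeric(b1) || !is.numeric(b2) || length(b1) != 1 ||
        length(b2) != 1 || !(b1 > 0) || !(b2 > 0))
        stop("b1 and b2 must be positive scalars (ms/um^2)")
    if (b1 >= b2)
        stop("shells must satisfy 0 < b1 < b2 (b1 = b2 is not invertible)")
    if (is.null(directions)) directions <- .defaultDirections()
    directions <- as.matrix(directions)
    scheme <- new("AcquisitionScheme",
                  bvalues = c(0, b1, b2),
                  directions = directions,
                  weights = c(rep(1 / 15, 3), rep(2 / 15, 6)),
                  partition = c(rep("axis", 3), rep("bisector", 6)),
                  timings = c(delta = delta, Delta = Delta))
    if (certify) certifyScheme(scheme)
    scheme
}

#' Certify a direction scheme against the trace identity
#'
#' A direction set is valid for 1-9-9 estimation iff the weighted direction
#' average of the apparent kurtosis equals the spherical mean (1/5)Tr(W) for
#' every fully symmetric rank-4 tensor. This checks the identity on random
#' tensors (and the analogous rank-2 identity, weighted average of n'Dn
#' against Tr(D)/3) and errors if it fails.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param nTensors number of random tensors to test.
#' @param tol largest tolerated absolute deviation.
#' @param seed RNG seed for the random tensors.
#' @return \code{TRUE} invisibly; errors on failure.
#' @export
certifyScheme <- function(scheme, nTensors = 100, tol = 1e-10, seed = 1L) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    set.seed(seed)
    for (i in seq_len(nTensors)) {
        W <- kurtosisTensor(array(stats::rnorm(81), dim = c(3, 3, 3, 3)))
        avg <- sum(scheme@weights *
                   apply(scheme@directions, 1, apparentKurtosis, W = W))
        if (abs(avg - mktTrace(W)) > tol)
            stop("direction scheme failed the rank-4 trace identity (",
                 format(abs(avg - mktTrace(W))), " > ", format(tol), ")")
        m <- matrix(stats::rnorm(9), 3); m <- m + t(m)
        quad <- rowSums((scheme@directions %*% m) * scheme@directions)
        if (abs(sum(scheme@weights * quad) - sum(diag(m)) / 3) > tol)
            stop("direction scheme failed the rank-2 trace identity")
    }
    invisible(TRUE)
}

#' Number of image volumes required by a scheme
#'
#' @param scheme an [AcquisitionScheme-class].
#' @return Total volume count (1 + 9 + 9 = 19).
#' @export
nVolumes <- function(scheme) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    1L + 2L * nrow(scheme@directions)
}

#' Scheme accessors
#'
#' @param scheme an [AcquisitionScheme-class].
#' @return \code{bValues}: numeric(3) c(0, b1, b2); \code{schemeDirections}:
#'   9x3 matrix; \code{schemeWeights}: numeric(9).
#' @export
bValues <- function(scheme) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    scheme@bvalues
}

#' @rdname bValues
#' @export
schemeDirections <- function(scheme) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    scheme@directions
}

#' @rdname bValues
#' @export
schemeWeights <- function(scheme) {
    stopifnot(is(scheme, "AcquisitionScheme"))
    scheme@weights
}

#' @describeIn AcquisitionScheme-class compact display
#' @param object an AcquisitionScheme
#' @export
setMethod("show", "AcquisitionScheme", function(object) {
    b <- object@bvalues
    cat(sprintf("1-9-9 AcquisitionScheme: %d volumes, b = %s ms/um^2\n",
                nVolumes(object), paste(format(b), collapse = ", ")))
    cat(sprintf("  %d axis directions (w = 1/15), %d bisectors (w = 2/15)\n",
                sum(object@partition == "axis"),
                sum(object@partition == "bisector")))
    if (!all(is.na(object@timings)))
        cat(sprintf("  timings delta/Delta = %s/%s ms (metadata)\n",
                    format(object@timings[["delta"]]),
                    format(object@timings[["Delta"]])))
})
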