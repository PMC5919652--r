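#' Construct a diffusion tensor
#'
#' @param x either a symmetric 3x3 matrix of tensor components
#'   (\eqn{\mu m^2/ms}), or a single nonnegative number giving the mean
#'   diffusivity of an isotropic tensor \code{x * diag(3)}.
#' @return A [DiffusionTensor-class].
#' @examples
#' D <- diffusionTensor(0.5)           # isotropic, MD = 0.5 um^2/ms
#' meanDiffusivity(D)
#' @export
diffusionTensor <- function(x) {
    if (is.numeric(x) && length(x) == 1) {
        x <- diag(3) * x
    } else if (is.numeric(x) && identical(dim(x), c(3L, 3L))) {
        x <- (x + t(x)) / 2  # enforce exact symmetry against rounding
    } else {
        stop("x must be a 3x3 matrix or a single mean diffusivity")
    }
    new("DiffusionTensor", tensor = x)
}

#' Mean diffusivity Tr(D)/3
#'
#' @param D a [DiffusionTensor-class] or symmetric 3x3 matrix.
#' @return Mean diffusivity in \eqn{\mu m^2/ms}.
#' @export
meanDiffusivity <- function(D) {
    m <- if (is(D, "DiffusionTensor")) D@tensor else D
    sum(diag(m)) / 3
}

## index letters used for the 15 unique components of W
.tensorLetters <- c("x", "y", "z")

.symmetrize4 <- function(a) {
    ## average over the 4! index permutations
    perms <- .permutations4()
    out <- array(0, dim = c(3, 3, 3, 3))
    for (p in perms) out <- out + aperm(a, p)
    out / length(perms)
}

.permutations4 <- function() {
    idx <- 1:4
    out <- list()
    for (i in idx) for (j in setdiff(idx, i))
        for (k in setdiff(idx, c(i, j))) {
            l <- setdiff(idx, c(i, j, k))
            out[[length(out) + 1]] <- c(i, j, k, l)
        }
    out
}

#' Construct a kurtosis tensor
#'
#' Accepts either a full 3x3x3x3 array (symmetrized over index permutations,
#' then validated) or a named numeric vector of unique components such as
#' \code{c(xxxx = 2, xxyy = 0.3)}; component names are 4-letter strings over
#' x/y/z in any order, and unnamed components default to zero.
#'
#' @param x array of dimension c(3,3,3,3), or a named numeric vector of
#'   unique components.
#' @return A [KurtosisTensor-class].
#' @examples
#' W <- kurtosisTensor(c(xxxx = 2))
#' apparentKurtosis(W, c(1, 0, 0))   # 2
#' mktTrace(W)                       # 2/5
#' @export
kurtosisTensor <- function(x) {
    if (is.array(x) && identical(dim(x), c(3L, 3L, 3L, 3L))) {
        a <- .symmetrize4(x)
    } else if (is.numeric(x) && !is.null(names(x))) {
        a <- array(0, dim = c(3, 3, 3, 3))
        for (nm in names(x)) {
            ix <- match(strsplit(nm, "")[[1]], .tensorLetters)
            if (length(ix) != 4 || any(is.na(ix)))
                stop("component names must be 4 letters over x/y/z, e.g. 'xxyy'")
            ## assign the value to every permutation of the index tuple
            for (p in .permutations4())
                a[ix[p[1]], ix[p[2]], ix[p[3]], ix[p[4]]] <- x[[nm]]
        }
    } else {
        stop("x must be a 3x3x3x3 array or a named vector of unique components")
    }
    new("KurtosisTensor", tensor = a)
}

#' The fully symmetric isotropic rank-4 tensor, scaled to a target MKT
#'
#' Builds \code{mkt * I} with \code{I_ijkl = (d_ij d_kl + d_ik d_jl +
#' d_il d_jk)/3}, the unique fully symmetric isotropic tensor with spherical
#' mean 1. The result has \code{W_iiii = mkt}, \code{W_iijj = mkt/3} and
#' apparent kurtosis equal to \code{mkt} along every direction.
#'
#' @param mkt target mean kurtosis tensor value (dimensionless).
#' @return A [KurtosisTensor-class].
#' @export
isotropicKurtosisTensor <- function(mkt = 1) {
    d <- diag(3)
    a <- array(0, dim = c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
        a[i, j, k, l] <- (d[i, j] * d[k, l] + d[i, k] * d[j, l] +
                          d[i, l] * d[j, k]) / 3
    new("KurtosisTensor", tensor = a * mkt)
}

#' Apparent kurtosis along a direction
#'
#' Contracts the kurtosis tensor with a unit direction four times:
#' \eqn{W(\hat n) = n_i n_j n_k n_l W_{ijkl}} (sum over all 81 index
#' combinations).
#'
#' @param W a [KurtosisTensor-class].
#' @param n unit 3-vector (norm 1 within 1e-9).
#' @return The apparent kurtosis (dimensionless).
#' @export
apparentKurtosis <- function(W, n) {
    stopifnot(is(W, "KurtosisTensor"))
    n <- as.numeric(n)
    if (length(n) != 3 || abs(sqrt(sum(n^2)) - 1) > 1e-9)
        stop("n must be a unit 3-vector")
    sum(W@tensor * (n %o% n %o% n %o% n))
}

#' Mean of the kurtosis tensor, (1/5)Tr(W)
#'
#' The spherical average of the apparent kurtosis of a fully symmetric
#' rank-4 tensor reduces to one fifth of its trace:
#' \deqn{\bar W = (W_{xxxx} + W_{yyyy} + W_{zzzz}
#'   + 2W_{xxyy} + 2W_{xxzz} + 2W_{yyzz})/5.}
#'
#' @param W a [KurtosisTensor-class].
#' @return MKT (dimensionless).
#' @export
mktTrace <- function(W) {
    stopifnot(is(W, "KurtosisTensor"))
    a <- W@tensor
    (a[1, 1, 1, 1] + a[2, 2, 2, 2] + a[3, 3, 3, 3] +
     2 * a[1, 1, 2, 2] + 2 * a[1, 1, 3, 3] + 2 * a[2, 2, 3, 3]) / 5
}

#' @describeIn DiffusionTensor-class compact display
#' @param object a DiffusionTensor
#' @export
setMethod("show", "DiffusionTensor", function(object) {
    cat("DiffusionTensor (um^2/ms), MD =",
        format(meanDiffusivity(object), digits = 6), "\n")
    print(object@tensor)
})

#' @describeIn KurtosisTensor-class compact display
#' @param object a KurtosisTensor
#' @export
setMethod("show", "KurtosisTensor", function(object) {
    cat("KurtosisTensor (dimensionless), MKT =",
        format(mktTrace(object), digits = 6), "\n")
    u <- c(xxxx = object@tensor[1, 1, 1, 1], yyyy = object@tensor[2, 2, 2, 2],
           zzzz = object@tensor[3, 3, 3, 3], xxyy = object@tensor[1, 1, 2, 2],
           xxzz = object@tensor[1, 1, 3, 3], yyzz = object@tensor[2, 2, 3, 3])
    print(round(u, 6))
})

#' Extract the tensor components as a base array
#'
#' @param x a [DiffusionTensor-class] or [KurtosisTensor-class].
#' @return The underlying numeric matrix/array.
#' @export
tensorArray <- function(x) {
    stopifnot(is(x, "DiffusionTensor") || is(x, "KurtosisTensor"))
    x@tensor
}
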