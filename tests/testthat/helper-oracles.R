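# Independent oracles kept deliberately naive: explicit index loops and
# quadrature, never reusing the package's closed forms.

# 81-term brute-force contraction n_i n_j n_k n_l W_ijkl
bruteApparentKurtosis <- function(Warr, n) {
  acc <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    acc <- acc + n[i] * n[j] * n[k] * n[l] * Warr[i, j, k, l]
  acc
}

# brute-force quadratic form n' D n
bruteQuadraticForm <- function(Dm, n) {
  acc <- 0
  for (i in 1:3) for (j in 1:3) acc <- acc + n[i] * n[j] * Dm[i, j]
  acc
}

# random fully symmetric rank-4 tensor (returns the package class plus the
# raw array for the oracles)
randomSymmetricW <- function() {
  a <- array(rnorm(81), dim = c(3, 3, 3, 3))
  W <- kurtosisTensor(a)
  list(W = W, arr = tensorArray(W))
}

# random symmetric positive semidefinite rank-2 tensor with MD ~ tissue scale
randomPSD <- function(scale = 0.6) {
  m <- matrix(rnorm(9, sd = scale), 3)
  diffusionTensor(crossprod(m) / 3)
}

# quasi-uniform points on the sphere (Fibonacci lattice)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# noiseless 19-signal vector for (D, W) under a scheme, via predictSignal
noiselessSignals <- function(scheme, D, W, s0 = 1) {
  b <- bValues(scheme)
  dirs <- schemeDirections(scheme)
  c(s0,
    apply(dirs, 1, function(n) predictSignal(s0, b[2], n, D, W)),
    apply(dirs, 1, function(n) predictSignal(s0, b[3], n, D, W)))
}

# Dice overlap of two binary masks
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# explicit two-way sum-of-squares decomposition (ICC oracle)
bruteTwoWayICC <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  ssr <- ssc <- sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + g)^2
  }
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - g)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# small default phantom shared by pipeline tests (cheap to rebuild)
defaultTruth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantom(phantomSpec())
    cache
  }
})
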