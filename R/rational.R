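## Exact integer arithmetic helpers.
##
## Cone computations (double description, Fourier-Motzkin) must be exact so
## that flux patterns (signs) are extracted without rounding artifacts. All
## such computations run on integer-valued doubles; vectors are kept primitive
## (divided by their gcd) and an overflow guard aborts rather than losing
## exactness silently.

.INT_MAX_SAFE <- 2^53

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

## gcd of a numeric vector of integers (0 for the zero vector)
.gcdVec <- function(v) {
  g <- 0
  for (x in v) {
    if (x != 0) g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

.checkOverflow <- function(v) {
  if (any(abs(v) >= .INT_MAX_SAFE)) {
    stop("exact integer arithmetic overflow (coefficients exceeded 2^53); ",
         "the instance is too ill-conditioned for exact enumeration",
         call. = FALSE)
  }
  v
}

## divide an integer vector by its gcd; optionally normalize sign so the
## first nonzero entry is positive
.primitive <- function(v, signNormalize = FALSE) {
  g <- .gcdVec(v)
  if (g > 1) v <- v / g
  if (signNormalize) {
    nz <- which(v != 0)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
  }
  v
}

## continued-fraction rational approximation of a single number
.ratApprox <- function(x, tol = 1e-9, maxDen = 1e9) {
  if (x == 0) return(c(0, 1))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > maxDen) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h / k) < tol * max(1, abs(x))) break
    if (abs(b - a) < 1e-15) break
    b <- 1 / (b - a)
  }
  c(sign * h1, k1)
}

## scale each row of a numeric matrix to integers (mass balances are
## invariant to row scaling); returns an integer-valued matrix
.integerizeRows <- function(S, tol = 1e-9) {
  out <- S
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    nz <- which(row != 0)
    if (!length(nz)) next
    dens <- vapply(row[nz], function(x) .ratApprox(x, tol)[2], numeric(1))
    l <- 1
    for (d in dens) {
      l <- l / .gcd2(l, d) * d
      if (l >= .INT_MAX_SAFE) stop("row denominator lcm overflow")
    }
    r <- round(row * l)
    if (any(abs(row * l - r) > 1e-6 * pmax(1, abs(r)))) {
      stop("could not rationalize stoichiometric row ", i)
    }
    out[i, ] <- .primitive(r)
  }
  .checkOverflow(out)
  out
}
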