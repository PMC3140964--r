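# Exact rational arithmetic on parallel numerator/denominator arrays.
#
# Stoichiometric coefficients in the shipped fixtures are small rationals, so
# all values stay far below 2^53 and double-precision integers behave exactly.
# Every structural decision in the package (rank, nullity, elementarity,
# nullspace rays) is made with these helpers, never with floating point.

# elementwise gcd of two nonnegative integer vectors
vgcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(nz <- b != 0)) {
    r <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b[nz] <- r
  }
  a
}

# canonicalize: den > 0, gcd(num, den) == 1, 0 represented as 0/1
frac_reduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational arithmetic")
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- vgcd(num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  if (any(abs(num) >= 2^53) || any(den >= 2^53)) {
    stop("rational arithmetic overflow (coefficient growth beyond 2^53)")
  }
  list(num = num, den = den)
}

frac_add <- function(n1, d1, n2, d2) frac_reduce(n1 * d2 + n2 * d1, d1 * d2)
frac_sub <- function(n1, d1, n2, d2) frac_reduce(n1 * d2 - n2 * d1, d1 * d2)
frac_mul <- function(n1, d1, n2, d2) frac_reduce(n1 * n2, d1 * d2)
frac_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("division by zero in rational arithmetic")
  frac_reduce(n1 * d2, d1 * n2)
}

# convert numeric vector with simple decimal entries (e.g. 0.5, 2, -1.25) to
# exact fractions; denominators are powers of 10 up to 1e6
frac_from_numeric <- function(x, max_den = 1e6) {
  den <- rep(1, length(x))
  num <- x
  bad <- abs(num - round(num)) > 1e-9
  while (any(bad)) {
    den[bad] <- den[bad] * 10
    num[bad] <- x[bad] * den[bad]
    if (any(den > max_den)) stop("coefficient is not a simple decimal fraction")
    bad <- abs(num - round(num)) > 1e-9
  }
  frac_reduce(round(num), den)
}

# rational matrix: list(num, den) of equal-dim matrices
rmat <- function(x) {
  x <- as.matrix(x)
  f <- frac_from_numeric(as.vector(x))
  list(num = matrix(f$num, nrow(x)), den = matrix(f$den, nrow(x)))
}

rmat_to_numeric <- function(r) r$num / r$den

# reduced row echelon form by fraction-exact Gauss-Jordan elimination.
# Returns list(num, den, pivots = column index per pivot row, rank).
rat_rref <- function(r) {
  num <- r$num
  den <- r$den
  m <- nrow(num)
  n <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(num[row:m, col] != 0)
    if (length(sel) == 0) next
    p <- row + sel[1] - 1L
    if (p != row) {
      num[c(row, p), ] <- num[c(p, row), ]
      den[c(row, p), ] <- den[c(p, row), ]
    }
    # scale pivot row to 1
    sc <- frac_div(num[row, ], den[row, ], num[row, col], den[row, col])
    num[row, ] <- sc$num
    den[row, ] <- sc$den
    # eliminate in all other rows
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      f <- frac_mul(rep(num[i, col], n), rep(den[i, col], n), num[row, ], den[row, ])
      z <- frac_sub(num[i, ], den[i, ], f$num, f$den)
      num[i, ] <- z$num
      den[i, ] <- z$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

rat_rank <- function(r) rat_rref(r)$rank

# exact rational nullspace basis of a matrix (columns = basis vectors).
# Free variables are set to 1 one at a time, pivot variables solved from rref.
rat_nullspace <- function(r) {
  n <- ncol(r$num)
  rr <- rat_rref(r)
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  if (length(free) == 0) {
    return(list(num = matrix(0, n, 0), den = matrix(1, n, 0)))
  }
  bn <- matrix(0, n, length(free))
  bd <- matrix(1, n, length(free))
  for (k in seq_along(free)) {
    fc <- free[k]
    bn[fc, k] <- 1
    for (i in seq_along(piv)) {
      # pivot variable = -rref[i, fc]
      bn[piv[i], k] <- -rr$num[i, fc]
      bd[piv[i], k] <- rr$den[i, fc]
    }
  }
  frac_mat_reduce(list(num = bn, den = bd))
}

frac_mat_reduce <- function(r) {
  f <- frac_reduce(as.vector(r$num), as.vector(r$den))
  list(num = matrix(f$num, nrow(r$num)), den = matrix(f$den, nrow(r$num)))
}

# scale a rational vector so its smallest nonzero absolute entry equals 1
# (the canonical normalization used for flux modes); exact.
rat_normalize_min1 <- function(num, den) {
  nz <- which(num != 0)
  if (length(nz) == 0) return(list(num = num, den = den))
  # find min |num/den| among nonzero: compare a/b vs c/d via a*d vs c*b
  best <- nz[1]
  for (i in nz[-1]) {
    if (abs(num[i]) * den[best] < abs(num[best]) * den[i]) best <- i
  }
  frac_div(num, den, rep(abs(num[best]), length(num)), rep(den[best], length(num)))
}
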