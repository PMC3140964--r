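# Dense two-phase primal simplex with Bland's rule.
#
# All linear programs in this package are small (tens of rows and columns),
# well scaled, and have rational data, so a plain dense tableau with Bland's
# anti-cycling rule is both fast enough and fully deterministic: the same
# input always yields the same optimal basis, which the enumeration engines
# rely on for reproducible witness fluxes. Structural conclusions that must
# be exact (elementarity, nullity) are never drawn from the simplex; they go
# through the rational-arithmetic layer.

.lp_tol <- 1e-9

# minimize costs %*% x  s.t.  tableau rows (basis-canonical)  x >= 0
simplex_iterate <- function(tab, basis, costs, max_iter = 20000L) {
  m <- nrow(tab)
  N <- ncol(tab) - 1L
  for (iter in seq_len(max_iter)) {
    rc <- costs - as.vector(costs[basis] %*% tab[, seq_len(N), drop = FALSE])
    enter <- which(rc < -.lp_tol)
    if (length(enter) == 0) {
      return(list(status = "optimal", tab = tab, basis = basis))
    }
    j <- min(enter) # Bland
    col <- tab[, j]
    pos <- which(col > .lp_tol)
    if (length(pos) == 0) {
      return(list(status = "unbounded", tab = tab, basis = basis))
    }
    ratio <- tab[pos, N + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + .lp_tol]
    i <- cand[which.min(basis[cand])] # Bland on ties
    # pivot on (i, j)
    tab[i, ] <- tab[i, ] / tab[i, j]
    other <- setdiff(seq_len(m), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
    }
  stop("simplex iteration limit exceeded")
}

#' @noRd
# Solve min/max c'x s.t. A x = b, x >= 0. Returns status, x, value.
lp_solve <- function(obj, A, b, dir = c("min", "max")) {
  dir <- match.arg(dir)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n)
  if (dir == "max") obj <- -obj
  # make rhs nonnegative
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  costs1 <- c(rep(0, n), rep(1, m))
  r1 <- simplex_iterate(tab, basis, costs1)
  if (r1$status != "optimal") stop("phase-1 simplex failed") # cannot be unbounded
  obj1 <- sum(costs1[r1$basis] * r1$tab[, n + m + 1L])
  if (obj1 > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  tab <- r1$tab
  basis <- r1$basis
  # drive remaining artificials out of the basis
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(tab[i, seq_len(n)]) > .lp_tol)
      if (length(piv) == 0) {
        drop_rows <- c(drop_rows, i) # redundant constraint
      } else {
        j <- min(piv)
        tab[i, ] <- tab[i, ] / tab[i, j]
        other <- setdiff(seq_len(m), i)
        tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
        basis[i] <- j
      }
    }
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE] # strip artificials
  r2 <- simplex_iterate(tab, basis, obj)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = if (dir == "max") Inf else -Inf))
  }
  x <- numeric(n)
  x[r2$basis] <- r2$tab[, n + 1L]
  x[abs(x) < .lp_tol] <- 0
  value <- sum(obj * x)
  list(status = "optimal", x = x, value = if (dir == "max") -value else value)
}

# Flux LP over the columns of a stoichiometric matrix S (rows already
# restricted to internal metabolites). Supports forced-zero columns, lower
# bounds (via substitution), extra equality and <= rows, and an objective
# over named columns. Returns full named flux vector.
lp_flux <- function(S, obj = NULL, lower = NULL, zero = NULL,
                    eq = NULL, le = NULL, dir = "min") {
  cols <- colnames(S)
  keep <- setdiff(cols, zero)
  A <- S[, keep, drop = FALSE]
  b <- rep(0, nrow(A))
  rows_eq <- NULL
  b_eq <- NULL
  if (!is.null(eq)) {
    # coefficients on dropped (zero) columns simply vanish
    rows_eq <- eq$A[, keep, drop = FALSE]
    b_eq <- eq$b
  }
  nslack <- 0L
  rows_le <- NULL
  b_le <- NULL
  if (!is.null(le)) {
    rows_le <- le$A[, keep, drop = FALSE]
    b_le <- le$b
    nslack <- nrow(rows_le)
  }
  Afull <- rbind(A, rows_eq, rows_le)
  bfull <- c(b, b_eq, b_le)
  if (nslack > 0) {
    slack <- rbind(matrix(0, nrow(A) + length(b_eq), nslack), diag(nslack))
    Afull <- cbind(Afull, slack)
  }
  # lower bounds: x = l + u, u >= 0
  l <- rep(0, length(keep))
  names(l) <- keep
  if (!is.null(lower)) {
    lw <- lower[names(lower) %in% keep]
    l[names(lw)] <- lw
  }
  if (any(l != 0)) {
    bfull <- bfull - as.vector(Afull[, seq_along(keep), drop = FALSE] %*% l)
  }
  cvec <- rep(0, ncol(Afull))
  if (!is.null(obj)) {
    ob <- obj[names(obj) %in% keep]
    cvec[match(names(ob), keep)] <- ob
  }
  res <- lp_solve(cvec, Afull, bfull, dir = dir)
  if (res$status != "optimal") {
    return(list(status = res$status, flux = NULL, value = res$value))
  }
  u <- res$x[seq_along(keep)]
  v <- numeric(length(cols))
  names(v) <- cols
  v[keep] <- u + l
  # objective value must account for the lower-bound offset
  value <- if (is.null(obj)) 0 else {
    ob <- obj[names(obj) %in% cols]
    sum(ob * v[names(ob)])
  }
  list(status = "optimal", flux = v, value = value)
}
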