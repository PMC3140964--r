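# Exhaustive elementary flux mode enumeration for small networks.
#
# The flux cone {v : N v = 0, v >= 0} of a fully irreversible network is
# pointed, and its extreme rays are exactly the elementary flux modes. They
# are enumerated by the double description method run in the nullspace of N
# with exact rational arithmetic throughout: the algorithm starts from a
# rational nullspace basis (a lineality space) and intersects with one
# nonnegativity halfspace per reaction, using the combinatorial adjacency
# test on zero sets. This module is deliberately tuned for correctness, not
# scale - it is the ground truth the optimization engines are tested against.

frac_vec_sub_scaled <- function(an, ad, bn, bd, fn, fd) {
  # a - f * b elementwise, exact
  s <- frac_mul(rep(fn, length(bn)), rep(fd, length(bn)), bn, bd)
  frac_sub(an, ad, s$num, s$den)
}

ray_zero_set <- function(r) which(r$num == 0)

#' Enumerate all elementary flux modes of a small network
#'
#' @param net a `metnet` with only irreversible reactions (use
#'   [split_reversible()] first)
#' @param max_cols refuse networks with more reaction columns than this;
#'   exhaustive enumeration is only meant for small networks. Larger systems
#'   should be analyzed with [enumerate_efps()] or [k_shortest()].
#' @param drop_futile drop two-cycles consisting of both directions of a
#'   split reversible reaction (the default); these are spurious modes
#'   introduced by the splitting.
#' @return list of `flux_mode` objects, each with elements `flux` (named
#'   numeric, normalized so the smallest nonzero entry is 1), `support`
#'   (character), and `elementary = TRUE`. Sorted by support size, then
#'   lexicographically by support.
#' @export
enumerate_efms <- function(net, max_cols = 32L, drop_futile = TRUE) {
  if (any(vapply(net$reactions, `[[`, logical(1), "reversible"))) {
    stop("network has reversible reactions; apply split_reversible() first")
  }
  S <- stoich_matrix(net)
  n <- ncol(S)
  if (n > max_cols) {
    stop("network has ", n, " columns, above the exhaustive-enumeration cap of ",
         max_cols, "; use the optimization engines (enumerate_efps, k_shortest)")
  }
  R <- rmat(S)
  lineality <- rat_nullspace(R) # columns are basis vectors of the nullspace
  q <- ncol(lineality$num)
  lin <- lapply(seq_len(q), function(j) list(num = lineality$num[, j], den = lineality$den[, j]))
  rays <- list()
  for (i in seq_len(n)) { # impose v_i >= 0
    if (length(lin) > 0) {
      li <- which(vapply(lin, function(l) l$num[i] != 0, logical(1)))
      if (length(li) > 0) {
        lstar <- lin[[li[1]]]
        if (lstar$num[i] < 0) lstar <- list(num = -lstar$num, den = lstar$den)
        reduce <- function(v) {
          if (v$num[i] == 0) return(v)
          f <- frac_div(v$num[i], v$den[i], lstar$num[i], lstar$den[i])
          frac_vec_sub_scaled(v$num, v$den, lstar$num, lstar$den, f$num, f$den)
        }
        lin <- lapply(lin[-li[1]], reduce)
        rays <- lapply(rays, reduce)
        rays <- c(rays, list(lstar))
        next
      }
    }
    vi <- vapply(rays, function(r) r$num[i] / r$den[i], numeric(1))
    if (length(rays) == 0 || all(vi >= 0)) next
    Ppos <- rays[vi > 0]
    Z <- rays[vi == 0]
    Nneg <- rays[vi < 0]
    zero_sets <- lapply(rays, ray_zero_set)
    newr <- list()
    for (p in Ppos) {
      for (ng in Nneg) {
        zp <- which(p$num == 0)
        zn <- which(ng$num == 0)
        zz <- intersect(zp, zn)
        # adjacency: no third ray's zero set contains Z(p) n Z(n)
        adjacent <- TRUE
        for (k in seq_along(rays)) {
          z <- zero_sets[[k]]
          if (length(z) >= length(zz) && all(zz %in% z) &&
              !identical(z, zp) && !identical(z, zn)) {
            adjacent <- FALSE
            break
          }
        }
        if (!adjacent) next
        # combine: (-n_i) * p + (p_i) * n, i-th coordinate becomes 0
        a <- frac_mul(rep(-ng$num[i], length(p$num)), rep(ng$den[i], length(p$num)),
                      p$num, p$den)
        b <- frac_mul(rep(p$num[i], length(p$num)), rep(p$den[i], length(p$num)),
                      ng$num, ng$den)
        s <- frac_add(a$num, a$den, b$num, b$den)
        nm <- rat_normalize_min1(s$num, s$den)
        newr <- c(newr, list(nm))
      }
    }
    rays <- c(Ppos, Z, newr)
  }
  if (length(lin) > 0) stop("flux cone is not pointed; network is inconsistent")
  # normalize, deduplicate, optionally drop futile split-direction 2-cycles
  pairs <- split_pairs(net)
  cols <- colnames(S)
  modes <- list()
  seen <- character(0)
  for (r in rays) {
    nm <- rat_normalize_min1(r$num, r$den)
    supp <- cols[nm$num != 0]
    if (drop_futile && !is.null(pairs) && length(supp) == 2 &&
        any(apply(pairs, 1, function(pr) setequal(pr, supp)))) next
    key <- paste(supp, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    flux <- stats::setNames(nm$num / nm$den, cols)
    modes[[length(modes) + 1]] <- structure(
      list(flux = flux, exact = stats::setNames(nm$num / nm$den, cols),
           support = supp, elementary = TRUE),
      class = "flux_mode")
  }
  order_modes(modes)
}

order_modes <- function(modes) {
  if (length(modes) == 0) return(modes)
  keys <- vapply(modes, function(m) paste(sort(m$support), collapse = "|"), character(1))
  sizes <- vapply(modes, function(m) length(m$support), integer(1))
  modes[order(sizes, keys)]
}

#' @export
print.flux_mode <- function(x, ...) {
  cat("flux mode over", length(x$support), "reactions:\n")
  v <- x$flux[x$support]
  cat(paste0("  ", names(v), " = ", format(v)), sep = "\n")
  invisible(x)
}

#' Test whether a steady-state flux vector is elementary
#'
#' A nonnegative steady-state flux is elementary iff the submatrix of N
#' restricted to its support has nullity exactly 1 (the rank test). The test
#' is performed in exact rational arithmetic.
#'
#' @param net a `metnet` with only irreversible reactions
#' @param flux named numeric flux vector (nonnegative, steady state)
#' @return logical
#' @export
is_elementary <- function(net, flux) {
  S <- stoich_matrix(net)
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  v[names(flux)] <- flux
  if (any(v < 0)) stop("flux vector has negative entries")
  supp <- names(v)[v != 0]
  if (length(supp) == 0) stop("zero vector is not a flux mode")
  resid <- S %*% v
  if (max(abs(resid)) > 1e-8) stop("flux vector is not at steady state")
  sub <- rmat(S[, supp, drop = FALSE])
  nullity <- length(supp) - rat_rank(sub)
  nullity == 1
}

#' Project flux modes onto a subsystem
#'
#' Returns the set of distinct nonempty intersections of mode supports with
#' the subsystem: the complete flux-pattern universe of the subsystem when
#' the mode list is complete.
#'
#' @param modes list of `flux_mode`
#' @param sub a [subsystem()]
#' @return list of character vectors (sorted), canonically ordered
#' @export
project_patterns <- function(modes, sub) {
  pats <- lapply(modes, function(m) sort(intersect(m$support, sub$ids)))
  pats <- pats[vapply(pats, length, integer(1)) > 0]
  pats <- unique(pats)
  keys <- vapply(pats, paste, character(1), collapse = "|")
  pats[order(lengths(pats), keys)]
}

# union-irreducible elements of a family of sets: those not expressible as
# the union of other members (each a strict subset)
union_irreducible <- function(sets) {
  if (length(sets) <= 1) return(sets)
  keep <- logical(length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    subs <- sets[vapply(sets, function(t) length(t) < length(s) && all(t %in% s), logical(1))]
    covered <- length(subs) > 0 && setequal(unique(unlist(subs)), s)
    keep[i] <- !covered
  }
  sets[keep]
}
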