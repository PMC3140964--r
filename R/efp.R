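# Elementary flux pattern enumeration over a subsystem.
#
# A set S of subsystem reactions is a flux pattern if some whole-network
# steady-state flux v >= 0 is positive exactly on S within the subsystem.
# Flux patterns are closed under union; the elementary (union-irreducible)
# ones generate the lattice. The engine decides pattern-hood with one LP
# feasibility query per candidate member set, scanning candidates in
# cardinality order (smallest first, ties broken lexicographically), and
# post-filters the union-reducible sets. Each surviving pattern carries a
# support-minimized, rank-certified witness mode of the entire network.
#
# Split-direction handling: a candidate containing both directions of a
# split reversible reaction is rejected a priori, and when a subsystem
# member's opposite direction lies outside the subsystem that opposite
# direction is forced to zero in the query - otherwise the futile
# two-cycle would make any split member trivially "usable".

check_split_net <- function(net) {
  if (any(vapply(net$reactions, `[[`, logical(1), "reversible"))) {
    stop("network has reversible reactions; apply split_reversible() first")
  }
}

# partner map: for each split direction, the id of its opposite direction
partner_map <- function(net) {
  pairs <- split_pairs(net)
  pm <- character(0)
  if (!is.null(pairs)) {
    pm <- stats::setNames(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  }
  pm
}

# LP feasibility for "pattern = members within sub"; returns NULL or a flux
pattern_flux <- function(S, sub_ids, members, pm, minimize = TRUE) {
  forbidden <- setdiff(sub_ids, members)
  partners <- unname(pm[members[members %in% names(pm)]])
  zero <- union(forbidden, setdiff(partners, members))
  lower <- stats::setNames(rep(1, length(members)), members)
  obj <- stats::setNames(rep(1, ncol(S)), colnames(S))
  res <- lp_flux(S, obj = if (minimize) obj else NULL,
                 lower = lower, zero = zero, dir = "min")
  if (res$status != "optimal") return(NULL)
  cancel_futile(res$flux, pm)
}

# cancel futile two-cycles on split pairs (both directions positive)
cancel_futile <- function(flux, pm) {
  for (r in intersect(names(flux)[flux > 0], names(pm))) {
    p <- pm[[r]]
    if (p %in% names(flux) && flux[r] > 0 && flux[p] > 0) {
      m <- min(flux[r], flux[p])
      flux[r] <- flux[r] - m
      flux[p] <- flux[p] - m
    }
  }
  flux
}

#' Enumerate elementary flux patterns of a subsystem
#'
#' Finds every flux pattern of the subsystem that cannot be written as a
#' union of other flux patterns. Each returned pattern carries a witness:
#' an elementary flux mode of the entire network whose subsystem support
#' equals the pattern exactly.
#'
#' @param net a `metnet` with only irreversible reactions
#' @param sub a [subsystem()]
#' @return list of `flux_pattern` objects (fields `members`, `witness`,
#'   `elementary`), ordered by pattern size then lexicographically
#' @export
enumerate_efps <- function(net, sub) {
  check_split_net(net)
  S <- stoich_matrix(net)
  pm <- partner_map(net)
  k <- length(sub$ids)
  ids <- sort(sub$ids)
  patterns <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(ids, size, simplify = FALSE)
    for (members in combos) {
      if (any(members %in% names(pm) & unname(pm[members]) %in% members)) next
      if (!is.null(pattern_flux(S, sub$ids, members, pm, minimize = FALSE))) {
        patterns <- c(patterns, list(members))
      }
    }
  }
  elem <- union_irreducible(patterns)
  out <- lapply(elem, function(members) {
    w <- witness_mode(net, flux_pattern(sub, members))
    flux_pattern(sub, members, witness = w)
  })
  keys <- vapply(out, function(p) paste(p$members, collapse = "|"), character(1))
  out[order(lengths(lapply(out, `[[`, "members")), keys)]
}

#' Construct a flux pattern object
#'
#' @param sub a [subsystem()]
#' @param members subsystem reaction ids forming the pattern
#' @param witness optional witness `flux_mode`
#' @param elementary union-irreducibility status
#' @export
flux_pattern <- function(sub, members, witness = NULL, elementary = TRUE) {
  stopifnot(all(members %in% sub$ids))
  structure(list(subsystem = sub, members = sort(members),
                 witness = witness, elementary = elementary),
            class = "flux_pattern")
}

#' @export
print.flux_pattern <- function(x, ...) {
  cat("flux pattern {", paste(x$members, collapse = ", "), "}",
      if (!is.null(x$witness)) sprintf(" (witness over %d reactions)",
                                       length(x$witness$support)) else "", "\n",
      sep = "")
  invisible(x)
}

#' Does a flux pattern with the given required/forbidden reactions exist?
#'
#' Single feasibility query: is there a steady-state flux whose subsystem
#' support includes all `required` and none of the `forbidden` reactions?
#'
#' @param net a `metnet` with only irreversible reactions
#' @param sub a [subsystem()]
#' @param required,forbidden subsystem reaction ids
#' @return logical
#' @export
pattern_exists <- function(net, sub, required = character(0),
                           forbidden = character(0)) {
  check_split_net(net)
  stopifnot(all(c(required, forbidden) %in% sub$ids))
  S <- stoich_matrix(net)
  pm <- partner_map(net)
  partners <- unname(pm[required[required %in% names(pm)]])
  zero <- union(forbidden, setdiff(partners, required))
  lower <- stats::setNames(rep(1, length(required)), required)
  res <- lp_flux(S, lower = lower, zero = zero)
  res$status == "optimal"
}

#' Extract a witness elementary mode for a flux pattern
#'
#' Solves a linear program for a whole-network steady-state flux whose
#' subsystem support equals the pattern, then reduces the support to
#' elementarity (certified by the exact rank test) by repeatedly testing
#' single-reaction removals outside the pattern.
#'
#' @param net a `metnet` with only irreversible reactions
#' @param pattern a [flux_pattern()]
#' @return a `flux_mode`
#' @export
witness_mode <- function(net, pattern) {
  check_split_net(net)
  S <- stoich_matrix(net)
  pm <- partner_map(net)
  sub_ids <- pattern$subsystem$ids
  members <- pattern$members
  forbidden <- setdiff(sub_ids, members)
  partners <- unname(pm[members[members %in% names(pm)]])
  zero <- union(forbidden, setdiff(partners, members))
  mode <- minimal_mode(net, S, pm, lower = stats::setNames(rep(1, length(members)), members),
                       zero = zero, keep = members)
  if (is.null(mode)) stop("input is not a flux pattern (no witness flux exists)")
  mode
}

# Find a support-minimal steady-state flux satisfying lower bounds and
# zeros; reduce by testing removal of one support reaction at a time
# (lexicographic), re-solving a min-total-flux LP each round. The result is
# certified elementary by the exact rank test.
minimal_mode <- function(net, S, pm, lower, zero, keep) {
  obj <- stats::setNames(rep(1, ncol(S)), colnames(S))
  res <- lp_flux(S, obj = obj, lower = lower, zero = zero, dir = "min")
  if (res$status != "optimal") return(NULL)
  flux <- cancel_futile(res$flux, pm)
  # Reduce until the support is a single elementary mode: as long as the
  # exact rank test rejects the current support, force support members to
  # zero one at a time (lexicographic) wherever the constrained system
  # stays feasible. The forced-zero set only grows, so the loop terminates.
  flux_exact <- NULL
  repeat {
    supp <- names(flux)[flux > 1e-9]
    flux_exact <- rationalize_flux(S, supp)
    if (!is.null(flux_exact)) break
    removable <- sort(setdiff(supp, keep))
    improved <- FALSE
    for (r in removable) {
      res2 <- lp_flux(S, obj = obj, lower = lower, zero = union(zero, r), dir = "min")
      if (res2$status == "optimal") {
        flux <- cancel_futile(res2$flux, pm)
        zero <- union(zero, r)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  if (is.null(flux_exact)) {
    stop("support reduction failed to reach an elementary mode")
  }
  supp <- names(flux)[flux > 1e-9]
  structure(list(flux = flux_exact, support = supp, elementary = TRUE),
            class = "flux_mode")
}

# Given a support believed elementary, recover the exact rational flux by
# a nullspace computation; returns NULL if the support is not elementary
# or the kernel vector is not strictly positive on it.
rationalize_flux <- function(S, supp) {
  sub <- rmat(S[, supp, drop = FALSE])
  ns <- rat_nullspace(sub)
  if (ncol(ns$num) != 1) return(NULL)
  v <- rat_normalize_min1(ns$num[, 1], ns$den[, 1])
  x <- v$num / v$den
  if (any(x < 0)) {
    if (all(x <= 0)) x <- -x else return(NULL)
  }
  if (any(x == 0)) return(NULL)
  out <- stats::setNames(numeric(ncol(S)), colnames(S))
  out[supp] <- x
  out
}
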