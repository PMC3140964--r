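# Small networks and independent oracles shared across tests.

# linear chain: A_in -> A -> B -> B_out
chain_net <- function() {
  metnet(
    data.frame(id = c("A", "B")),
    list(
      reaction("A_in", c(A = 1)),
      reaction("AtoB", c(A = -1, B = 1)),
      reaction("B_out", c(B = -1))
    )
  )
}

# diamond: source -> S, two parallel branches S -> P, sink P ->
diamond_net <- function() {
  metnet(
    data.frame(id = c("S", "P")),
    list(
      reaction("S_in", c(S = 1)),
      reaction("branch1", c(S = -1, P = 1)),
      reaction("branch2", c(S = -1, P = 1)),
      reaction("P_out", c(P = -1))
    )
  )
}

# toy 2-cycle that produces ATP unconditionally: blocking the producing
# column makes the ATPase flux bounded (zero)
futile_atp_net <- function() {
  metnet(
    data.frame(id = c("atp", "adp")),
    list(
      reaction("PUMP", c(adp = -1, atp = 1)),
      reaction("ATPASE", c(atp = -1, adp = 1))
    )
  )
}

mode_support_keys <- function(modes) {
  sort(vapply(modes, function(m) paste(sort(m$support), collapse = "|"), character(1)))
}

pattern_keys <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
}

# Independent oracle: enumerate elementary flux modes by naive support
# lattice search - for every subset of columns, keep supports whose
# submatrix has nullity one and a strictly positive kernel vector on the
# support. Exponential; only for networks with <= 12 columns.
naive_efms <- function(net) {
  S <- stoich_matrix(net)
  n <- ncol(S)
  stopifnot(n <= 12)
  ids <- colnames(S)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    supp <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    flux <- fluxpattern:::rationalize_flux(S, supp)
    if (!is.null(flux)) out[[length(out) + 1]] <- list(support = supp, flux = flux)
  }
  # keep support-minimal ones only
  keep <- vapply(seq_along(out), function(i) {
    si <- out[[i]]$support
    !any(vapply(seq_along(out), function(j) {
      j != i && length(out[[j]]$support) < length(si) && all(out[[j]]$support %in% si)
    }, logical(1)))
  }, logical(1))
  out[keep]
}

expect_steady_nonneg <- function(net, flux) {
  S <- stoich_matrix(net)
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  v[names(flux)] <- flux
  expect_true(all(v >= 0))
  expect_lt(max(abs(S %*% v)), 1e-8)
}

# canonical pathway-7 / pathway-14 route reaction sets on the
# cofactor-carrying ketogenesis fixture
route_p7 <- function() {
  c("EX_in_accoa_m", "ACAT", "HMGS", "HMGL", "ADC", "CYP2E1", "ACDH", "MGDH",
    "PYRT", "PC", "PEPCK", "GNGL", "UPPERR", "EX_out_coa_m")
}
route_p14 <- function() {
  c("EX_in_accoa_m", "ACAT", "HMGS", "HMGL", "ADC", "CYP2E1", "AKRED", "MGDH",
    "PYRT", "PC", "PEPCK", "GNGL", "UPPERR", "EX_out_coa_m")
}
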