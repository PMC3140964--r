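test_that("network construction validates ids and stoichiometries", {
  expect_error(
    metnet(data.frame(id = c("A", "A")), list(reaction("r", c(A = 1)))),
    "duplicate metabolite")
  expect_error(
    metnet(data.frame(id = "A"),
           list(reaction("r", c(A = 1)), reaction("r", c(A = -1)))),
    "duplicate reaction")
  expect_error(
    metnet(data.frame(id = "A"), list(reaction("r", c(B = 1)))),
    "unknown metabolites")
  expect_error(
    metnet(data.frame(id = "A"), list(reaction("r", c(A = 0)))),
    "zero coefficients")
})

test_that("stoichiometric matrix reflects declared stoichiometries", {
  net <- chain_net()
  S <- stoich_matrix(net)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["A", "A_in"], 1)
  expect_equal(S["A", "AtoB"], -1)
  expect_equal(S["B", "AtoB"], 1)
  # external metabolites impose no constraint
  net$metabolites$external[net$metabolites$id == "B"] <- TRUE
  expect_equal(rownames(stoich_matrix(net)), "A")
  expect_equal(nrow(stoich_matrix(net, internal_only = FALSE)), 2)
})

test_that("splitting reversible reactions yields exact negated pairs", {
  net <- chain_net()
  expect_identical(reaction_ids(split_reversible(net)), reaction_ids(net))

  net2 <- metnet(
    data.frame(id = c("A", "B")),
    list(reaction("A_in", c(A = 1)),
         reaction("AB", c(A = -1, B = 1), reversible = TRUE),
         reaction("B_out", c(B = -1))))
  sp <- split_reversible(net2)
  S <- stoich_matrix(sp)
  expect_equal(ncol(S), 4)
  expect_equal(S[, "AB_f"], -S[, "AB_b"])
  expect_equal(sp$reactions[["AB_f"]]$origin, "AB")
  expect_false(any(vapply(sp$reactions, `[[`, logical(1), "reversible")))

  # column count after split = irreversible + 2 x reversible
  g <- build_glycolysis_ppp()
  nrev <- sum(vapply(g$reactions, `[[`, logical(1), "reversible"))
  expect_equal(length(split_reversible(g)$reactions),
               length(g$reactions) + nrev)
})

test_that("boundary reactions are added deterministically", {
  net <- chain_net()
  out <- add_boundary(net, inflows = "B", outflows = c("A", "B"))
  expect_setequal(setdiff(reaction_ids(out), reaction_ids(net)),
                  c("EX_in_B", "EX_out_A", "EX_out_B"))
  expect_equal(out$reactions[["EX_in_B"]]$stoich, c(B = 1))
  expect_equal(out$reactions[["EX_out_B"]]$stoich, c(B = -1))
  expect_identical(reaction_ids(add_boundary(net)), reaction_ids(net))
  expect_error(add_boundary(net, inflows = "nope"), "unknown metabolites")
})

test_that("blocking reactions removes their columns and logs provenance", {
  net <- chain_net()
  expect_identical(block_reactions(net, character(0)), net)
  blocked <- block_reactions(net, "AtoB")
  expect_false("AtoB" %in% reaction_ids(blocked))
  expect_equal(attr(blocked, "blocked"), "AtoB")
  expect_error(block_reactions(net, "nope"), "unknown reactions")

  # blocking the producing column of an unconditional ATP cycle makes the
  # ATPase flux bounded at zero
  fut <- futile_atp_net()
  S <- stoich_matrix(fut)
  res <- fluxpattern:::lp_flux(S, obj = c(ATPASE = 1), dir = "max")
  expect_equal(res$status, "unbounded")
  S2 <- stoich_matrix(block_reactions(fut, "PUMP"))
  res2 <- fluxpattern:::lp_flux(S2, obj = c(ATPASE = 1), dir = "max")
  expect_equal(res2$status, "optimal")
  expect_equal(res2$value, 0)
})

test_that("split network feasibility matches the unsplit reversible system", {
  # N v = 0 with v >= 0, v != 0 exists in the split network iff the
  # reversible system admits a nonzero steady-state flux
  for (seed in 1:5) {
    net <- build_random(seed, n_modes = 2, n_mets = 5)
    sp <- split_reversible(net)
    S <- stoich_matrix(sp)
    ex <- grep("^EX_in_", colnames(S), value = TRUE)[1]
    res <- fluxpattern:::lp_flux(S, lower = stats::setNames(1, ex))
    expect_equal(res$status, "optimal")
    expect_steady_nonneg(sp, res$flux)
  }
})

test_that("subsystem construction validates membership", {
  net <- chain_net()
  sub <- subsystem(net, c("A_in", "B_out"))
  expect_equal(sub$k, 2)
  expect_error(subsystem(net, "nope"), "unknown reactions")
  expect_error(subsystem(net, character(0)), "nonempty")
})
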