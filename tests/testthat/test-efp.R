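test_that("seed subsystem of the glycolysis-PPP fixture has two patterns", {
  net <- split_reversible(build_glycolysis_ppp())
  sub <- subsystem(net, c("EX_in_glc", "EX_out_r5p"))
  pats <- enumerate_efps(net, sub)
  expect_identical(pattern_keys(lapply(pats, `[[`, "members")),
                   pattern_keys(list("EX_in_glc", c("EX_in_glc", "EX_out_r5p"))))
  # the R5P pattern's witness routes glucose through the oxidative branch
  w <- Filter(function(p) "EX_out_r5p" %in% p$members, pats)[[1]]$witness
  expect_true("G6PDH" %in% w$support)
  expect_setequal(w$support, c("EX_in_glc", "HEX1", "G6PDH", "RPI_f", "EX_out_r5p"))
})

test_that("witnesses are verified elementary modes matching their pattern", {
  net <- split_reversible(build_glycolysis_ppp())
  sub <- subsystem(net, c("EX_in_glc", "G6PDH", "EX_out_r5p"))
  pats <- enumerate_efps(net, sub)
  expect_length(pats, 3)
  for (p in pats) {
    w <- p$witness
    expect_steady_nonneg(net, w$flux)
    expect_true(is_elementary(net, w$flux))
    expect_identical(sort(intersect(w$support, sub$ids)), p$members)
  }
})

test_that("no returned pattern is a union of other returned patterns", {
  net <- split_reversible(build_glycolysis_ppp())
  subs <- list(
    subsystem(net, c("EX_in_glc", "EX_out_r5p", "G6PDH", "PFK", "FBP1")),
    subsystem(net, sort(reaction_ids(net))[1:8])
  )
  for (sub in subs) {
    pats <- lapply(enumerate_efps(net, sub), `[[`, "members")
    for (i in seq_along(pats)) {
      others <- pats[-i]
      inside <- others[vapply(others, function(s) all(s %in% pats[[i]]), logical(1))]
      if (length(inside)) {
        expect_false(setequal(unique(unlist(inside)), pats[[i]]))
      }
    }
  }
})

test_that("pattern existence queries answer the worked examples", {
  net <- split_reversible(build_glycolysis_ppp())
  sub <- subsystem(net, c("EX_in_glc", "EX_out_r5p"))
  # R5P cannot leave without glucose coming in
  expect_false(pattern_exists(net, sub, required = "EX_out_r5p",
                              forbidden = "EX_in_glc"))
  expect_true(pattern_exists(net, sub, required = c("EX_in_glc", "EX_out_r5p")))

  tca <- split_reversible(build_tca(FALSE))
  stca <- subsystem(tca, c("EX_in_accoa", "EX_out_oaa"))
  expect_false(pattern_exists(tca, stca, required = "EX_out_oaa"))
  tcag <- split_reversible(build_tca(TRUE))
  stcag <- subsystem(tcag, c("EX_in_accoa", "EX_out_oaa"))
  expect_true(pattern_exists(tcag, stcag, required = "EX_out_oaa"))
})

test_that("witness extraction works on the single-route chain", {
  net <- chain_net()
  sub <- subsystem(net, c("A_in", "B_out"))
  p <- flux_pattern(sub, c("A_in", "B_out"))
  w <- witness_mode(net, p)
  expect_setequal(w$support, reaction_ids(net))
  expect_error(witness_mode(net, flux_pattern(sub, "B_out")), "not a flux pattern")
})

test_that("engine equals union-irreducible oracle projections on fixtures and random networks", {
  cases <- list(
    list(net = split_reversible(build_tca(TRUE)),
         sub = c("EX_in_accoa", "EX_out_oaa", "ICL", "IDH")),
    list(net = split_reversible(build_ketone_acetone(FALSE)),
         sub = c("EX_in_accoa_m", "EX_out_g6p_c", "ACDH", "AKRED", "ADC"))
  )
  for (seed in 1:20) {
    rn <- split_reversible(build_random(seed, n_modes = 3, n_mets = 6))
    if (length(rn$reactions) > 20) next
    ids <- sort(reaction_ids(rn))
    cases <- c(cases, list(list(net = rn, sub = ids[seq(1, length(ids), by = 2)])))
  }
  for (case in cases) {
    net <- case$net
    sub <- subsystem(net, case$sub)
    oracle <- fluxpattern:::union_irreducible(
      project_patterns(enumerate_efms(net), sub))
    engine <- lapply(enumerate_efps(net, sub), `[[`, "members")
    expect_identical(pattern_keys(engine), pattern_keys(oracle))
  }
})

test_that("adding a reaction never removes an existing flux pattern", {
  for (seed in 1:5) {
    net <- split_reversible(build_random(seed, n_modes = 3, n_mets = 6))
    ids <- sort(reaction_ids(net))
    sub_ids <- ids[seq(1, length(ids), by = 2)]
    pats <- enumerate_efps(net, subsystem(net, sub_ids))
    # augment with a new bypass reaction between two random metabolites
    mets <- net$metabolites$id
    aug <- metnet(net$metabolites,
                  c(unname(net$reactions),
                    list(reaction("R_bypass",
                                  stats::setNames(c(-1, 1), mets[1:2])))))
    sub2 <- subsystem(aug, sub_ids)
    for (p in pats) {
      expect_true(!is.null(fluxpattern:::pattern_flux(
        stoich_matrix(aug), sub_ids, p$members,
        fluxpattern:::partner_map(aug), minimize = FALSE)))
    }
  }
})

test_that("an infeasible subsystem yields the empty pattern set", {
  net <- chain_net()
  dead <- block_reactions(net, "AtoB") # disconnects A from B
  expect_length(enumerate_efps(dead, subsystem(dead, c("A_in", "B_out"))), 0)
})
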