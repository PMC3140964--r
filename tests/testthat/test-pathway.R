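test_that("essential reactions match the worked examples", {
  net <- split_reversible(build_glycolysis_ppp())
  ess <- essential_reactions(net, "EX_in_glc", "EX_out_r5p")
  expect_true(all(c("EX_in_glc", "HEX1", "RPI_f", "EX_out_r5p") %in% ess))
  expect_false("G6PDH" %in% ess) # the non-oxidative alternative exists
  expect_false("PGI_f" %in% ess)

  kn <- split_reversible(build_ketone_acetone(FALSE))
  ess2 <- essential_reactions(kn, "EX_in_accoa_m", "EX_out_g6p_c")
  # acetoacetate decarboxylation and acetone monooxygenation lie on all routes
  expect_true(all(c("ADC", "CYP2E1", "MGDH", "PC", "PEPCK") %in% ess2))
  expect_false("ACDH" %in% ess2)
  expect_false("AKRED" %in% ess2)

  ch <- chain_net()
  expect_identical(essential_reactions(ch, "A_in", "B_out"),
                   sort(reaction_ids(ch)))
  dead <- block_reactions(ch, "AtoB")
  expect_error(essential_reactions(dead, "A_in", "B_out"), "unreachable")
})

test_that("every essential reaction appears in every oracle route", {
  nets <- list(
    list(net = split_reversible(build_glycolysis_ppp()),
         source = "EX_in_glc", target = "EX_out_r5p"),
    list(net = split_reversible(build_ketone_acetone(FALSE)),
         source = "EX_in_accoa_m", target = "EX_out_g6p_c"))
  for (seed in 1:10) {
    rn <- split_reversible(build_random(seed, 3, 6))
    tg <- grep("^EX_out_", sort(reaction_ids(rn)), value = TRUE)[1]
    src <- grep("^EX_in_", sort(reaction_ids(rn)), value = TRUE)[1]
    nets <- c(nets, list(list(net = rn, source = src, target = tg)))
  }
  for (case in nets) {
    ess <- essential_reactions(case$net, case$source, case$target)
    oracle_routes <- Filter(function(m) case$target %in% m$support,
                            enumerate_efms(case$net))
    for (m in oracle_routes) {
      expect_true(all(ess %in% m$support))
    }
  }
})

test_that("discovery walks the glycolysis-PPP example in three iterations", {
  net <- split_reversible(build_glycolysis_ppp())
  rep <- discover(net, "EX_in_glc", "EX_out_r5p")
  expect_length(rep$iterations, 3)
  expect_equal(vapply(rep$iterations, `[[`, integer(1), "n_patterns"),
               c(2L, 3L, 8L))
  expect_equal(rep$iterations[[3]]$n_target_patterns, 2L)
  expect_length(rep$routes, 2)
  # the two routes are the oxidative and non-oxidative R5P pathways,
  # exactly the oracle's target-containing modes
  oracle <- Filter(function(m) "EX_out_r5p" %in% m$support,
                   enumerate_efms(net))
  expect_identical(mode_support_keys(rep$routes), mode_support_keys(oracle))
  # the iteration-2 subsystem is inflow + oxidative branch + outflow
  expect_setequal(rep$iterations[[2]]$subsystem,
                  c("EX_in_glc", "EX_out_r5p", "G6PDH"))
})

test_that("discovered routes equal oracle routes on fixtures and random networks", {
  cases <- list(
    list(net = split_reversible(build_ketone_acetone(FALSE)),
         source = "EX_in_accoa_m", target = "EX_out_g6p_c"))
  for (seed in 1:10) {
    rn <- split_reversible(build_random(seed, 3, 6))
    if (length(rn$reactions) > 20) next
    tg <- grep("^EX_out_", sort(reaction_ids(rn)), value = TRUE)[1]
    src0 <- grep("^EX_in_", sort(reaction_ids(rn)), value = TRUE)
    # pick a source that can actually feed the target
    src <- NULL
    for (s in src0) {
      if (pattern_exists(rn, subsystem(rn, c(s, tg)), required = c(s, tg))) {
        src <- s
        break
      }
    }
    if (is.null(src)) next
    cases <- c(cases, list(list(net = rn, source = src, target = tg)))
  }
  for (case in cases) {
    rep <- discover(case$net, case$source, case$target)
    oracle_target <- Filter(function(m) case$target %in% m$support,
                            enumerate_efms(case$net))
    expect_gt(length(rep$routes), 0)
    # every reported route is a genuine elementary target mode
    expect_true(all(mode_support_keys(rep$routes) %in%
                      mode_support_keys(oracle_target)))
    for (m in rep$routes) {
      expect_true(all(rep$essential %in% m$support))
      expect_true(is_elementary(case$net, m$flux))
    }
  }
})

test_that("discovery recovers the full oracle route set on the fixtures", {
  kn <- split_reversible(build_ketone_acetone(FALSE))
  rep <- discover(kn, "EX_in_accoa_m", "EX_out_g6p_c")
  oracle <- Filter(function(m) "EX_out_g6p_c" %in% m$support, enumerate_efms(kn))
  expect_identical(mode_support_keys(rep$routes), mode_support_keys(oracle))
})

test_that("discovery on the ketone fixture finds both acetol branches", {
  kn <- split_reversible(build_ketone_acetone(FALSE))
  rep <- discover(kn, "EX_in_accoa_m", "EX_out_g6p_c")
  expect_length(rep$routes, 2)
  branch <- vapply(rep$routes, function(m) {
    if ("ACDH" %in% m$support) "ACDH" else "AKRED"
  }, character(1))
  expect_setequal(branch, c("ACDH", "AKRED"))
  # acetone is an intermediate of every route
  for (m in rep$routes) expect_true(all(c("ADC", "CYP2E1") %in% m$support))
})

test_that("segments connect consecutive essential sequences", {
  kn <- split_reversible(build_ketone_acetone(FALSE))
  rep <- discover(kn, "EX_in_accoa_m", "EX_out_g6p_c")
  segs <- segment_by_essential(rep)
  expect_length(segs, 1)
  expect_setequal(segs[[1]]$alternatives, c("ACDH", "AKRED"))
  expect_equal(segs[[1]]$from, "CYP2E1")
  expect_equal(segs[[1]]$to, "MGDH")

  # fully essential single route: one sequence, no alternative segments
  ch <- chain_net()
  rep2 <- discover(ch, "A_in", "B_out")
  expect_length(rep2$iterations, 1)
  expect_length(rep2$routes, 1)
  expect_length(rep2$sequences, 1)
  expect_length(segment_by_essential(rep2), 0)
})

test_that("discovery errors distinguish unreachable targets", {
  ch <- block_reactions(chain_net(), "AtoB")
  expect_error(discover(ch, "A_in", "B_out"), "unreachable")
})
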