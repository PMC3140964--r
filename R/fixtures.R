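# Programmatic example networks.
#
# These fixtures are the package's study systems: small, fully auditable
# networks on which every engine can be validated against the exhaustive
# EFM oracle. Boundary reactions follow the EX_in_/EX_out_ convention of
# add_boundary(). CO2 is external everywhere (unbalanced).

#' Glycolysis plus pentose phosphate pathway example network
#'
#' Hepatic upper glycolysis and the pentose phosphate pathway: glucose
#' exchange (inflow and efflux), hexokinase, reversible phosphoglucose
#' isomerase, phosphofructokinase and fructose-1,6-bisphosphatase (the
#' liver-type substrate cycle), reversible aldolase to a lumped triose
#' phosphate (drained by an outflow), the lumped oxidative pentose
#' phosphate branch releasing CO2, and the reversible non-oxidative
#' interconversions (ribose-5-phosphate isomerase RPI, ribulose-5-phosphate
#' epimerase RPE, transketolases TKT1/TKT2, transaldolase TALA), with a
#' ribose-5-phosphate outflow. 15 reactions, 7 reversible; 22 columns
#' after splitting.
#'
#' On this network the discovery procedure for ribose-5-phosphate
#' production from glucose reproduces the classic three-iteration
#' walkthrough: 2, 3 and 8 elementary flux patterns, two of the final
#' eight containing the R5P outflow, and exactly two R5P-producing routes
#' (oxidative and non-oxidative).
#'
#' @return a `metnet`
#' @export
build_glycolysis_ppp <- function() {
  mets <- data.frame(
    id = c("glc", "g6p", "f6p", "fbp", "tp", "ru5p", "x5p", "r5p", "s7p", "e4p", "co2"),
    external = c(rep(FALSE, 10), TRUE)
  )
  rxns <- list(
    reaction("HEX1", c(glc = -1, g6p = 1)),
    reaction("PGI", c(g6p = -1, f6p = 1), reversible = TRUE),
    reaction("PFK", c(f6p = -1, fbp = 1)),
    reaction("FBA", c(fbp = -1, tp = 2), reversible = TRUE),
    reaction("FBP1", c(fbp = -1, f6p = 1)),
    reaction("G6PDH", c(g6p = -1, ru5p = 1, co2 = 1)), # lumped oxidative PPP
    reaction("RPI", c(ru5p = -1, r5p = 1), reversible = TRUE),
    reaction("RPE", c(ru5p = -1, x5p = 1), reversible = TRUE),
    reaction("TKT1", c(x5p = -1, r5p = -1, s7p = 1, tp = 1), reversible = TRUE),
    reaction("TALA", c(s7p = -1, tp = -1, e4p = 1, f6p = 1), reversible = TRUE),
    reaction("TKT2", c(x5p = -1, e4p = -1, f6p = 1, tp = 1), reversible = TRUE)
  )
  net <- metnet(mets, rxns)
  add_boundary(net, inflows = "glc", outflows = c("glc", "tp", "r5p"))
}

#' TCA cycle network with or without the glyoxylate shunt
#'
#' Acetyl-CoA inflow, the carbon skeleton of the TCA cycle, and an
#' oxaloacetate outflow. Without the shunt, no steady-state flux can
#' produce net oxaloacetate from acetyl-CoA (the carbons leave as CO2);
#' with isocitrate lyase (ICL) and malate synthase (MALS) added, one
#' oxaloacetate can be made from two acetyl-CoA.
#'
#' @param glyoxylate include the glyoxylate shunt reactions
#' @return a `metnet`
#' @export
build_tca <- function(glyoxylate = FALSE) {
  mets <- data.frame(
    id = c("accoa", "oaa", "cit", "icit", "akg", "succ", "fum", "mal", "glx", "co2"),
    external = c(rep(FALSE, 9), TRUE)
  )
  rxns <- list(
    reaction("CS", c(accoa = -1, oaa = -1, cit = 1)),
    reaction("ACO", c(cit = -1, icit = 1)),
    reaction("IDH", c(icit = -1, akg = 1, co2 = 1)),
    reaction("AKGDH", c(akg = -1, succ = 1, co2 = 1)),
    reaction("SDH", c(succ = -1, fum = 1)),
    reaction("FUM", c(fum = -1, mal = 1)),
    reaction("MDH", c(mal = -1, oaa = 1))
  )
  if (glyoxylate) {
    rxns <- c(rxns, list(
      reaction("ICL", c(icit = -1, glx = 1, succ = 1)),
      reaction("MALS", c(glx = -1, accoa = -1, mal = 1))
    ))
  }
  net <- metnet(mets[mets$id != "glx" | glyoxylate, , drop = FALSE], rxns)
  add_boundary(net, inflows = "accoa", outflows = "oaa")
}

#' Ketogenesis / acetone-degradation network
#'
#' The gluconeogenesis-from-acetyl-CoA fixture. The carbon skeleton runs
#' from a mitochondrial acetyl-CoA inflow through ketogenesis (thiolase
#' ACAT, HMG-CoA synthase HMGS, HMG-CoA lyase HMGL), acetoacetate
#' decarboxylation to acetone (ADC, lumped with transport), cytochrome
#' P450 2E1 monooxygenation of acetone to acetol (CYP2E1), two alternative
#' acetol-to-methylglyoxal steps (ACDH, an NAD+-coupled dehydrogenation,
#' and AKRED, a direct NADPH-coupled monooxygenase-type conversion),
#' methylglyoxal oxidation to pyruvate (MGDH), pyruvate import and
#' carboxylation (PYRT, PC), PEP carboxykinase (PEPCK), a lumped
#' gluconeogenic segment from PEP to dihydroxyacetone phosphate (GNGL,
#' charging 1 ATP at the phosphoglycerate kinase step and 1 cytosolic NADH
#' at the GAPDH step per PEP), fructose-bisphosphate assembly to G6P
#' (UPPERR) and a cytosolic glucose-6-phosphate outflow.
#'
#' With `include_cofactors = TRUE` the network carries explicit charged
#' cofactor species (`atp`, `gtp`, cytosolic/mitochondrial `nadh_c`/
#' `nadh_m`, `nadph_c`, `fadh2_m`; the discharged partners are implicit),
#' the pyruvate-malate NADPH replenishment cycle (PMCYC, 1 ATP + 1
#' mitochondrial NADH per cytosolic NADPH), a nucleoside diphosphate
#' kinase (NDK), and the surrounding energy metabolism needed for the
#' efficiency metrics: glycolysis (HK, UPPER, LOWER), pyruvate
#' dehydrogenase and a lumped TCA cycle, glucose-6-phosphatase, the
#' glycerol branch, the citrate-shuttle export of acetyl-CoA, a lipogenesis
#' lump and the beta-oxidation lump (0.5 palmitate yields 4 acetyl-CoA,
#' 3.5 NADH and 3.5 FADH2 while hydrolyzing 1 ATP).
#'
#' With `include_cofactors = FALSE` only the carbon skeleton from
#' acetyl-CoA to G6P is returned (plus the coenzyme A outflow), which keeps
#' the network within reach of exhaustive EFM enumeration.
#'
#' @param include_cofactors carry cofactor species and energy metabolism
#' @param lactaldehyde include the optional methylglyoxal to D-lactaldehyde
#'   to D-lactate branch (off by default)
#' @return a `metnet`
#' @export
build_ketone_acetone <- function(include_cofactors = FALSE, lactaldehyde = FALSE) {
  carbon_mets <- c("accoa_m", "aacoa_m", "hmgcoa_m", "acac_m", "acetone_c",
                   "acetol_c", "mglx_c", "pyr_c", "pyr_m", "oaa_m", "pep_c",
                   "dhap_c", "g6p_c", "coa_m", "co2")
  if (lactaldehyde) carbon_mets <- c(carbon_mets, "dlacald_c", "dlac_c")
  if (!include_cofactors) {
    mets <- data.frame(id = carbon_mets, external = carbon_mets == "co2")
    rxns <- list(
      reaction("ACAT", c(accoa_m = -2, aacoa_m = 1, coa_m = 1)),
      reaction("HMGS", c(aacoa_m = -1, accoa_m = -1, hmgcoa_m = 1, coa_m = 1)),
      reaction("HMGL", c(hmgcoa_m = -1, acac_m = 1, accoa_m = 1)),
      reaction("ADC", c(acac_m = -1, acetone_c = 1, co2 = 1)),
      reaction("CYP2E1", c(acetone_c = -1, acetol_c = 1)),
      reaction("ACDH", c(acetol_c = -1, mglx_c = 1)),
      reaction("AKRED", c(acetol_c = -1, mglx_c = 1)),
      reaction("MGDH", c(mglx_c = -1, pyr_c = 1)),
      reaction("PYRT", c(pyr_c = -1, pyr_m = 1)),
      reaction("PC", c(pyr_m = -1, co2 = -1, oaa_m = 1)),
      reaction("PEPCK", c(oaa_m = -1, pep_c = 1, co2 = 1)),
      reaction("GNGL", c(pep_c = -1, dhap_c = 1)),
      reaction("UPPERR", c(dhap_c = -2, g6p_c = 1))
    )
    if (lactaldehyde) {
      rxns <- c(rxns, list(
        reaction("MGRED", c(mglx_c = -1, dlacald_c = 1)),
        reaction("DLADH", c(dlacald_c = -1, dlac_c = 1)),
        reaction("DLDH", c(dlac_c = -1, pyr_c = 1))
      ))
    }
    net <- metnet(mets, rxns)
    return(add_boundary(net, inflows = "accoa_m", outflows = c("g6p_c", "coa_m")))
  }
  mets <- c(carbon_mets, "glc_c", "glyc_c", "g3p_c", "palm_c", "accoa_c", "coa_c",
            "atp", "gtp", "nadh_c", "nadh_m", "nadph_c", "fadh2_m")
  mets <- data.frame(id = mets, external = mets == "co2")
  rxns <- list(
    # ketogenesis and acetone degradation
    reaction("ACAT", c(accoa_m = -2, aacoa_m = 1, coa_m = 1)),
    reaction("HMGS", c(aacoa_m = -1, accoa_m = -1, hmgcoa_m = 1, coa_m = 1)),
    reaction("HMGL", c(hmgcoa_m = -1, acac_m = 1, accoa_m = 1)),
    reaction("ADC", c(acac_m = -1, acetone_c = 1, co2 = 1)),
    reaction("CYP2E1", c(acetone_c = -1, nadph_c = -1, acetol_c = 1)),
    reaction("ACDH", c(acetol_c = -1, mglx_c = 1, nadh_c = 1)),
    reaction("AKRED", c(acetol_c = -1, nadph_c = -1, mglx_c = 1)),
    reaction("MGDH", c(mglx_c = -1, pyr_c = 1, nadph_c = 1)),
    # pyruvate to G6P
    reaction("PYRT", c(pyr_c = -1, pyr_m = 1)),
    reaction("PC", c(pyr_m = -1, co2 = -1, atp = -1, oaa_m = 1)),
    reaction("PEPCK", c(oaa_m = -1, gtp = -1, pep_c = 1, co2 = 1)),
    reaction("GNGL", c(pep_c = -1, atp = -1, nadh_c = -1, dhap_c = 1)),
    reaction("UPPERR", c(dhap_c = -2, g6p_c = 1)),
    reaction("G6PASE", c(g6p_c = -1, glc_c = 1)),
    # glycolysis, pyruvate oxidation, lumped TCA
    reaction("HK", c(glc_c = -1, atp = -1, g6p_c = 1)),
    reaction("UPPER", c(g6p_c = -1, atp = -1, dhap_c = 2)),
    reaction("LOWER", c(dhap_c = -1, pyr_c = 1, atp = 2, nadh_c = 1)),
    reaction("PDH", c(pyr_m = -1, coa_m = -1, accoa_m = 1, co2 = 1, nadh_m = 1)),
    reaction("TCA", c(accoa_m = -1, coa_m = 1, co2 = 2, nadh_m = 3, fadh2_m = 1, gtp = 1)),
    # glycerol branch
    reaction("GLYK", c(glyc_c = -1, atp = -1, g3p_c = 1)),
    reaction("G3PDH", c(g3p_c = -1, dhap_c = 1, nadh_c = 1), reversible = TRUE),
    reaction("G3PASE", c(g3p_c = -1, glyc_c = 1)),
    # fatty acid storage and mobilization
    reaction("CITSH", c(accoa_m = -1, atp = -1, coa_c = -1, accoa_c = 1, coa_m = 1)),
    reaction("LIPO", c(accoa_c = -8, atp = -7, nadph_c = -14, palm_c = 1, coa_c = 8)),
    reaction("BOX", c(palm_c = -1, atp = -2, coa_m = -8,
                      accoa_m = 8, nadh_m = 7, fadh2_m = 7)),
    # cofactor machinery
    reaction("PMCYC", c(atp = -1, nadh_m = -1, nadph_c = 1)),
    reaction("NDK", c(atp = -1, gtp = 1), reversible = TRUE)
  )
  if (lactaldehyde) {
    rxns <- c(rxns, list(
      reaction("MGRED", c(mglx_c = -1, nadph_c = -1, dlacald_c = 1)),
      reaction("DLADH", c(dlacald_c = -1, dlac_c = 1, nadh_c = 1)),
      reaction("DLDH", c(dlac_c = -1, pyr_c = 1, nadh_c = 1))
    ))
  }
  net <- metnet(mets, rxns)
  add_boundary(net,
               inflows = c("accoa_m", "glc_c", "glyc_c", "palm_c"),
               outflows = c("g6p_c", "coa_m", "glc_c", "glyc_c", "palm_c"))
}

#' Random feasible network
#'
#' Builds a network as a superposition of `n_modes` randomly drawn
#' source-to-sink chains over a pool of `n_mets` metabolites, guaranteeing
#' a nonzero steady-state flux cone. Chains may share reactions, so the
#' resulting elementary mode structure is richer than the generating
#' routes. Deterministic for a fixed seed.
#'
#' @param seed integer seed
#' @param n_modes number of generating routes (>= 1)
#' @param n_mets metabolite pool size (>= 3)
#' @return a `metnet` (irreversible reactions only)
#' @export
build_random <- function(seed, n_modes = 3, n_mets = 6) {
  if (n_modes < 1 || n_mets < 3) stop("degenerate parameters")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  pool <- paste0("m", seq_len(n_mets))
  rxns <- list()
  have <- character(0)
  add_rxn <- function(id, stoich) {
    if (!(id %in% have)) {
      rxns[[length(rxns) + 1]] <<- reaction(id, stoich)
      have <<- c(have, id)
    }
  }
  for (k in seq_len(n_modes)) {
    len <- sample(2:min(4, n_mets), 1)
    chain <- sample(pool, len)
    add_rxn(paste0("EX_in_", chain[1]), stats::setNames(1, chain[1]))
    for (i in seq_len(len - 1)) {
      coef <- if (stats::runif(1) < 0.25) 2 else 1
      st <- stats::setNames(c(-coef, 1), c(chain[i], chain[i + 1]))
      add_rxn(paste0("R_", chain[i], "_", chain[i + 1]), st)
    }
    add_rxn(paste0("EX_out_", chain[len]), stats::setNames(-1, chain[len]))
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  metnet(data.frame(id = used, external = FALSE), rxns)
}
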