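# Cofactor accounting, Gibbs free energy, and the two efficiency metrics.
#
# Cofactor convention: the fixtures carry only the charged species (atp,
# gtp, nadh_c, nadh_m, nadph_c, fadh2_m); the discharged partners are
# implicit. A route's net demand for a priced cofactor is settled through
# exchange columns added by the LP, priced in ATP equivalents by the
# CofactorPolicy: these exchanges play the role of a lumped respiratory
# chain with configurable yield (consuming NADH at the P/O ratio, in either
# direction). NADPH has no exchange: it must be balanced in-network through
# the pyruvate-malate replenishment cycle, which hydrolyzes one ATP and
# oxidizes one mitochondrial NADH per NADPH.

#' Cofactor accounting policy
#'
#' @param atp_per_nadh_m ATP equivalents per mitochondrial NADH (P/O ratio)
#' @param atp_per_nadh_c ATP equivalents per cytosolic NADH (after shuttle
#'   into the glycerol-phosphate shuttle / FADH2 entry point)
#' @param atp_per_fadh2 ATP equivalents per FADH2
#' @param species named character vector mapping the roles `atp`, `gtp`,
#'   `nadh_m`, `nadh_c`, `nadph`, `fadh2` to metabolite ids in the network
#' @param balancing ids of pure cofactor-conversion reactions that any route
#'   may use to balance its cofactors (the replenishment cycle and
#'   nucleotide kinase in the shipped fixture)
#' @return a `cofactor_policy`
#' @export
cofactor_policy <- function(atp_per_nadh_m = 2.5,
                            atp_per_nadh_c = 1.5,
                            atp_per_fadh2 = 1.5,
                            species = c(atp = "atp", gtp = "gtp",
                                        nadh_m = "nadh_m", nadh_c = "nadh_c",
                                        nadph = "nadph_c", fadh2 = "fadh2_m"),
                            balancing = c("PMCYC", "NDK_f", "NDK_b", "NDK")) {
  stopifnot(atp_per_nadh_m >= 0, atp_per_nadh_c >= 0, atp_per_fadh2 >= 0)
  structure(list(atp_per_nadh_m = atp_per_nadh_m,
                 atp_per_nadh_c = atp_per_nadh_c,
                 atp_per_fadh2 = atp_per_fadh2,
                 species = species, balancing = balancing),
            class = "cofactor_policy")
}

#' @export
print.cofactor_policy <- function(x, ...) {
  cat(sprintf(paste0("cofactor policy: NADH(mito)=%.2g, NADH(cyt)=%.2g, ",
                     "FADH2=%.2g ATP; NADPH via replenishment cycle\n"),
              x$atp_per_nadh_m, x$atp_per_nadh_c, x$atp_per_fadh2))
  invisible(x)
}

# priced currency species and their ATP-equivalent weights
policy_prices <- function(policy) {
  sp <- policy$species
  w <- c(1, policy$atp_per_nadh_m, policy$atp_per_nadh_c, policy$atp_per_fadh2)
  stats::setNames(w, c(sp[["atp"]], sp[["nadh_m"]], sp[["nadh_c"]], sp[["fadh2"]]))
}

# augment a stoichiometric matrix with priced cofactor import/export columns;
# returns list(S, obj) where obj prices imports positive, exports negative
currency_exchange <- function(S, policy) {
  pr <- policy_prices(policy)
  pr <- pr[names(pr) %in% rownames(S)]
  obj <- numeric(0)
  for (m in names(pr)) {
    imp <- stats::setNames(numeric(nrow(S)), rownames(S))
    imp[m] <- 1
    S <- cbind(S, imp, -imp)
    colnames(S)[ncol(S) - 1:0] <- paste0(c("XIMP_", "XEXP_"), m)
    obj <- c(obj, stats::setNames(c(pr[[m]], -pr[[m]]),
                                  paste0(c("XIMP_", "XEXP_"), m)))
  }
  list(S = S, obj = obj)
}

balancing_ids <- function(net, policy) {
  intersect(c(policy$balancing), reaction_ids(net))
}

# map parent reaction ids to their split directions where applicable
expand_split_ids <- function(net, ids) {
  if (length(ids) == 0) return(character(0))
  all_ids <- reaction_ids(net)
  origin <- vapply(net$reactions, function(r) r$origin %||% NA_character_, character(1))
  out <- character(0)
  for (id in ids) {
    if (id %in% all_ids) {
      out <- c(out, id)
    } else {
      kids <- all_ids[!is.na(origin) & origin == id]
      if (length(kids) == 0) stop("unknown reaction: ", id)
      out <- c(out, kids)
    }
  }
  unique(out)
}

#' Net ATP cost of a route under cofactor balancing
#'
#' Minimizes the net ATP-equivalent consumption over all steady-state
#' fluxes supported on the route (plus the policy's cofactor-balancing
#' reactions) that produce one unit of flux through `output`. Every
#' internal metabolite is balanced; priced cofactors (ATP and NAD(P)H/FADH2
#' pools) may be drawn from or returned to the network surroundings at the
#' policy's ATP-equivalent rates, while NADPH must be balanced through the
#' replenishment cycle.
#'
#' @param net cofactor-carrying `metnet` (see
#'   [build_ketone_acetone()] with `include_cofactors = TRUE`)
#' @param route character vector of reaction ids forming the route
#' @param policy a [cofactor_policy()]
#' @param output id of the product-forming reaction normalized to flux 1
#' @return net ATP moles consumed per mole of output (negative = net yield)
#' @export
atp_cost <- function(net, route, policy = cofactor_policy(),
                     output = "EX_out_g6p_c") {
  net <- split_reversible(net)
  ids <- reaction_ids(net)
  route <- expand_split_ids(net, route)
  output <- expand_split_ids(net, output)
  allowed <- union(union(route, output), balancing_ids(net, policy))
  S <- stoich_matrix(net)
  aug <- currency_exchange(S, policy)
  zero <- setdiff(ids, allowed)
  fix <- matrix(0, 1, ncol(aug$S), dimnames = list(NULL, colnames(aug$S)))
  fix[1, output] <- 1
  res <- lp_flux(aug$S, obj = aug$obj, zero = zero,
                 eq = list(A = fix, b = 1), dir = "min")
  if (res$status != "optimal") {
    stop("route cannot be balanced: ", diagnose_unbalanced(aug$S, route, zero))
  }
  res$value
}

diagnose_unbalanced <- function(S, route, zero) {
  # identify internal species that cannot be balanced on the allowed columns
  keep <- setdiff(colnames(S), zero)
  sub <- S[, keep, drop = FALSE]
  touched <- rownames(sub)[rowSums(sub != 0) > 0]
  one_sided <- touched[vapply(touched, function(m) {
    all(sub[m, ] >= 0) || all(sub[m, ] <= 0)
  }, logical(1))]
  if (length(one_sided)) {
    paste("species cannot be balanced:", paste(one_sided, collapse = ", "))
  } else {
    "no steady-state flux exists on the allowed reactions"
  }
}

#' Maximal ATP yield of catabolizing a substrate
#'
#' Fixes the substrate inflow at 1, forbids all other carbon inflows, and
#' maximizes the net ATP-equivalent export over the whole network under the
#' policy prices.
#'
#' @param net cofactor-carrying `metnet`
#' @param inflow id of the substrate inflow reaction (e.g. `EX_in_glc_c`)
#' @param policy a [cofactor_policy()]
#' @param forbid additional reaction ids excluded from the flux
#' @return ATP moles per mole substrate
#' @export
max_atp_yield <- function(net, inflow, policy = cofactor_policy(),
                          forbid = character(0)) {
  net <- split_reversible(net)
  ids <- reaction_ids(net)
  forbid <- expand_split_ids(net, forbid)
  if (!inflow %in% ids) stop("unknown inflow: ", inflow)
  other_in <- setdiff(grep("^EX_in_", ids, value = TRUE), inflow)
  S <- stoich_matrix(net)
  aug <- currency_exchange(S, policy)
  fix <- matrix(0, 1, ncol(aug$S), dimnames = list(NULL, colnames(aug$S)))
  fix[1, inflow] <- 1
  res <- lp_flux(aug$S, obj = aug$obj, zero = union(other_in, forbid),
                 eq = list(A = fix, b = 1), dir = "min")
  if (res$status != "optimal") stop("substrate cannot be catabolized (LP ", res$status, ")")
  -res$value
}

# two-stage helper: fix some exchanges, optimize carbon first, then cost.
# stage 1: optimize `carbon` flux (min or max) subject to fixed fluxes;
# stage 2: fix the stage-1 optimum and minimize net ATP-equivalent cost.
two_stage_cost <- function(net, policy, fixed, carbon, carbon_dir,
                           forbid = character(0)) {
  net <- split_reversible(net)
  ids <- reaction_ids(net)
  forbid <- setdiff(expand_split_ids(net, forbid), c(names(fixed), carbon))
  other_in <- setdiff(grep("^EX_in_", ids, value = TRUE),
                      c(names(fixed), carbon))
  S <- stoich_matrix(net)
  aug <- currency_exchange(S, policy)
  zero <- union(other_in, forbid)
  rows <- lapply(names(fixed), function(r) {
    a <- stats::setNames(numeric(ncol(aug$S)), colnames(aug$S))
    a[r] <- 1
    a
  })
  A <- do.call(rbind, rows)
  colnames(A) <- colnames(aug$S)
  cobj <- stats::setNames(numeric(1), carbon)
  cobj[carbon] <- 1
  s1 <- lp_flux(aug$S, obj = cobj, zero = zero,
                eq = list(A = A, b = unname(unlist(fixed))), dir = carbon_dir)
  if (s1$status != "optimal") stop("carbon stage infeasible (LP ", s1$status, ")")
  m <- s1$value
  a2 <- stats::setNames(numeric(ncol(aug$S)), colnames(aug$S))
  a2[carbon] <- 1
  A2 <- rbind(A, a2)
  s2 <- lp_flux(aug$S, obj = aug$obj, zero = zero,
                eq = list(A = A2, b = c(unname(unlist(fixed)), m)), dir = "min")
  if (s2$status != "optimal") stop("cost stage infeasible (LP ", s2$status, ")")
  list(carbon = m, cost = s2$value)
}

#' Gluconeogenic energy efficiency
#'
#' The ratio of the net ATP regained by converting a substrate to glucose
#' and catabolizing that glucose, to the ATP obtained by catabolizing the
#' substrate directly. A value of 1 means gluconeogenesis through the
#' compound loses no energy.
#'
#' @param net cofactor-carrying `metnet`
#' @param inflow substrate inflow reaction id (e.g. `EX_in_glyc_c`)
#' @param policy a [cofactor_policy()]
#' @param forbid reaction ids excluded from the gluconeogenic leg (e.g. to
#'   select among alternative routes)
#' @param glucose_out,glucose_in glucose exchange reaction ids
#' @return list with `efficiency` and the audit terms `atp_glucose`
#'   (catabolic yield of the glucose formed), `cost_gng` (net ATP cost of
#'   forming it), `moles_substrate` (substrate per glucose) and
#'   `atp_substrate` (direct catabolic yield per substrate)
#' @export
gluconeogenic_energy_efficiency <- function(net, inflow,
                                            policy = cofactor_policy(),
                                            forbid = character(0),
                                            glucose_out = "EX_out_glc_c",
                                            glucose_in = "EX_in_glc_c") {
  y_sub <- max_atp_yield(net, inflow, policy)
  if (y_sub <= 0) stop("substrate has no catabolic ATP yield")
  gng <- two_stage_cost(net, policy,
                        fixed = stats::setNames(list(1), glucose_out),
                        carbon = inflow, carbon_dir = "min",
                        forbid = union(forbid, glucose_in))
  if (gng$carbon <= 0) stop("no gluconeogenic route from this substrate")
  y_glc <- max_atp_yield(net, glucose_in, policy)
  eff <- (y_glc - gng$cost) / (gng$carbon * y_sub)
  list(efficiency = eff, atp_glucose = y_glc, cost_gng = gng$cost,
       moles_substrate = gng$carbon, atp_substrate = y_sub)
}

#' Glucose storage efficiency
#'
#' Moles of glucose regained per mole of glucose invested when glucose is
#' converted into a storage compound and the compound converted back into
#' glucose. ATP costs and yields of both legs are converted into glucose
#' equivalents at the glucose catabolic ATP yield.
#'
#' @param net cofactor-carrying `metnet`
#' @param compound_out,compound_in exchange reaction ids of the storage
#'   compound (e.g. `EX_out_palm_c` / `EX_in_palm_c`)
#' @param policy a [cofactor_policy()]
#' @param forbid reaction ids excluded from the return leg (e.g. to force a
#'   particular gluconeogenic route)
#' @param glucose_out,glucose_in glucose exchange reaction ids
#' @return list with `efficiency` and audit terms: `glc_invested`,
#'   `cost_forward`, `glc_regained`, `surplus_return`, `atp_glucose`
#' @export
glucose_storage_efficiency <- function(net, compound_out, compound_in,
                                       policy = cofactor_policy(),
                                       forbid = character(0),
                                       glucose_out = "EX_out_glc_c",
                                       glucose_in = "EX_in_glc_c") {
  ids <- reaction_ids(net)
  if (!all(c(compound_out, compound_in) %in% ids)) {
    stop("unknown compound exchange reactions")
  }
  fwd <- tryCatch(
    two_stage_cost(net, policy,
                   fixed = stats::setNames(list(1), compound_out),
                   carbon = glucose_in, carbon_dir = "min",
                   forbid = glucose_out),
    error = function(e) stop("compound cannot be synthesized from glucose: ",
                             conditionMessage(e)))
  ret <- two_stage_cost(net, policy,
                        fixed = stats::setNames(list(1), compound_in),
                        carbon = glucose_out, carbon_dir = "max",
                        forbid = union(forbid, glucose_in))
  y_glc <- max_atp_yield(net, glucose_in, policy)
  eff <- (ret$carbon - ret$cost / y_glc) / (fwd$carbon + fwd$cost / y_glc)
  list(efficiency = eff, glc_invested = fwd$carbon, cost_forward = fwd$cost,
       glc_regained = ret$carbon, surplus_return = -ret$cost,
       atp_glucose = y_glc)
}
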