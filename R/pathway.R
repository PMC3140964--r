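# Iterative pathway discovery: seed subsystem -> representative pathway ->
# essential reactions -> subsystem expansion until closure.

#' Essential reactions for a source-to-target conversion
#'
#' A reaction is essential iff no steady-state flux with unit target flux
#' exists when its flux is constrained to zero (one LP feasibility query
#' per reaction). The target reaction itself is trivially essential.
#'
#' @param net a `metnet` with only irreversible reactions
#' @param source inflow reaction id (used for the reachability check)
#' @param target outflow reaction id
#' @return sorted character vector of essential reaction ids
#' @export
essential_reactions <- function(net, source, target) {
  check_split_net(net)
  S <- stoich_matrix(net)
  ids <- colnames(S)
  stopifnot(source %in% ids, target %in% ids)
  base <- lp_flux(S, lower = stats::setNames(1, target))
  if (base$status != "optimal") {
    stop("target unreachable: no steady-state flux produces ", target)
  }
  ess <- character(0)
  for (r in ids) {
    if (r == target) {
      ess <- c(ess, r)
      next
    }
    res <- lp_flux(S, lower = stats::setNames(1, target), zero = r)
    if (res$status != "optimal") ess <- c(ess, r)
  }
  sort(ess)
}

# order the support of a mode by metabolite availability from the source;
# reactions become eligible once all their internal substrates have been
# produced. Falls back to appending leftovers (cycles) in sorted order.
order_route <- function(net, support, source) {
  ext <- net$metabolites$id[net$metabolites$external]
  avail <- ext
  placed <- character(0)
  pending <- setdiff(support, source)
  if (source %in% support) {
    placed <- source
    avail <- union(avail, names(net$reactions[[source]]$stoich))
  }
  repeat {
    eligible <- Filter(function(r) {
      st <- net$reactions[[r]]$stoich
      subs <- names(st)[st < 0]
      all(subs %in% avail)
    }, sort(pending))
    if (length(eligible) == 0) break
    r <- eligible[[1]]
    placed <- c(placed, r)
    pending <- setdiff(pending, r)
    st <- net$reactions[[r]]$stoich
    avail <- union(avail, names(st)[st > 0])
  }
  c(placed, sort(pending))
}

#' Discover all pathways from a source inflow to a target outflow
#'
#' Implements the iterative subsystem-expansion procedure: starting from
#' the seed subsystem consisting of the source and target exchange
#' reactions, it (1) enumerates the elementary flux patterns of the current
#' subsystem, (2) extracts witness modes for the target-containing
#' patterns, (3) adds every witness reaction that is neither essential nor
#' already in the subsystem, and (4) stops when the witnesses use only
#' subsystem or essential reactions. The final target-containing patterns'
#' witnesses, deduplicated by their non-cofactor support, are the complete
#' set of source-to-target routes.
#'
#' @param net a `metnet` with only irreversible reactions
#' @param source inflow reaction id
#' @param target outflow reaction id
#' @param max_iter iteration cap
#' @param cofactor_reactions reaction ids ignored when deciding whether two
#'   witnesses are the same route
#' @return a `pathway_report` with fields `source`, `target`, `essential`,
#'   `sequences` (maximal runs of essential reactions along the first
#'   route), `segments` (alternative-route segments between consecutive
#'   sequences), `routes` (witness `flux_mode`s) and `iterations` (audit
#'   trail: subsystem, pattern count, target-pattern count, reactions
#'   added)
#' @export
discover <- function(net, source, target, max_iter = 50L,
                     cofactor_reactions = character(0)) {
  check_split_net(net)
  S <- stoich_matrix(net)
  feas <- lp_flux(S, lower = stats::setNames(c(1, 1), c(source, target)))
  if (feas$status != "optimal") {
    stop("target unreachable from source at steady state")
  }
  essential <- essential_reactions(net, source, target)
  pmp <- partner_map(net)
  subsys_ids <- c(source, target)
  audit <- list()
  routes <- list()
  done <- FALSE
  for (it in seq_len(max_iter)) {
    pats <- enumerate_efps(net, subsystem(net, subsys_ids))
    tpats <- Filter(function(p) target %in% p$members, pats)
    new <- sort(unique(unlist(lapply(tpats, function(p) {
      setdiff(p$witness$support, union(subsys_ids, essential))
    }))))
    # a reversible reaction joins the subsystem as a whole: include the
    # opposite split direction of every added reaction
    new <- sort(union(new, setdiff(unname(pmp[intersect(new, names(pmp))]),
                                   c(subsys_ids, essential))))
    audit[[it]] <- list(subsystem = subsys_ids,
                        n_patterns = length(pats),
                        n_target_patterns = length(tpats),
                        added = new)
    if (length(new) == 0) {
      routes <- tpats
      done <- TRUE
      break
    }
    subsys_ids <- c(subsys_ids, new)
  }
  report <- structure(list(source = source, target = target,
                           essential = essential,
                           sequences = list(), segments = list(),
                           routes = list(), iterations = audit,
                           network = net,
                           cofactor_reactions = cofactor_reactions),
                      class = "pathway_report")
  if (!done) {
    stop("iteration cap (", max_iter, ") exceeded; subsystem grew to ",
         length(subsys_ids), " reactions")
  }
  # deduplicate witnesses by non-cofactor support
  keys <- vapply(routes, function(p) {
    paste(sort(setdiff(p$witness$support, cofactor_reactions)), collapse = "|")
  }, character(1))
  modes <- lapply(routes[!duplicated(keys)], `[[`, "witness")
  report$routes <- modes[order(vapply(modes, function(m) length(m$support), integer(1)),
                               vapply(modes, function(m) paste(sort(m$support), collapse = "|"),
                                      character(1)))]
  # essential sequences: maximal runs along the first route
  if (length(report$routes)) {
    ordered <- order_route(net, report$routes[[1]]$support, source)
    in_ess <- ordered %in% essential
    runs <- split(ordered[in_ess], cumsum(!in_ess)[in_ess])
    report$sequences <- unname(runs[lengths(runs) > 0])
  }
  report$segments <- compute_segments(report)
  report
}

# alternative-route segments between consecutive essential sequences:
# for every route, reactions falling between the bounding essential
# reactions (in that route's own ordering) are pooled.
compute_segments <- function(report) {
  seqs <- report$sequences
  if (length(seqs) < 1 || length(report$routes) == 0) return(list())
  net <- report$network
  segs <- list()
  if (length(seqs) >= 2) {
    for (i in seq_len(length(seqs) - 1)) {
      from <- seqs[[i]][length(seqs[[i]])]
      to <- seqs[[i + 1]][1]
      alts <- character(0)
      for (m in report$routes) {
        ordered <- order_route(net, m$support, report$source)
        a <- match(from, ordered)
        b <- match(to, ordered)
        if (!is.na(a) && !is.na(b) && b > a + 1) {
          alts <- union(alts, ordered[(a + 1):(b - 1)])
        }
      }
      st_from <- net$reactions[[from]]$stoich
      st_to <- net$reactions[[to]]$stoich
      segs[[length(segs) + 1]] <- list(
        from = from, to = to,
        boundary = c(product = paste(names(st_from)[st_from > 0], collapse = ","),
                     educt = paste(names(st_to)[st_to < 0], collapse = ",")),
        alternatives = sort(setdiff(alts, report$essential)))
    }
  }
  segs
}

#' Split a pathway report into sub-problems between essential sequences
#'
#' Each segment connects the product of one sequence of essential
#' reactions to the educt of the next and lists the alternative (non
#' essential) reactions observed there across all routes. With a single
#' fully essential route the conversion is fully determined and no
#' segments are returned.
#'
#' @param report a `pathway_report` from [discover()]
#' @return list of segments (fields `from`, `to`, `boundary`,
#'   `alternatives`)
#' @export
segment_by_essential <- function(report) {
  stopifnot(inherits(report, "pathway_report"))
  if (length(report$sequences) == 0) stop("report has no essential sequences")
  report$segments
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("pathway report %s -> %s\n", x$source, x$target))
  cat(sprintf("  %d iterations, %d routes, %d essential reactions\n",
              length(x$iterations), length(x$routes), length(x$essential)))
  for (i in seq_along(x$iterations)) {
    a <- x$iterations[[i]]
    cat(sprintf("  iter %d: subsystem %d, patterns %d (%d with target), added %d\n",
                i, length(a$subsystem), a$n_patterns, a$n_target_patterns,
                length(a$added)))
  }
  invisible(x)
}
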