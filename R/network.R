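#' Construct a stoichiometric metabolic network
#'
#' A `metnet` holds an ordered set of metabolites and an ordered set of
#' reactions and exposes the stoichiometric matrix N (one row per internal
#' metabolite, one column per reaction). Metabolites flagged `external` are
#' treated as unbalanced: they impose no steady-state constraint and their
#' rows are omitted from N.
#'
#' @param metabolites data frame with columns `id` (unique), and optionally
#'   `name`, `compartment`, `formula`, `external` (logical, default `FALSE`).
#'   Compartments are conventionally encoded as id suffixes (`accoa_m`,
#'   `g6p_c`); the `compartment` column is informative only.
#' @param reactions list of reactions, each a list with `id`, `stoich`
#'   (named numeric vector, negative = substrate, positive = product),
#'   `reversible` (logical) and optionally `origin` (id of the parent
#'   reaction a split direction came from).
#' @return An object of class `metnet`.
#' @examples
#' net <- metnet(
#'   data.frame(id = c("A", "B")),
#'   list(
#'     reaction("A_in", c(A = 1)),
#'     reaction("AtoB", c(A = -1, B = 1)),
#'     reaction("B_out", c(B = -1))
#'   )
#' )
#' stoich_matrix(net)
#' @export
metnet <- function(metabolites, reactions) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) {
    metabolites$compartment <- vapply(strsplit(metabolites$id, "_"), function(p) {
      s <- p[length(p)]
      if (nchar(s) == 1) s else ""
    }, character(1))
  }
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$external)) metabolites$external <- FALSE
  metabolites$external <- as.logical(metabolites$external)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  reactions <- lapply(reactions, function(r) {
    if (length(r$stoich) == 0) stop("reaction ", r$id, " has empty stoichiometry")
    if (any(r$stoich == 0)) stop("reaction ", r$id, " has zero coefficients")
    unknown <- setdiff(names(r$stoich), metabolites$id)
    if (length(unknown)) {
      stop("reaction ", r$id, " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    }
    if (is.null(r$reversible)) r$reversible <- FALSE
    if (is.null(r$origin)) r$origin <- NA_character_
    r
  })
  names(reactions) <- rids
  structure(list(metabolites = metabolites, reactions = reactions), class = "metnet")
}

#' Create a reaction
#'
#' @param id reaction identifier
#' @param stoich named numeric vector of signed coefficients
#'   (negative = substrate)
#' @param reversible logical
#' @param origin parent reaction id for split directions
#' @export
reaction <- function(id, stoich, reversible = FALSE, origin = NA_character_) {
  list(id = id, stoich = stoich, reversible = reversible, origin = origin)
}

reaction_ids <- function(net) names(net$reactions)

#' Stoichiometric matrix of a network
#'
#' @param net a `metnet`
#' @param internal_only drop rows of external metabolites (the default); the
#'   resulting matrix is the N used in all steady-state computations
#' @return numeric matrix with metabolite ids as row names and reaction ids
#'   as column names
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  mets <- net$metabolites$id
  S <- matrix(0, length(mets), length(net$reactions),
              dimnames = list(mets, reaction_ids(net)))
  for (r in net$reactions) S[names(r$stoich), r$id] <- r$stoich
  if (internal_only) S <- S[!net$metabolites$external, , drop = FALSE]
  S
}

#' @export
print.metnet <- function(x, ...) {
  ne <- sum(x$metabolites$external)
  nr <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat(sprintf("metnet: %d metabolites (%d external), %d reactions (%d reversible)\n",
              nrow(x$metabolites), ne, length(x$reactions), nr))
  invisible(x)
}

#' Split reversible reactions into irreversible direction pairs
#'
#' Each reversible reaction `r` is replaced by an irreversible forward copy
#' `r_f` and a backward copy `r_b` with negated stoichiometry, both tagged
#' with `origin = r`. Irreversible reactions pass through unchanged. The
#' resulting network admits only nonnegative fluxes.
#'
#' @param net a `metnet`
#' @return a `metnet` with only irreversible reactions
#' @export
split_reversible <- function(net) {
  out <- list()
  for (r in net$reactions) {
    if (!r$reversible) {
      out[[length(out) + 1]] <- r
    } else {
      out[[length(out) + 1]] <- reaction(paste0(r$id, "_f"), r$stoich, FALSE, origin = r$id)
      out[[length(out) + 1]] <- reaction(paste0(r$id, "_b"), -r$stoich, FALSE, origin = r$id)
    }
  }
  metnet(net$metabolites, out)
}

# split-direction pairs as a two-column matrix of reaction ids (r_f, r_b)
split_pairs <- function(net) {
  origin <- vapply(net$reactions, function(r) r$origin %||% NA_character_, character(1))
  parents <- unique(origin[!is.na(origin)])
  pairs <- NULL
  for (p in parents) {
    ids <- reaction_ids(net)[!is.na(origin) & origin == p]
    if (length(ids) == 2) pairs <- rbind(pairs, sort(ids))
  }
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add boundary exchange reactions
#'
#' Adds one irreversible single-metabolite exchange column per requested
#' flow: `EX_in_<id>` producing the metabolite, `EX_out_<id>` consuming it.
#'
#' @param net a `metnet`
#' @param inflows,outflows character vectors of metabolite ids
#' @return extended `metnet`
#' @export
add_boundary <- function(net, inflows = character(0), outflows = character(0)) {
  unknown <- setdiff(c(inflows, outflows), net$metabolites$id)
  if (length(unknown)) stop("unknown metabolites: ", paste(unknown, collapse = ", "))
  rxns <- net$reactions
  for (m in inflows) {
    s <- 1
    names(s) <- m
    rxns[[length(rxns) + 1]] <- reaction(paste0("EX_in_", m), s)
  }
  for (m in outflows) {
    s <- -1
    names(s) <- m
    rxns[[length(rxns) + 1]] <- reaction(paste0("EX_out_", m), s)
  }
  metnet(net$metabolites, unname(rxns))
}

#' Block reactions (zero-flux constraint)
#'
#' Removes the named columns from the network, which is equivalent to
#' constraining their flux to zero. The removed reactions are recorded in
#' the `blocked` attribute for provenance.
#'
#' @param net a `metnet`
#' @param ids reaction ids to block
#' @return reduced `metnet`
#' @export
block_reactions <- function(net, ids) {
  if (length(ids) == 0) return(net)
  unknown <- setdiff(ids, reaction_ids(net))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  kept <- net$reactions[setdiff(reaction_ids(net), ids)]
  out <- metnet(net$metabolites, unname(kept))
  attr(out, "blocked") <- c(attr(net, "blocked"), ids)
  out
}

#' Designate a subsystem of a network
#'
#' @param net a `metnet`
#' @param ids ordered subset of reaction ids; flux patterns are defined over
#'   this set
#' @export
subsystem <- function(net, ids) {
  unknown <- setdiff(ids, reaction_ids(net))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  if (length(ids) == 0) stop("subsystem must be nonempty")
  structure(list(ids = ids, k = length(ids)), class = "subsystem")
}

#' @export
print.subsystem <- function(x, ...) {
  cat("subsystem of", x$k, "reactions:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}
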