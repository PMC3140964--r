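# Network I/O: a hand-auditable TSV dialect, SBML Level 2/3, and a JSON dump.

#' Read a metabolic network from file
#'
#' @param path file path
#' @param format `"tsv"`, `"sbml"` or `"auto"` (by extension: `.xml`/`.sbml`
#'   is SBML, anything else the TSV dialect)
#' @return a `metnet`
#' @export
read_network <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) "sbml" else "tsv"
  }
  switch(format, tsv = read_network_tsv(path), sbml = read_network_sbml(path))
}

# equation grammar: "2 A + B -> C"; an empty side denotes a boundary flow
parse_equation <- function(eq, line) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("malformed equation on line ", line, ": ", eq)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(side, sgn) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      if (t == "") stop("malformed equation on line ", line, ": ", eq)
      parts <- strsplit(t, "\\s+")[[1]]
      if (length(parts) == 1) {
        coef <- 1
        met <- parts
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient '", parts[1], "' on line ", line)
        met <- parts[2]
      } else {
        stop("malformed term '", t, "' on line ", line)
      }
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sgn * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) + rhs[m]
  st <- st[st != 0]
  if (length(st) == 0) stop("empty net stoichiometry on line ", line, ": ", eq)
  st
}

#' @rdname read_network
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  external <- character(0)
  rxns <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#!")) {
      body <- trimws(sub("^#!\\s*", "", ln))
      if (startsWith(body, "external:")) {
        external <- c(external, strsplit(trimws(sub("^external:", "", body)), "\\s+")[[1]])
      }
      next
    }
    if (startsWith(ln, "#")) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3) {
      stop("line ", i, ": expected 3 tab-separated fields (id, reversible, equation)")
    }
    rev <- fields[2]
    if (!rev %in% c("0", "1")) stop("line ", i, ": reversible flag must be 0 or 1")
    rxns[[length(rxns) + 1]] <- reaction(fields[1], parse_equation(fields[3], i),
                                         reversible = rev == "1")
  }
  mets <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  metnet(data.frame(id = mets, external = mets %in% external), rxns)
}

format_equation <- function(stoich) {
  fmt <- function(ids, coefs) {
    paste(mapply(function(m, cf) if (cf == 1) m else paste(format(cf), m),
                 ids, coefs), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(names(lhs), -unname(lhs)), "->", fmt(names(rhs), unname(rhs)))
}

#' Write a network in the TSV dialect
#'
#' One reaction per line: `id <TAB> reversible(0/1) <TAB> equation`, with a
#' `#! external:` directive listing unbalanced metabolites.
#'
#' @param net a `metnet`
#' @param path output path
#' @export
write_network_tsv <- function(net, path) {
  ext <- net$metabolites$id[net$metabolites$external]
  lines <- character(0)
  if (length(ext)) lines <- paste("#! external:", paste(ext, collapse = " "))
  for (r in net$reactions) {
    lines <- c(lines, paste(r$id, if (r$reversible) "1" else "0",
                            format_equation(r$stoich), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_network
#' @export
read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML: ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> element")
  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (length(sp) == 0) stop("malformed SBML: no species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "",
                         xml2::xml_attr(sp, "compartment")),
    external = !is.na(xml2::xml_attr(sp, "boundaryCondition")) &
      xml2::xml_attr(sp, "boundaryCondition") == "true",
    stringsAsFactors = FALSE
  )
  rx <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- xml2::xml_attr(node, "reversible")
    # SBML L2 defaults reversible to true; L3 requires the attribute
    rev <- if (is.na(rev)) TRUE else rev == "true"
    get_side <- function(tag, sgn) {
      refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0) return(numeric(0))
      coef <- xml2::xml_attr(refs, "stoichiometry")
      coef <- ifelse(is.na(coef), 1, as.numeric(coef))
      stats::setNames(sgn * coef, xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    agg <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(agg), names(agg))
    st <- st[st != 0]
    reaction(id, st, reversible = rev)
  })
  metnet(mets, rxns)
}

#' Write a network as SBML Level 3 Version 1
#'
#' @param net a `metnet`
#' @param path output path
#' @export
write_network_sbml <- function(net, path) {
  comps <- unique(net$metabolites$compartment)
  comps[comps == ""] <- "default"
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "model")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(comps)) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    cp <- if (m$compartment == "") "default" else m$compartment
    xml2::xml_add_child(ls, "species", id = m$id, name = m$name, compartment = cp,
      hasOnlySubstanceUnits = "false", constant = "false",
      boundaryCondition = if (m$external) "true" else "false")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (r in net$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
      reversible = if (r$reversible) "true" else "false", fast = "false")
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      side <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(side, "speciesReference", species = m,
          stoichiometry = format(-unname(subs[m])), constant = "true")
      }
    }
    if (length(prods)) {
      side <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(side, "speciesReference", species = m,
          stoichiometry = format(unname(prods[m])), constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Serialize a network to JSON
#'
#' @param net a `metnet`
#' @param path optional output path; if `NULL` the JSON string is returned
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(
    metabolites = net$metabolites,
    reactions = lapply(unname(net$reactions), function(r) {
      list(id = r$id, stoichiometry = as.list(r$stoich),
           reversible = r$reversible, origin = r$origin)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
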