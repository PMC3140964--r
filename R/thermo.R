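# Gibbs free energy of overall conversions from transformed formation
# energies and metabolite concentrations.

#' Thermodynamic table
#'
#' Transformed Gibbs energies of formation (kJ/mol at the stated pH) and
#' molar concentrations for metabolites. Metabolites without a measured
#' concentration fall back to `default_conc` (1 mM, a conventional
#' physiological default).
#'
#' @param formation_energy named numeric vector, kJ/mol
#' @param concentration named numeric vector, mol/l (may be empty)
#' @param pH pH at which the formation energies are transformed
#' @param temperature temperature in kelvin (default 37 degrees C)
#' @param default_conc fallback concentration, mol/l
#' @export
thermo_table <- function(formation_energy, concentration = numeric(0),
                         pH = 7.2, temperature = 310.15, default_conc = 1e-3) {
  stopifnot(!is.null(names(formation_energy)))
  structure(list(formation_energy = formation_energy,
                 concentration = concentration,
                 pH = pH, temperature = temperature,
                 R = 8.31446e-3, # kJ/(mol K)
                 default_conc = default_conc),
            class = "thermo_table")
}

#' Read a thermodynamic table from TSV
#'
#' Columns: `metabolite`, `formation_energy` (kJ/mol), `concentration`
#' (mol/l; empty or NA = use the default).
#'
#' @param path file path
#' @param ... passed on to [thermo_table()]
#' @export
read_thermo_tsv <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "formation_energy")
  if (!all(need %in% names(df))) {
    stop("thermo TSV must have columns: ", paste(need, collapse = ", "))
  }
  fe <- stats::setNames(df$formation_energy, df$metabolite)
  conc <- numeric(0)
  if ("concentration" %in% names(df)) {
    ok <- !is.na(df$concentration)
    conc <- stats::setNames(df$concentration[ok], df$metabolite[ok])
  }
  thermo_table(fe, conc, ...)
}

#' Write a thermodynamic table to TSV
#' @param table a [thermo_table()]
#' @param path output path
#' @export
write_thermo_tsv <- function(table, path) {
  mets <- names(table$formation_energy)
  conc <- table$concentration[mets]
  utils::write.table(
    data.frame(metabolite = mets,
               formation_energy = unname(table$formation_energy),
               concentration = unname(conc)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gibbs free energy change of an overall conversion
#'
#' Computes `sum_i s_i dGf_i - sum_j s_j dGf_j + R T (sum_i s_i ln c_i -
#' sum_j s_j ln c_j)` over products i and substrates j of the net
#' stoichiometry, using transformed formation energies and concentrations
#' from the table.
#'
#' @param stoich named numeric vector of the overall conversion
#'   (negative = substrate)
#' @param table a [thermo_table()]
#' @return kJ per mole of conversion
#' @export
gibbs_change <- function(stoich, table) {
  if (length(stoich) == 0) return(0)
  missing_fe <- setdiff(names(stoich), names(table$formation_energy))
  if (length(missing_fe)) {
    stop("no formation energy for: ", paste(missing_fe, collapse = ", "))
  }
  fe <- table$formation_energy[names(stoich)]
  conc <- rep(table$default_conc, length(stoich))
  names(conc) <- names(stoich)
  known <- intersect(names(stoich), names(table$concentration))
  conc[known] <- table$concentration[known]
  sum(stoich * fe) + table$R * table$temperature * sum(stoich * log(conc))
}

#' Net stoichiometry of a flux mode or route flux
#'
#' The overall conversion carried by a flux vector: the net production of
#' every metabolite (external metabolites included). Entries below 1e-9 in
#' magnitude are dropped.
#'
#' @param net a `metnet`
#' @param flux named numeric flux vector
#' @param drop_exchanges ignore boundary exchange fluxes (`EX_in_`/
#'   `EX_out_` columns), so the conversion shows what the carried pathway
#'   itself turns over rather than zeros at the exchanged species
#' @return named numeric vector (negative = net substrate)
#' @export
net_conversion <- function(net, flux, drop_exchanges = FALSE) {
  S <- stoich_matrix(net, internal_only = FALSE)
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  v[names(flux)] <- flux
  if (drop_exchanges) v[grep("^EX_(in|out)_", names(v))] <- 0
  tot <- as.vector(S %*% v)
  names(tot) <- rownames(S)
  tot[abs(tot) > 1e-9]
}
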