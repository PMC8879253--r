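#' Compartmentalised metabolic networks
#'
#' A `metabolic_network` is the shared representation used by both the
#' pathway-scale kinetic model and the medium-scale stoichiometric model.
#' It holds three compartments tables:
#' \describe{
#'   \item{compartments}{`id`, `name`, `relative_volume` (fraction of the
#'     cytosol volume, dimensionless, > 0).}
#'   \item{metabolites}{`id`, `name`, `compartment`, `formula` (optional
#'     elemental formula; may be `NA`), `n_carbon` (integer carbons per
#'     molecule), `boundary` (fixed-concentration / exchange species).}
#'   \item{reactions}{`id`, `name`, `reversible`, `lb`, `ub`, `transport`,
#'     `ec` plus a parallel `stoichiometry` list mapping reaction id to a
#'     named numeric vector of signed coefficients.}
#' }
#'
#' Flux units are contextual: mmol.min-1.L-1 in the kinetic model,
#' mmol.gDW-1.h-1 in the stoichiometric model.
#'
#' @param compartments data.frame with columns id, name, relative_volume.
#' @param metabolites data.frame with columns id, name, compartment,
#'   formula, n_carbon, boundary.
#' @param reactions data.frame with columns id, name, reversible, lb, ub,
#'   transport and optionally ec.
#' @param stoichiometry named list (one element per reaction id) of named
#'   numeric coefficient vectors (negative = consumed).
#' @return An object of class `metabolic_network`.
#' @seealso [build_kinetic_network()], [validate_network()],
#'   [stoich_matrix()]
#' @export
metabolic_network <- function(compartments, metabolites, reactions, stoichiometry) {
  stopifnot(is.data.frame(compartments), is.data.frame(metabolites),
            is.data.frame(reactions), is.list(stoichiometry))
  if (is.null(reactions$ec)) reactions$ec <- NA_character_
  if (anyDuplicated(compartments$id)) stop("duplicate compartment ids")
  if (anyDuplicated(metabolites$id))  stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id))    stop("duplicate reaction ids")
  if (!setequal(names(stoichiometry), reactions$id))
    stop("stoichiometry list must have exactly one entry per reaction id")
  stoichiometry <- stoichiometry[reactions$id]
  net <- structure(list(
    compartments = compartments,
    metabolites  = metabolites,
    reactions    = reactions,
    stoichiometry = stoichiometry
  ), class = "metabolic_network")
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:",
      nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,",
      nrow(x$compartments), "compartments\n")
  ntr <- sum(x$reactions$transport)
  cat("  transport reactions:", ntr,
      " boundary species:", sum(x$metabolites$boundary), "\n")
  invisible(x)
}

#' Count carbon atoms in an elemental formula
#'
#' @param formula character formula such as `"C6H12O6"`.
#' @return integer carbon count (0 when no C present).
#' @keywords internal
formula_carbon <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_integer_)
    m <- regmatches(f, gregexpr("C(?![a-z])([0-9]*)", f, perl = TRUE))[[1]]
    if (length(m) == 0) return(0L)
    sum(vapply(m, function(tok) {
      n <- sub("^C", "", tok)
      if (nzchar(n)) as.integer(n) else 1L
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

# carbons per molecule for common substrates, usable without a network
.substrate_carbons <- c(
  glucose = 6L, glycerol = 3L, ethanol = 2L, acetate = 2L,
  water = 0L, co2 = 1L, dha = 22L
)

#' Carbons per molecule of a substrate or network metabolite
#'
#' Looks a name up among the built-in substrates (glucose, glycerol,
#' ethanol, acetate, water, co2, dha) and, when a network is supplied,
#' among its metabolite ids and names.
#'
#' @param name substrate or metabolite name/id.
#' @param network optional `metabolic_network` to search.
#' @return integer number of carbon atoms per molecule.
#' @export
carbon_count <- function(name, network = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  if (key %in% names(.substrate_carbons))
    return(unname(.substrate_carbons[[key]]))
  if (!is.null(network)) {
    met <- network$metabolites
    hit <- which(met$id == name | tolower(met$name) == key)
    if (length(hit) >= 1L) return(as.integer(met$n_carbon[hit[1L]]))
  }
  stop("unknown metabolite or substrate: ", name)
}

#' Validate a metabolic network
#'
#' Checks structural invariants (resolvable stoichiometry keys, existing
#' compartments, positive volumes, bound ordering, irreversibility implying
#' a non-negative lower bound, non-empty stoichiometries, formula/carbon
#' agreement) and, optionally, per-reaction carbon conservation.
#' Violations are returned as data, not raised as conditions.
#'
#' @param network a `metabolic_network`.
#' @param check_elements when `TRUE`, additionally require that every
#'   non-transport, non-exchange, non-biomass reaction conserves carbon
#'   (sum of coefficient x n_carbon equal to zero).
#' @return character vector of violation messages; empty if the network is
#'   valid.
#' @export
validate_network <- function(network, check_elements = FALSE) {
  v <- character(0)
  cmp <- network$compartments; met <- network$metabolites
  rxn <- network$reactions;    sto <- network$stoichiometry
  if (any(cmp$relative_volume <= 0))
    v <- c(v, paste0("non-positive compartment volume: ",
                     paste(cmp$id[cmp$relative_volume <= 0], collapse = ", ")))
  bad_cmp <- setdiff(met$compartment, cmp$id)
  if (length(bad_cmp))
    v <- c(v, paste0("metabolite compartment not defined: ",
                     paste(bad_cmp, collapse = ", ")))
  has_formula <- !is.na(met$formula) & nzchar(met$formula)
  if (any(has_formula)) {
    fc <- formula_carbon(met$formula[has_formula])
    mism <- which(fc != met$n_carbon[has_formula])
    if (length(mism))
      v <- c(v, paste0("n_carbon disagrees with formula: ",
                       paste(met$id[has_formula][mism], collapse = ", ")))
  }
  for (i in seq_len(nrow(rxn))) {
    id <- rxn$id[i]; s <- sto[[id]]
    if (length(s) == 0) { v <- c(v, paste0("empty stoichiometry: ", id)); next }
    unknown <- setdiff(names(s), met$id)
    if (length(unknown))
      v <- c(v, paste0("reaction ", id, " references unknown metabolite(s): ",
                       paste(unknown, collapse = ", ")))
    if (rxn$lb[i] > rxn$ub[i])
      v <- c(v, paste0("reaction ", id, ": lower bound exceeds upper bound"))
    if (!rxn$reversible[i] && rxn$lb[i] < 0)
      v <- c(v, paste0("reaction ", id, ": irreversible but lower bound < 0"))
  }
  if (check_elements) {
    nc <- stats::setNames(met$n_carbon, met$id)
    skip <- rxn$transport | grepl("^ex_", rxn$id) | grepl("biomass", rxn$id)
    for (i in which(!skip)) {
      id <- rxn$id[i]; s <- sto[[id]]
      known <- intersect(names(s), met$id)
      bal <- sum(s[known] * nc[known])
      if (abs(bal) > 1e-9)
        v <- c(v, paste0("reaction ", id, " does not conserve carbon (net ",
                         format(bal), ")"))
    }
  }
  v
}

#' Stoichiometric matrix of a network
#'
#' @param network a `metabolic_network`.
#' @param internal_only drop boundary (fixed/exchange) species rows.
#' @return numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(network, internal_only = FALSE) {
  met <- network$metabolites$id
  rxn <- network$reactions$id
  S <- matrix(0, nrow = length(met), ncol = length(rxn),
              dimnames = list(met, rxn))
  for (j in seq_along(rxn)) {
    s <- network$stoichiometry[[rxn[j]]]
    keep <- intersect(names(s), met)
    S[keep, j] <- s[keep]
  }
  if (internal_only) S <- S[!network$metabolites$boundary, , drop = FALSE]
  S
}

#' Parse a reaction equation string
#'
#' Equations use `"->"` for irreversible and `"<=>"` for reversible
#' reactions, e.g. `"1 fdp_c -> 1 dhap_c + 1 gra3p_c"`.  Coefficients
#' default to 1 when omitted.
#'
#' @param equation equation string.
#' @return list with elements `stoichiometry` (named numeric) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  reversible <- grepl("<=>", equation, fixed = TRUE)
  sides <- if (reversible) strsplit(equation, "<=>", fixed = TRUE)[[1]]
           else            strsplit(equation, "->",  fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("malformed equation: ", equation)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) next
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("bad coefficient in term: ", term)
        out[toks[2]] <- sign * coef + (if (toks[2] %in% names(out)) out[toks[2]] else 0)
      } else if (length(toks) == 1L) {
        out[toks[1]] <- sign * 1 + (if (toks[1] %in% names(out)) out[toks[1]] else 0)
      } else stop("bad term: ", term)
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  s <- lhs
  for (m in names(rhs)) s[m] <- (if (m %in% names(s)) s[m] else 0) + rhs[m]
  s <- s[s != 0]
  list(stoichiometry = s, reversible = reversible)
}

#' Format a stoichiometry vector as an equation string
#'
#' @param stoichiometry named numeric coefficient vector.
#' @param reversible logical; selects `"<=>"` versus `"->"`.
#' @return equation string.
#' @export
format_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(v, nm) {
    if (length(v) == 0) return("")
    paste(paste(format(abs(v), trim = TRUE, scientific = FALSE), nm),
          collapse = " + ")
  }
  lhs <- stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt(unname(lhs), names(lhs)),
        if (reversible) "<=>" else "->",
        fmt(unname(rhs), names(rhs)))
}

#' Write a network to the two-file tabular format
#'
#' Writes `<stem>_metabolites.tsv` (id, name, compartment, formula,
#' n_carbon, boundary) and `<stem>_reactions.tsv` (id, name, equation,
#' reversible, lb, ub, transport, ec).  A third small file
#' `<stem>_compartments.tsv` carries the compartment volumes.
#'
#' @param network a `metabolic_network`.
#' @param stem path prefix for the output files.
#' @return (invisibly) the three file paths written.
#' @export
write_network_tsv <- function(network, stem) {
  mf <- paste0(stem, "_metabolites.tsv")
  rf <- paste0(stem, "_reactions.tsv")
  cf <- paste0(stem, "_compartments.tsv")
  utils::write.table(network$metabolites, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rx <- network$reactions
  rx$equation <- vapply(rx$id, function(id)
    format_equation(network$stoichiometry[[id]],
                    network$reactions$reversible[network$reactions$id == id]),
    character(1))
  rx <- rx[, c("id", "name", "equation", "reversible", "lb", "ub", "transport", "ec")]
  utils::write.table(rx, rf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$compartments, cf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metabolites = mf, reactions = rf, compartments = cf))
}

#' Read a network from the two-file tabular format
#'
#' Inverse of [write_network_tsv()].
#'
#' @param stem path prefix used when the files were written.
#' @return a `metabolic_network`.
#' @export
read_network_tsv <- function(stem) {
  met <- utils::read.delim(paste0(stem, "_metabolites.tsv"),
                           stringsAsFactors = FALSE)
  rx  <- utils::read.delim(paste0(stem, "_reactions.tsv"),
                           stringsAsFactors = FALSE)
  cmp <- utils::read.delim(paste0(stem, "_compartments.tsv"),
                           stringsAsFactors = FALSE)
  met$formula <- as.character(met$formula)
  sto <- lapply(rx$equation, function(eq) parse_equation(eq)$stoichiometry)
  names(sto) <- rx$id
  rx$equation <- NULL
  metabolic_network(cmp, met, rx, sto)
}
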