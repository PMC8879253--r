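# Minimal SBML level-3 core reader/writer.  Only the constructs the two
# models need are covered: compartments (with size), species (with
# boundaryCondition), reactions (reversible flag, reactant/product
# stoichiometries).  Package-specific fields (carbon counts, flux bounds,
# transport flags, kinetic rate-law parameters) travel in a JSON payload
# inside each element's <annotation>, so a round trip is loss-free while
# the core remains consumable by standard SBML tooling.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"

.annotate <- function(node, payload) {
  ann <- xml2::xml_add_child(node, "annotation")
  meta <- xml2::xml_add_child(ann, "dhafluxMeta")
  xml2::xml_set_text(meta, jsonlite::toJSON(payload, auto_unbox = TRUE,
                                            digits = NA, null = "null"))
  invisible(node)
}

.read_annotation <- function(node) {
  meta <- xml2::xml_find_first(node, ".//*[local-name()='dhafluxMeta']")
  if (inherits(meta, "xml_missing")) return(NULL)
  jsonlite::fromJSON(xml2::xml_text(meta), simplifyVector = TRUE)
}

#' Export a network (optionally with kinetic rate laws) to SBML
#'
#' @param network a `metabolic_network`.
#' @param path output file path.
#' @param rate_laws optional named list of [rate_law()] objects keyed by
#'   reaction id; serialised into per-reaction annotations.
#' @return (invisibly) `path`.
#' @export
write_sbml <- function(network, path, rate_laws = NULL) {
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "dhaflux_model")

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(network$compartments))) {
    cmp <- network$compartments[i, ]
    xml2::xml_add_child(lc, "compartment", id = cmp$id, name = cmp$name,
                        size = format(cmp$relative_volume, digits = 15),
                        constant = "true")
  }

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites))) {
    met <- network$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = met$id, name = met$name,
                              compartment = met$compartment,
                              boundaryCondition = tolower(as.character(met$boundary)),
                              hasOnlySubstanceUnits = "false", constant = "false")
    .annotate(sp, list(n_carbon = met$n_carbon,
                       formula = if (is.na(met$formula)) NULL else met$formula))
  }

  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$reactions))) {
    rx <- network$reactions[i, ]
    s <- network$stoichiometry[[rx$id]]
    rn <- xml2::xml_add_child(lr, "reaction", id = rx$id, name = rx$name,
                              reversible = tolower(as.character(rx$reversible)),
                              fast = "false")
    payload <- list(lb = rx$lb, ub = rx$ub, transport = rx$transport,
                    ec = if (is.na(rx$ec)) NULL else rx$ec)
    if (!is.null(rate_laws) && rx$id %in% names(rate_laws)) {
      law <- rate_laws[[rx$id]]
      # named maps go through as JSON objects (auto_unbox would strip the
      # metabolite names off length-1 vectors)
      payload$rate_law <- list(
        form = law$form, Vm = law$Vm, k_over = law$k_over,
        Km = as.list(law$Km),
        Keq = if (is.na(law$Keq)) NULL else law$Keq,
        substrates = as.list(law$substrates),
        products = as.list(law$products))
    }
    .annotate(rn, payload)
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lre, "speciesReference", species = m,
                            stoichiometry = format(-reac[[m]], digits = 15),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lpr, "speciesReference", species = m,
                            stoichiometry = format(prod[[m]], digits = 15),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from SBML written by [write_sbml()]
#'
#' Core constructs (compartments, species, reactions, stoichiometry,
#' reversibility) are read from any SBML level-3 file; package-specific
#' fields are recovered from annotations when present and defaulted
#' otherwise.
#'
#' @param path SBML file path.
#' @return list with elements `network` (a `metabolic_network`) and
#'   `rate_laws` (named list, possibly empty).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find_all <- function(x, nm)
    xml2::xml_find_all(x, paste0(".//*[local-name()='", nm, "']"))
  attr1 <- function(node, a) xml2::xml_attr(node, a)

  cnodes <- find_all(doc, "compartment")
  cmp <- data.frame(
    id = vapply(cnodes, attr1, "", a = "id"),
    name = vapply(cnodes, attr1, "", a = "name"),
    relative_volume = as.numeric(vapply(cnodes, attr1, "", a = "size")),
    stringsAsFactors = FALSE)

  snodes <- find_all(doc, "species")
  met <- do.call(rbind, lapply(snodes, function(sp) {
    meta <- .read_annotation(sp)
    data.frame(id = attr1(sp, "id"), name = attr1(sp, "name"),
               compartment = attr1(sp, "compartment"),
               formula = if (!is.null(meta$formula)) meta$formula else NA_character_,
               n_carbon = if (!is.null(meta$n_carbon)) as.integer(meta$n_carbon) else 0L,
               boundary = identical(attr1(sp, "boundaryCondition"), "true"),
               stringsAsFactors = FALSE)
  }))

  rnodes <- find_all(doc, "reaction")
  rows <- list(); sto <- list(); laws <- list()
  for (rn in rnodes) {
    id <- attr1(rn, "id")
    meta <- .read_annotation(rn)
    rev <- identical(attr1(rn, "reversible"), "true")
    s <- numeric(0)
    for (sr in find_all(rn, "speciesReference")) {
      coef <- as.numeric(attr1(sr, "stoichiometry"))
      parent <- xml2::xml_name(xml2::xml_parent(sr))
      sgn <- if (identical(parent, "listOfReactants")) -1 else 1
      m <- attr1(sr, "species")
      s[m] <- (if (m %in% names(s)) s[m] else 0) + sgn * coef
    }
    rows[[id]] <- data.frame(
      id = id, name = attr1(rn, "name"), reversible = rev,
      lb = if (!is.null(meta$lb)) meta$lb else if (rev) -1000 else 0,
      ub = if (!is.null(meta$ub)) meta$ub else 1000,
      transport = isTRUE(meta$transport),
      ec = if (!is.null(meta$ec)) meta$ec else NA_character_,
      stringsAsFactors = FALSE)
    sto[[id]] <- s
    if (!is.null(meta$rate_law)) {
      rl <- meta$rate_law
      laws[[id]] <- rate_law(form = rl$form, Vm = rl$Vm, k_over = rl$k_over,
                             Km = unlist(rl$Km),
                             Keq = if (is.null(rl$Keq)) NA_real_ else rl$Keq,
                             substrates = unlist(rl$substrates),
                             products = unlist(rl$products))
    }
  }
  network <- metabolic_network(cmp, met, do.call(rbind, rows), sto)
  list(network = network, rate_laws = laws)
}
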