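#' Biomass composition
#'
#' Macromolecule mass fractions (g per gDW) mapped to lumped precursor
#' demands (mmol per gDW).  Protein is resolved into five precursor
#' families (glutamate, aspartate, alanine, serine, aromatic), carbohydrate
#' into anhydroglucose units, lipid into a C18 acyl pool plus DHA, and
#' RNA/DNA into an average nucleotide.
#'
#' @param fraction_overrides named numeric vector overriding the default
#'   macromolecule fractions (`protein`, `carbohydrate`, `lipid`, `RNA`,
#'   `DNA`, `DHA`, `ash`); `lipid` is the non-DHA lipid fraction.
#' @param gam growth-associated ATP demand, mmol gDW-1.
#' @return object of class `biomass_composition` with `fractions`,
#'   `precursors` (mmol/gDW), `masses` (g/mol) and `gam`.
#' @export
gen_biomass_composition <- function(fraction_overrides = NULL, gam = 0) {
  fr <- c(protein = 0.45, carbohydrate = 0.25, lipid = 0.165,
          DHA = 0.035, RNA = 0.06, DNA = 0.01, ash = 0.03)
  if (!is.null(fraction_overrides)) {
    bad <- setdiff(names(fraction_overrides), names(fr))
    if (length(bad)) stop("unknown biomass fraction(s): ",
                          paste(bad, collapse = ", "))
    fr[names(fraction_overrides)] <- fraction_overrides
  }
  if (sum(fr) > 1 + 1e-9) stop("biomass fractions sum above 1")
  # protein precursor family shares (mol fraction of residues)
  aa_share <- c(glu = 0.30, asp = 0.28, ala = 0.22, ser = 0.12, aro = 0.08)
  aa_residue_mass <- c(glu = 129.1, asp = 115.1, ala = 71.1, ser = 87.1,
                       aro = 150.0)
  res_mass <- sum(aa_share * aa_residue_mass)
  res_mmol <- 1000 * fr[["protein"]] / res_mass
  prec <- c(
    glu_c  = res_mmol * aa_share[["glu"]],
    asp_c  = res_mmol * aa_share[["asp"]],
    ala_c  = res_mmol * aa_share[["ala"]],
    ser_c  = res_mmol * aa_share[["ser"]],
    aro_c  = res_mmol * aa_share[["aro"]],
    carb_c = 1000 * fr[["carbohydrate"]] / 162.14,
    c18_c  = 1000 * fr[["lipid"]] / 284.5,
    dha_c  = 1000 * fr[["DHA"]] / 328.5,
    nmp_c  = 1000 * (fr[["RNA"]] + fr[["DNA"]]) / 321.0
  )
  structure(list(fractions = fr, precursors = prec,
                 masses = c(glu_c = 129.1, asp_c = 115.1, ala_c = 71.1,
                            ser_c = 87.1, aro_c = 150.0, carb_c = 162.14,
                            c18_c = 284.5, dha_c = 328.5, nmp_c = 321.0),
                 gam = gam),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("Biomass composition (g/gDW):\n")
  print(round(x$fractions, 3))
  cat("precursor demands (mmol/gDW):\n")
  print(round(x$precursors, 4))
  invisible(x)
}

#' Read a biomass composition from delimited text
#'
#' Two-column file (component, g_per_gDW) with component names matching
#' the macromolecule fractions of [gen_biomass_composition()].
#'
#' @param path file path.
#' @param ... passed to [gen_biomass_composition()].
#' @return a `biomass_composition`.
#' @export
read_biomass_composition <- function(path, ...) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  gen_biomass_composition(stats::setNames(d[[2]], d[[1]]), ...)
}

# carbon counts for the stoich-only species
.stoich_extra_mets <- function() {
  m <- function(id, name, comp, nc, boundary = FALSE)
    data.frame(id = id, name = name, compartment = comp, formula = NA,
               n_carbon = nc, boundary = boundary, stringsAsFactors = FALSE)
  rbind(
    m("ac_e",    "external acetate",  "e", 2L),
    m("o2_e",    "external oxygen",   "e", 0L),
    m("co2_e",   "external CO2",      "e", 1L),
    m("h2o_e",   "external water",    "e", 0L),
    m("h_e",     "external proton",   "e", 0L),
    m("nh3_e",   "external ammonia",  "e", 0L),
    m("biomass_e", "biomass",         "e", 0L),
    m("dha_e",   "secreted DHA",      "e", 22L),
    m("o2_c",    "oxygen",            "c", 0L),
    m("o2_m",    "oxygen (mito)",     "m", 0L),
    m("co2_c",   "CO2 (cytosol)",     "c", 1L),
    m("h2o_c",   "water",             "c", 0L),
    m("h2o_m",   "water (mito)",      "m", 0L),
    m("h_c",     "proton",            "c", 0L),
    m("nh3_c",   "ammonia",           "c", 0L),
    m("atp_c",   "ATP equivalent",    "c", 0L),
    m("atp_m",   "ATP equivalent (mito)", "m", 0L),
    m("nadh_c",  "NADH equivalent",   "c", 0L),
    m("nadh_m",  "NADH equivalent (mito)", "m", 0L),
    m("nadph_c", "NADPH equivalent",  "c", 0L),
    m("pg6_c",   "6-phosphogluconate", "c", 6L),
    m("ru5p_c",  "ribulose 5-phosphate", "c", 5L),
    m("r5p_c",   "ribose 5-phosphate", "c", 5L),
    m("xu5p_c",  "xylulose 5-phosphate", "c", 5L),
    m("s7p_c",   "sedoheptulose 7-phosphate", "c", 7L),
    m("e4p_c",   "erythrose 4-phosphate", "c", 4L),
    m("glu_c",   "glutamate family precursor", "c", 5L),
    m("asp_c",   "aspartate family precursor", "c", 4L),
    m("ala_c",   "alanine family precursor", "c", 3L),
    m("ser_c",   "serine family precursor", "c", 3L),
    m("aro_c",   "aromatic precursor", "c", 10L),
    m("akg_c",   "2-oxoglutarate (cytosol)", "c", 5L),
    m("mal_c",   "malate (cytosol)",  "c", 4L),
    m("glx_m",   "glyoxylate",        "m", 2L),
    m("glyc3p_m", "glycerol 3-phosphate (mito)", "m", 3L),
    m("dhap_m",  "dihydroxyacetone phosphate (mito)", "m", 3L),
    m("nmp_c",   "average nucleotide", "c", 9L),
    m("carb_c",  "carbohydrate unit", "c", 6L),
    m("c18_c",   "C18 acyl unit",     "c", 18L),
    m("dha_c",   "docosahexaenoate",  "c", 22L),
    m("accoa_fa_c", "Acetyl-CoA committed to fatty-acid synthesis", "c", 2L),
    m("biomass_c", "biomass (cytosol)", "c", 0L)
  )
}

# stoich versions of the kinetic reactions carry the energy and redox
# cofactors that the kinetic model lumps away
.stoich_cofactor_patch <- list(
  hk      = c(atp_c = -1),
  pfk     = c(atp_c = -1),
  gra3pdh = c(nadh_c = 1),
  pgk     = c(atp_c = 1),
  pyk     = c(atp_c = 1),
  glyk    = c(atp_c = -1),
  g3pd    = c(nadh_c = 1),
  adh     = c(nadh_c = 1),
  aldh    = c(nadh_c = 1),
  acalig  = c(atp_c = -1),   # ATP->AMP ligase with pyrophosphate energy recovery
  pdh     = c(nadh_m = 1),
  pyc     = c(atp_m = -1),
  ide     = c(nadh_m = 1),
  ogdh    = c(nadh_m = 1),
  ss      = c(atp_m = 1),
  sde     = c(nadh_m = 1),
  mde     = c(nadh_m = 1),
  me      = c(nadh_m = 1),
  acl     = c(atp_c = -1)
)

#' Build the medium-scale constraint-based stoichiometric model
#'
#' Constructs a reduced central-carbon reconstruction in three
#' compartments: the complete kinetic subnetwork (same reaction ids,
#' extended with energy/redox cofactors), pentose phosphate pathway,
#' gluconeogenesis, glyoxylate shunt, lumped amino-acid / nucleotide /
#' carbohydrate / fatty-acid synthesis to DHA, lumped oxidative ATP
#' generation, the biomass equation derived from `composition`, a DHA
#' overproduction sink, and the exchange set (glucose, glycerol, ethanol,
#' acetate, O2, CO2, H2O, H+, ammonia, biomass, DHA).  Flux unit:
#' mmol gDW-1 h-1 (biomass flux in h-1).
#'
#' @param composition a [gen_biomass_composition()].
#' @return object of class `stoich_model` with fields `network`,
#'   `composition`, `biomass_reaction`, `dha_reaction`, `exchanges`.
#' @export
build_stoich_model <- function(composition = gen_biomass_composition()) {
  stopifnot(inherits(composition, "biomass_composition"))
  kin <- build_kinetic_network()
  mets <- rbind(kin$metabolites, .stoich_extra_mets())
  # every species is balanced in the stoichiometric model; openness enters
  # only through the exchange reactions
  mets$boundary <- FALSE
  # the kinetic Acetyl-CoA sink species is not part of the stoich scope
  mets <- mets[mets$id != "accoa_sink_e", ]

  rx_rows <- kin$reactions
  sto <- kin$stoichiometry
  # repurpose the kinetic sink as the committed fatty-acid supply step
  sto[["accoa_sink"]] <- c(accoa_c = -1, accoa_fa_c = 1, coa_c = 1)
  for (id in names(.stoich_cofactor_patch)) {
    p <- .stoich_cofactor_patch[[id]]
    s <- sto[[id]]
    for (mname in names(p))
      s[mname] <- (if (mname %in% names(s)) s[mname] else 0) + p[[mname]]
    sto[[id]] <- s
  }

  r <- function(id, name, eq, transport = FALSE, lb = NULL, ub = 1000) {
    p <- parse_equation(eq)
    if (is.null(lb)) lb <- if (p$reversible) -1000 else 0
    list(row = data.frame(id = id, name = name, reversible = p$reversible,
                          lb = lb, ub = ub, transport = transport,
                          ec = NA_character_, stringsAsFactors = FALSE),
         stoich = p$stoichiometry)
  }
  pr <- composition$precursors
  biomass_lhs <- paste(
    paste(sprintf("%.6f", unname(pr)), names(pr), collapse = " + "),
    "+", sprintf("%.6f", composition$gam), "atp_c")
  defs <- list(
    # pentose phosphate pathway
    r("g6pd", "glucose-6-phosphate dehydrogenase",
      "g6p_c -> pg6_c + nadph_c"),
    r("gnd",  "6-phosphogluconate dehydrogenase",
      "pg6_c -> ru5p_c + co2_c + nadph_c"),
    r("rpi",  "ribose-5-phosphate isomerase", "ru5p_c <=> r5p_c"),
    r("rpe",  "ribulose-5-phosphate epimerase", "ru5p_c <=> xu5p_c"),
    r("tkt1", "transketolase 1", "xu5p_c + r5p_c <=> s7p_c + gra3p_c"),
    r("tal",  "transaldolase", "s7p_c + gra3p_c <=> e4p_c + f6p_c"),
    r("tkt2", "transketolase 2", "xu5p_c + e4p_c <=> f6p_c + gra3p_c"),
    # gluconeogenesis
    r("pepck", "PEP carboxykinase", "oaa_c + atp_c -> pep_c + co2_c"),
    r("fbpase", "fructose-1,6-bisphosphatase", "fdp_c -> f6p_c"),
    r("mdh_c", "malate dehydrogenase (cytosolic)",
      "mal_c <=> oaa_c + nadh_c"),
    # glyoxylate shunt
    r("icl", "isocitrate lyase", "icit_m -> glx_m + succ_m"),
    r("mas", "malate synthase", "glx_m + accoa_m -> mal_m + coa_m"),
    # dinoflagellate-type pyruvate:NADP+ oxidoreductase (PNO): a
    # reversible pyruvate/Acetyl-CoA node alongside the committed PDH
    r("pno", "pyruvate:NADP+ oxidoreductase (reversible)",
      "pyr_m + coa_m <=> accoa_m + co2_m + nadh_m"),
    # lumped phosphoketolase + phosphotransacetylase: carbon-lossless
    # acetyl supply from sugar phosphates
    r("pk_f6p", "phosphoketolase (F6P, lumped with PTA)",
      "f6p_c + coa_c -> e4p_c + accoa_c"),
    r("pk_x5p", "phosphoketolase (X5P, lumped with PTA)",
      "xu5p_c + coa_c -> gra3p_c + accoa_c"),
    # amino-acid family synthesis (nitrogen enters via glutamate)
    r("gdh", "glutamate dehydrogenase (biosynthetic)",
      "akg_c + nh3_c + nadph_c -> glu_c"),
    r("alat", "alanine transaminase", "glu_c + pyr_c <=> akg_c + ala_c"),
    r("aspat", "aspartate transaminase", "glu_c + oaa_c <=> akg_c + asp_c"),
    r("sert", "serine synthesis (lumped)",
      "gri3p_c + glu_c -> ser_c + akg_c + nadh_c"),
    r("arot", "aromatic synthesis (lumped)",
      "e4p_c + 2 pep_c + glu_c + nadph_c -> aro_c + akg_c"),
    r("nmpsyn", "nucleotide synthesis (lumped)",
      "r5p_c + asp_c + glu_c + 2 atp_c -> nmp_c + akg_c"),
    r("carbsyn", "carbohydrate polymerisation (lumped)",
      "g6p_c + atp_c -> carb_c + h2o_c"),
    # fatty-acid synthesis
    r("fas18", "fatty-acid synthesis to C18 (lumped)",
      "9 accoa_fa_c + 16 nadph_c + 8 atp_c -> c18_c"),
    r("dhasyn", "polyketide-route DHA synthesis (lumped)",
      "11 accoa_fa_c + 14 nadph_c + 10 atp_c -> dha_c"),
    # non-phosphorylating NADP-GAPDH: direct lipogenic NADPH supply from
    # the triose oxidation step (widespread in chromalveolate lineages)
    r("gapn", "non-phosphorylating NADP-GAPDH",
      "gra3p_c -> gri3p_c + nadph_c"),
    # energy metabolism
    r("oxphos", "oxidative phosphorylation (lumped, P/O = 3)",
      "nadh_m + 0.5 o2_m -> 3 atp_m + h2o_m"),
    r("thd", "transhydrogenase (lumped)", "nadh_c <=> nadph_c"),
    r("atpdrain", "ATP dissipation / maintenance", "atp_c -> "),
    r("g3pdm", "glycerol-3-phosphate dehydrogenase (mito, FAD)",
      "glyc3p_m -> dhap_m + nadh_m"),
    # biomass and product
    r("biomass_syn", "biomass equation",
      paste(biomass_lhs, "-> biomass_c")),
    # transports
    r("act",   "acetate uptake", "ac_e -> ac_c", TRUE),
    r("o2t",   "O2 diffusion", "o2_e -> o2_c", TRUE),
    r("o2tm",  "O2 diffusion (mito)", "o2_c -> o2_m", TRUE),
    r("co2tm", "CO2 diffusion (mito)", "co2_m <=> co2_c", TRUE),
    r("co2t",  "CO2 diffusion", "co2_c <=> co2_e", TRUE),
    r("h2omt", "water transport (mito)", "h2o_m <=> h2o_c", TRUE),
    r("h2ot",  "water transport", "h2o_c <=> h2o_e", TRUE),
    r("ht",    "proton transport", "h_c <=> h_e", TRUE),
    r("nh3t",  "ammonia uptake", "nh3_e -> nh3_c", TRUE),
    r("akgt",  "2-oxoglutarate shuttle", "akg_m <=> akg_c", TRUE),
    r("malt",  "malate shuttle", "mal_m <=> mal_c", TRUE),
    r("atpt",  "adenine nucleotide translocase", "atp_m <=> atp_c", TRUE),
    r("redsh", "malate-aspartate shuttle (lumped NADH import)",
      "nadh_c -> nadh_m", TRUE),
    r("coat", "CoA carrier return", "coa_m -> coa_c", TRUE),
    r("glyc3pt", "glycerol-3-phosphate shuttle (in)",
      "glyc3p_c -> glyc3p_m", TRUE),
    r("dhapt", "glycerol-3-phosphate shuttle (out)",
      "dhap_m -> dhap_c", TRUE),
    r("biomass_t", "biomass export", "biomass_c -> biomass_e", TRUE),
    r("dhat",  "DHA export", "dha_c -> dha_e", TRUE),
    # exchanges (uptake = negative flux)
    r("ex_glc",  "glucose exchange",  "glucose_e -> ", TRUE, lb = 0),
    r("ex_glyc", "glycerol exchange", "glycerol_e -> ", TRUE, lb = 0),
    r("ex_etoh", "ethanol exchange",  "ethanol_e -> ", TRUE, lb = 0),
    r("ex_ac",   "acetate exchange",  "ac_e -> ", TRUE, lb = 0),
    r("ex_o2",   "O2 exchange",       "o2_e <=> ", TRUE, lb = -1000),
    r("ex_co2",  "CO2 exchange",      "co2_e -> ", TRUE, lb = 0),
    r("ex_h2o",  "water exchange",    "h2o_e <=> ", TRUE, lb = -1000),
    r("ex_h",    "proton exchange",   "h_e <=> ", TRUE, lb = -1000),
    r("ex_nh3",  "ammonia exchange",  "nh3_e <=> ", TRUE, lb = -1000),
    r("ex_biomass", "biomass sink",   "biomass_e -> ", TRUE, lb = 0),
    r("ex_dha",  "DHA sink",          "dha_e -> ", TRUE, lb = 0)
  )
  rows2 <- do.call(rbind, lapply(defs, `[[`, "row"))
  sto2 <- lapply(defs, `[[`, "stoich")
  names(sto2) <- rows2$id
  # uptake transports in the stoich scope are plain irreversible transports
  rows <- rbind(rx_rows, rows2)
  sto <- c(sto, sto2)
  net <- metabolic_network(kin$compartments, mets, rows, sto)
  structure(list(network = net, composition = composition,
                 biomass_reaction = "biomass_syn",
                 dha_reaction = "ex_dha",
                 exchanges = grep("^ex_", rows$id, value = TRUE),
                 substrate_exchange = c(glucose = "ex_glc",
                                        glycerol = "ex_glyc",
                                        ethanol = "ex_etoh",
                                        acetate = "ex_ac")),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Constraint-based stoichiometric model:",
      nrow(x$network$reactions), "reactions,",
      nrow(x$network$metabolites), "metabolites,",
      sum(x$network$reactions$transport), "transports\n")
  invisible(x)
}

#' Solve flux balance analysis on a stoichiometric model
#'
#' Maximizes (or minimizes) the flux of `objective_reaction` subject to
#' S v = 0 (all species balanced except the free CoA carriers) and the
#' model's flux bounds, optionally overridden by `fixed_bounds`.  With
#' `canonical = TRUE` the reported flux vector is canonicalised by
#' minimizing the total absolute flux at the fixed optimal objective
#' (parsimonious FBA), making reported distributions reproducible under
#' degenerate optima.
#'
#' @param model a `stoich_model`.
#' @param objective_reaction reaction id to optimize.
#' @param fixed_bounds named list/vector `reaction id -> c(lb, ub)`.
#' @param maximize direction.
#' @param canonical canonicalise the flux vector by parsimony.
#' @return object of class `fba_solution`: `status`, `objective_value`,
#'   `fluxes`.
#' @export
solve_fba <- function(model, objective_reaction, fixed_bounds = NULL,
                      maximize = TRUE, canonical = FALSE) {
  net <- model$network
  rxn <- net$reactions
  lb <- rxn$lb; ub <- rxn$ub
  names(lb) <- names(ub) <- rxn$id
  if (!is.null(fixed_bounds))
    for (id in names(fixed_bounds)) {
      if (!id %in% rxn$id) stop("unknown reaction in fixed_bounds: ", id)
      lb[id] <- fixed_bounds[[id]][1]
      ub[id] <- fixed_bounds[[id]][2]
    }
  stopifnot(objective_reaction %in% rxn$id)
  S <- stoich_matrix(net, internal_only = TRUE)
  obj <- as.numeric(rxn$id == objective_reaction)
  res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
  if (res$status != "optimal")
    return(structure(list(status = res$status,
                          objective_value = NA_real_, fluxes = NULL),
                     class = "fba_solution"))
  vopt <- res$objective
  fluxes <- stats::setNames(res$solution, rxn$id)
  if (canonical) {
    # minimize sum |v| at the fixed optimal objective; only columns that
    # can run negative need the p - q split
    n <- ncol(S)
    lb2 <- lb; ub2 <- ub
    lb2[objective_reaction] <- ub2[objective_reaction] <- vopt
    neg <- which(lb2 < 0)
    A2 <- cbind(S, -S[, neg, drop = FALSE])
    lbp <- pmax(lb2, 0); ubp <- pmax(ub2, 0)
    lbq <- pmax(-ub2[neg], 0); ubq <- pmax(-lb2[neg], 0)
    res2 <- lp_solve(rep(-1, n + length(neg)), A2, rep(0, nrow(S)),
                     c(lbp, lbq), c(ubp, ubq), maximize = TRUE)
    if (res2$status == "optimal") {
      v2 <- res2$solution[seq_len(n)]
      v2[neg] <- v2[neg] - res2$solution[n + seq_along(neg)]
      fluxes <- stats::setNames(v2, rxn$id)
    }
  }
  structure(list(status = "optimal", objective_value = vopt,
                 fluxes = fluxes),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 6))
  cat("\n")
  invisible(x)
}

# close all carbon uptakes, then open the named substrate
.growth_bounds <- function(model, substrate, uptake) {
  ex <- model$substrate_exchange
  if (!substrate %in% names(ex)) stop("unknown substrate: ", substrate)
  fb <- list()
  for (s in names(ex)) fb[[ex[[s]]]] <- c(0, 1000)
  fb[[ex[[substrate]]]] <- c(-uptake, 0)
  fb
}

#' Maximal growth on a single substrate
#'
#' Opens only the named substrate's carbon uptake (plus the inorganic
#' exchanges) at the given rate and maximizes the biomass reaction.
#'
#' @param model a `stoich_model`.
#' @param substrate `"glucose"`, `"glycerol"`, `"ethanol"` or `"acetate"`.
#' @param uptake uptake bound, mmol gDW-1 h-1.
#' @param canonical canonicalise the reported flux vector.
#' @return list with `mu_max` (h-1) and `solution` (an `fba_solution`).
#' @export
max_growth <- function(model, substrate, uptake, canonical = FALSE) {
  fb <- .growth_bounds(model, substrate, uptake)
  sol <- solve_fba(model, model$biomass_reaction, fixed_bounds = fb,
                   canonical = canonical)
  mu <- if (sol$status == "optimal") sol$objective_value else 0
  if (mu <= 1e-10 && sol$status == "optimal")
    attr(sol, "diagnostic") <- .blocked_precursors(model, fb)
  list(mu_max = mu, solution = sol)
}

# which biomass precursors cannot be produced at all (growth diagnosis)
.blocked_precursors <- function(model, fixed_bounds) {
  blocked <- character(0)
  for (p in names(model$composition$precursors)) {
    probe <- paste0("probe_", p)
    net2 <- model$network
    net2$reactions <- rbind(net2$reactions, data.frame(
      id = probe, name = probe, reversible = FALSE, lb = 0, ub = 1000,
      transport = FALSE, ec = NA_character_, stringsAsFactors = FALSE))
    net2$stoichiometry[[probe]] <- stats::setNames(-1, p)
    m2 <- model; m2$network <- net2
    s <- solve_fba(m2, probe, fixed_bounds = fixed_bounds)
    if (s$status != "optimal" || s$objective_value < 1e-9)
      blocked <- c(blocked, p)
  }
  blocked
}

#' Minimal substrate carbon per gram of biomass
#'
#' The model-optimal efficiency of carbon transformation into biomass:
#' n_C * uptake / mu_max at the FBA optimum, in mmol C1 per gDW.  The LP
#' is homogeneous in the uptake bound, so the value is uptake-scale
#' invariant.
#'
#' @param model a `stoich_model`.
#' @param substrate substrate name.
#' @param uptake uptake bound (the result does not depend on it).
#' @return carbon-per-biomass ratio, mmol C1 gDW-1.
#' @export
min_carbon_per_biomass <- function(model, substrate, uptake = 1) {
  g <- max_growth(model, substrate, uptake)
  if (g$mu_max <= 0) stop("model does not grow on ", substrate)
  carbon_count(substrate) * uptake / g$mu_max
}

#' DHA production potential at reduced biomass intensities
#'
#' For each biomass fraction f, biomass flux is fixed at f * mu_max and
#' DHA overproduction (the DHA sink flux) is maximized, mirroring the
#' assumption that every metabolic resource not invested in biomass is
#' redirected towards DHA.
#'
#' @param model a `stoich_model`.
#' @param substrate substrate name.
#' @param uptake uptake bound, mmol gDW-1 h-1.
#' @param biomass_fractions fractions of mu_max to scan (in (0, 1]).
#' @return data.frame of class `dha_scan`: fraction, mu, dha_flux
#'   (mmol gDW-1 h-1), pct_carbon_to_dha, pct_dha_of_tfa, status.
#' @export
dha_potential_scan <- function(model, substrate, uptake,
                               biomass_fractions = c(1, 0.8, 0.4)) {
  stopifnot(all(biomass_fractions > 0), all(biomass_fractions <= 1))
  g <- max_growth(model, substrate, uptake)
  if (g$mu_max <= 0) stop("model does not grow on ", substrate)
  nC <- carbon_count(substrate)
  pr <- model$composition$precursors
  out <- lapply(biomass_fractions, function(f) {
    mu <- f * g$mu_max
    fb <- .growth_bounds(model, substrate, uptake)
    fb[[model$biomass_reaction]] <- c(mu, mu)
    sol <- solve_fba(model, model$dha_reaction, fixed_bounds = fb)
    if (sol$status != "optimal")
      return(data.frame(fraction = f, mu = mu, dha_flux = NA_real_,
                        pct_carbon_to_dha = NA_real_,
                        pct_dha_of_tfa = NA_real_, status = sol$status,
                        stringsAsFactors = FALSE))
    vdha <- sol$objective_value
    # total DHA and fatty-acid mass flows, mg gDW-1 h-1
    dha_total  <- (vdha + mu * pr[["dha_c"]]) * 328.5
    tfa_total  <- dha_total + mu * pr[["c18_c"]] * 284.5
    data.frame(fraction = f, mu = mu, dha_flux = vdha,
               pct_carbon_to_dha = 100 * 22 * vdha / (nC * uptake),
               pct_dha_of_tfa = 100 * dha_total / tfa_total,
               status = "optimal", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("dha_scan", class(res))
  attr(res, "mu_max") <- g$mu_max
  attr(res, "substrate") <- substrate
  res
}

#' @export
plot.dha_scan <- function(x, ...) {
  graphics::barplot(
    rbind(x$pct_carbon_to_dha, x$pct_dha_of_tfa),
    beside = TRUE,
    names.arg = paste0(100 * x$fraction, "%"),
    legend.text = c("% substrate carbon to DHA", "% DHA of TFA"),
    xlab = "biomass production intensity (fraction of mu_max)",
    ylab = "percent", ...)
  invisible(x)
}

#' Write an FBA solution as delimited text plus JSON summary
#'
#' @param solution an `fba_solution`.
#' @param stem output path prefix (writes `<stem>.tsv`, `<stem>.json`).
#' @return invisibly, the file paths.
#' @export
write_fba_solution <- function(solution, stem) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  if (!is.null(solution$fluxes))
    write_flux_tsv(solution$fluxes, tsv)
  jsonlite::write_json(list(status = solution$status,
                            objective = solution$objective_value),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
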