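# Pathway-scale network: substrate uptake routes (glucose, glycerol,
# ethanol), glycolysis, the Krebs cycle and the cytosolic Acetyl-CoA
# (DHA precursor) supply via ATP-citrate lyase, in three compartments.
#
# Conventions:
#  * metabolite ids carry a compartment suffix (_e, _c, _m);
#  * Acetyl-CoA counts 2 carbons (the acetyl group) and free CoA 0, so the
#    carrier moiety never enters the carbon accounting;
#  * CO2 and free CoA are fixed (boundary) species, which keeps every
#    decarboxylation and CoA-transfer reaction carbon-balanced;
#  * no energy or redox cofactors are represented at this scale.

.kin_metabolites <- function() {
  m <- function(id, name, comp, formula, nc, boundary = FALSE)
    data.frame(id = id, name = name, compartment = comp,
               formula = formula, n_carbon = nc, boundary = boundary,
               stringsAsFactors = FALSE)
  rbind(
    m("glucose_e",    "external glucose",          "e", "C6H12O6",    6L, TRUE),
    m("glycerol_e",   "external glycerol",         "e", "C3H8O3",     3L, TRUE),
    m("ethanol_e",    "external ethanol",          "e", "C2H6O",      2L, TRUE),
    m("accoa_sink_e", "Acetyl-CoA sink (acetyl units to lipid synthesis)",
                                                   "e", NA,           2L, TRUE),
    m("glucose_c",    "glucose",                   "c", "C6H12O6",    6L),
    m("g6p_c",        "glucose 6-phosphate",       "c", "C6H13O9P",   6L),
    m("f6p_c",        "fructose 6-phosphate",      "c", "C6H13O9P",   6L),
    m("fdp_c",        "fructose 1,6-bisphosphate", "c", "C6H14O12P2", 6L),
    m("dhap_c",       "dihydroxyacetone phosphate","c", "C3H7O6P",    3L),
    m("gra3p_c",      "glyceraldehyde 3-phosphate","c", "C3H7O6P",    3L),
    m("bpg_c",        "glycerate 1,3-bisphosphate","c", "C3H8O10P2",  3L),
    m("gri3p_c",      "glycerate 3-phosphate",     "c", "C3H7O7P",    3L),
    m("gri2p_c",      "glycerate 2-phosphate",     "c", "C3H7O7P",    3L),
    m("pep_c",        "phosphoenolpyruvate",       "c", "C3H5O6P",    3L),
    m("pyr_c",        "pyruvate",                  "c", "C3H4O3",     3L),
    m("glycerol_c",   "glycerol",                  "c", "C3H8O3",     3L),
    m("glyc3p_c",     "glycerol 3-phosphate",      "c", "C3H9O6P",    3L),
    m("ethanol_c",    "ethanol",                   "c", "C2H6O",      2L),
    m("acald_c",      "acetaldehyde",              "c", "C2H4O",      2L),
    m("ac_c",         "acetate",                   "c", "C2H4O2",     2L),
    m("accoa_c",      "Acetyl-CoA (cytosolic)",    "c", NA,           2L),
    m("coa_c",        "coenzyme A (cytosolic)",    "c", NA,           0L, TRUE),
    m("cit_c",        "citrate (cytosolic)",       "c", "C6H8O7",     6L),
    m("oaa_c",        "oxaloacetate (cytosolic)",  "c", "C4H4O5",     4L),
    m("pyr_m",        "pyruvate (mitochondrial)",  "m", "C3H4O3",     3L),
    m("accoa_m",      "Acetyl-CoA (mitochondrial)","m", NA,           2L),
    m("coa_m",        "coenzyme A (mitochondrial)","m", NA,           0L, TRUE),
    m("oaa_m",        "oxaloacetate",              "m", "C4H4O5",     4L),
    m("cit_m",        "citrate",                   "m", "C6H8O7",     6L),
    m("icit_m",       "isocitrate",                "m", "C6H8O7",     6L),
    m("akg_m",        "2-oxoglutarate",            "m", "C5H6O5",     5L),
    m("succoa_m",     "succinyl-CoA",              "m", NA,           4L),
    m("succ_m",       "succinate",                 "m", "C4H6O4",     4L),
    m("fum_m",        "fumarate",                  "m", "C4H4O4",     4L),
    m("mal_m",        "malate",                    "m", "C4H6O5",     4L),
    m("co2_m",        "carbon dioxide",            "m", "CO2",        1L, TRUE)
  )
}

.kin_reactions <- function() {
  r <- function(id, name, eq, transport = FALSE, ec = NA_character_) {
    p <- parse_equation(eq)
    list(row = data.frame(id = id, name = name, reversible = p$reversible,
                          lb = if (p$reversible) -1000 else 0, ub = 1000,
                          transport = transport, ec = ec,
                          stringsAsFactors = FALSE),
         stoich = p$stoichiometry)
  }
  defs <- list(
    r("glct",    "glucose uptake",  "glucose_e -> glucose_c",  TRUE),
    r("glyct",   "glycerol uptake", "glycerol_e -> glycerol_c", TRUE),
    r("etoht",   "ethanol uptake",  "ethanol_e -> ethanol_c",  TRUE),
    r("hk",      "hexokinase",                 "glucose_c -> g6p_c", ec = "2.7.1.1"),
    r("pgi",     "phosphoglucose isomerase",   "g6p_c <=> f6p_c",    ec = "5.3.1.9"),
    r("pfk",     "phosphofructokinase",        "f6p_c -> fdp_c",     ec = "2.7.1.11"),
    r("ald",     "fructose-bisphosphate aldolase", "fdp_c <=> dhap_c + gra3p_c", ec = "4.1.2.13"),
    r("tpi",     "triosephosphate isomerase",  "dhap_c <=> gra3p_c", ec = "5.3.1.1"),
    r("gra3pdh", "glyceraldehyde-3-phosphate dehydrogenase", "gra3p_c <=> bpg_c", ec = "1.2.1.12"),
    r("pgk",     "3-phosphoglycerate kinase",  "bpg_c <=> gri3p_c",  ec = "2.7.2.3"),
    r("pgm",     "phosphoglycerate mutase",    "gri3p_c <=> gri2p_c", ec = "5.4.2.11"),
    r("eno",     "enolase",                    "gri2p_c <=> pep_c",  ec = "4.2.1.11"),
    r("pyk",     "pyruvate kinase",            "pep_c -> pyr_c",     ec = "2.7.1.40"),
    r("glyk",    "glycerol kinase",            "glycerol_c -> glyc3p_c", ec = "2.7.1.30"),
    r("g3pd",    "glycerol-3-phosphate dehydrogenase", "glyc3p_c <=> dhap_c", ec = "1.1.1.8"),
    r("adh",     "alcohol dehydrogenase",      "ethanol_c <=> acald_c", ec = "1.1.1.1"),
    r("aldh",    "acetaldehyde dehydrogenase", "acald_c -> ac_c",    ec = "1.2.1.3"),
    r("acalig",  "acetate-CoA ligase",         "ac_c + coa_c -> accoa_c", ec = "6.2.1.1"),
    r("pyrt",    "pyruvate transport (cytosol to mitochondria)", "pyr_c -> pyr_m", TRUE),
    r("pdh",     "pyruvate dehydrogenase",     "pyr_m + coa_m -> accoa_m + co2_m", ec = "1.2.4.1"),
    r("pyc",     "pyruvate carboxylase",       "pyr_m + co2_m -> oaa_m", ec = "6.4.1.1"),
    r("cs",      "citrate synthase",           "accoa_m + oaa_m -> cit_m + coa_m", ec = "2.3.3.1"),
    r("aco",     "aconitate hydratase",        "cit_m <=> icit_m",   ec = "4.2.1.3"),
    r("ide",     "isocitrate dehydrogenase",   "icit_m -> akg_m + co2_m", ec = "1.1.1.41"),
    r("ogdh",    "2-oxoglutarate dehydrogenase", "akg_m + coa_m -> succoa_m + co2_m", ec = "1.2.4.2"),
    r("ss",      "succinyl-CoA synthetase",    "succoa_m <=> succ_m + coa_m", ec = "6.2.1.5"),
    r("sde",     "succinate dehydrogenase",    "succ_m <=> fum_m",   ec = "1.3.5.1"),
    r("fuh",     "fumarate hydratase",         "fum_m <=> mal_m",    ec = "4.2.1.2"),
    r("mde",     "malate dehydrogenase",       "mal_m <=> oaa_m",    ec = "1.1.1.37"),
    r("me",      "malic enzyme",               "mal_m -> pyr_m + co2_m", ec = "1.1.1.40"),
    r("citt",    "citrate shuttle (mitochondria to cytosol)", "cit_m -> cit_c", TRUE),
    r("acl",     "ATP-dependent citrate lyase", "cit_c + coa_c -> accoa_c + oaa_c", ec = "2.3.3.8"),
    r("oaat",    "oxaloacetate shuttle (cytosol to mitochondria)", "oaa_c -> oaa_m", TRUE),
    r("accoat",  "Acetyl-CoA shuttle (cytosol to mitochondria)", "accoa_c -> accoa_m", TRUE),
    r("accoa_sink", "Acetyl-CoA sink towards fatty-acid synthesis",
      "accoa_c -> accoa_sink_e + coa_c", TRUE)
  )
  rows <- do.call(rbind, lapply(defs, `[[`, "row"))
  sto  <- lapply(defs, `[[`, "stoich")
  names(sto) <- rows$id
  list(reactions = rows, stoichiometry = sto)
}

#' Build the pathway-scale kinetic network
#'
#' Constructs the fixed 35-reaction, 36-metabolite network connecting
#' glucose, glycerol and ethanol uptake with glycolysis, the Krebs cycle
#' and cytosolic Acetyl-CoA production (ATP-citrate lyase), organised into
#' extracellular, cytosolic and mitochondrial compartments (mitochondrial
#' volume 1% of the cytosol).  The pentose phosphate pathway, glutamate
#' dehydrogenase and all energy/redox cofactor moieties are deliberately
#' absent at this scale.
#'
#' @return a `metabolic_network` with 35 reactions, 36 metabolites and 3
#'   compartments.
#' @export
build_kinetic_network <- function() {
  cmp <- data.frame(
    id = c("e", "c", "m"),
    name = c("extracellular", "cytosol", "mitochondria"),
    relative_volume = c(1, 1, 0.01),
    stringsAsFactors = FALSE
  )
  rx <- .kin_reactions()
  metabolic_network(cmp, .kin_metabolites(), rx$reactions, rx$stoichiometry)
}
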