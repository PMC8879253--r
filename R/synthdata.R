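# Synthetic-data generators: batch growth curves emulating the
# cultivation experiments, noisy flux datasets for parameter-recovery
# studies, and reference (growth-consistent) flux datasets derived from
# the stoichiometric model.  Every generator is deterministic under a
# fixed seed and carries its ground truth as an attribute.

#' Specification of a synthetic batch culture
#'
#' The generated curve follows the structure the rate estimators assume:
#' exponential growth at `mu_true` with substrate consumption
#' proportional to integrated biomass at `q_s_true`, a hard stop at
#' substrate exhaustion, and multiplicative lognormal measurement noise.
#'
#' @param mu_true specific growth rate, h-1 (observed range 0.017-0.051).
#' @param q_s_true biomass-specific uptake, mmol gDW-1 h-1.
#' @param x0 inoculum biomass, g/L.
#' @param s0 initial substrate, g/L.
#' @param t_end duration, h.
#' @param n_points number of samples.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 to 0.2).
#' @param seed integer RNG seed.
#' @param substrate substrate name (sets the molar mass).
#' @return object of class `curve_spec`.
#' @export
curve_spec <- function(mu_true, q_s_true, x0 = 0.3, s0 = 10, t_end = 120,
                       n_points = 15, noise_cv = 0, seed = 1,
                       substrate = "glycerol") {
  stopifnot(mu_true > 0, q_s_true > 0, x0 > 0, s0 > 0, t_end > 0,
            n_points >= 3, noise_cv >= 0, noise_cv <= 0.2)
  structure(list(mu_true = mu_true, q_s_true = q_s_true, x0 = x0, s0 = s0,
                 t_end = t_end, n_points = n_points, noise_cv = noise_cv,
                 seed = seed, substrate = substrate),
            class = "curve_spec")
}

#' Generate a synthetic batch growth curve
#'
#' @param spec a [curve_spec()].
#' @return a [growth_curve()] whose attribute `"truth"` records the
#'   generating parameters.
#' @export
gen_batch_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  M <- .molar_mass[[spec$substrate]]
  if (is.null(M)) stop("no molar mass for substrate ", spec$substrate)
  if (spec$s0 <= 0) stop("initial substrate must be positive")
  tt <- seq(0, spec$t_end, length.out = spec$n_points)
  mu <- spec$mu_true; qs <- spec$q_s_true
  # exhaustion time: s0 = qs*M/1000 * x0 (e^(mu t) - 1)/mu
  texh <- log(1 + mu * spec$s0 * 1000 / (qs * M * spec$x0)) / mu
  X <- ifelse(tt <= texh, spec$x0 * exp(mu * tt),
              spec$x0 * exp(mu * texh))
  xint <- ifelse(tt <= texh, spec$x0 * (exp(mu * tt) - 1) / mu,
                 spec$s0 * 1000 / (qs * M))
  S <- pmax(spec$s0 - qs * M / 1000 * xint, 0)
  if (spec$noise_cv > 0) {
    set.seed(spec$seed)
    sdl <- sqrt(log(1 + spec$noise_cv^2))
    noise <- function(n) exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    X <- X * noise(length(X))
    S <- S * noise(length(S))
  }
  cur <- growth_curve(tt, X,
                      stats::setNames(data.frame(S), spec$substrate))
  attr(cur, "truth") <- spec
  cur
}

#' Generate a noisy flux dataset from a kinetic model
#'
#' Solves the model's steady state under the given scenario, keeps the
#' non-zero fluxes, and perturbs them multiplicatively (seeded lognormal).
#' The unperturbed fluxes satisfy the kinetic network's node balances by
#' construction.
#'
#' @param model a `kinetic_model`.
#' @param substrate scenario substrate.
#' @param uptake_rate scenario uptake, mmol min-1 L-1.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed integer seed.
#' @return a [flux_dataset()] with attribute `"truth"` (the exact fluxes).
#' @export
gen_flux_dataset <- function(model, substrate, uptake_rate, noise_cv = 0,
                             seed = 1) {
  m <- configure_scenario(model, substrate, uptake_rate)
  ss <- find_steady_state(m, tol = 1e-6, quiet = TRUE)
  if (!ss$converged) stop("model does not reach a steady state")
  v <- ss$fluxes[abs(ss$fluxes) > 1e-6]
  targ <- v
  if (noise_cv > 0) {
    set.seed(seed)
    sdl <- sqrt(log(1 + noise_cv^2))
    targ <- v * exp(stats::rnorm(length(v), -sdl^2 / 2, sdl))
  }
  w <- rep(1, length(targ))
  w[names(targ) == .uptake_reaction[[substrate]]] <- 10
  ds <- flux_dataset(paste0("synthetic_", substrate),
                     data.frame(reaction = names(targ),
                                target = unname(targ), weight = w,
                                provenance = "synthetic",
                                stringsAsFactors = FALSE),
                     substrate, uptake_rate)
  attr(ds, "truth") <- v
  ds
}

#' Derive a growth-consistent reference flux dataset
#'
#' Construction of the packaged per-substrate flux datasets: the
#' stoichiometric model is solved with the substrate uptake and the
#' observed growth rate fixed and the printed anchor fluxes (lower-Krebs
#' segment and ATP-citrate lyase) imposed, the flux distribution is
#' canonicalised parsimoniously, and the kinetic-subnetwork fluxes are
#' converted to volumetric units.  The result is a flux table whose
#' biosynthetic branch draws are consistent with growth at the observed
#' rate - the role the 13C dataset plays for glucose.
#'
#' @param stoich a `stoich_model`.
#' @param substrate substrate name.
#' @param uptake_gdw uptake, mmol gDW-1 h-1.
#' @param mu observed growth rate, h-1.
#' @param anchors named vector of anchor fluxes in volumetric units
#'   (e.g. `c(ogdh = 2.43, acl = 3.87)`).
#' @param anchor_weight fitting weight given to measured anchors.
#' @param label dataset label.
#' @return a [flux_dataset()] in volumetric units.
#' @export
derive_reference_flux_dataset <- function(stoich, substrate, uptake_gdw,
                                          mu, anchors, anchor_weight = 10,
                                          label = paste0(substrate, "_ref"),
                                          classical_caps = (substrate == "glucose")) {
  fb <- .growth_bounds(stoich, substrate, uptake_gdw)
  # the observed uptake is a measurement: pin the exchange exactly
  fb[[stoich$substrate_exchange[[substrate]]]] <- c(-uptake_gdw, -uptake_gdw)
  fb[[stoich$biomass_reaction]] <- c(mu, mu)
  for (id in names(anchors)) {
    a <- convert_flux_set(anchors[[id]], "vol_to_gdw")
    fb[[id]] <- c(a * 0.999, a * 1.001)
  }
  # for the 13C-anchored glucose dataset, keep the derivation on the
  # classical EMP/PDH-dominant distribution that study describes: the
  # alternative acetyl routes and the oxidative PPP are capped at small
  # shares of the uptake (no flux data constrains these routes for the
  # other substrates, so their derivations leave them free)
  if (classical_caps) {
    fb[["pk_f6p"]] <- c(0, 0.05 * uptake_gdw)
    fb[["pk_x5p"]] <- c(0, 0.05 * uptake_gdw)
    fb[["pno"]]    <- c(0, 0)
    fb[["g6pd"]]   <- c(0, 0.1 * uptake_gdw)
    fb[["gapn"]]   <- c(0, 0.05 * uptake_gdw)
  }
  # biomass is pinned by its bounds; the parsimonious (minimal total
  # flux) solution at that growth rate is the canonical reference - the
  # anchored excess Acetyl-CoA drains to the DHA sink structurally
  sol <- solve_fba(stoich, stoich$biomass_reaction, fixed_bounds = fb,
                   canonical = TRUE)
  if (sol$status != "optimal")
    stop("reference solution infeasible for ", substrate,
         " at mu = ", mu)
  kin_ids <- build_kinetic_network()$reactions$id
  v <- convert_flux_set(sol$fluxes[kin_ids], "gdw_to_vol")
  v <- round(v[abs(v) > 5e-4], 4)
  # redundant lower-Krebs duplicates carry no independent information,
  # and the anaplerotic pair is structurally tied (pyc = me) in the
  # closed kinetic topology, so reference values must not pull it
  dup <- c("ss", "sde", "fuh", "aco", "ide", "mde", "accoat", "oaat",
           "pyc", "me")
  w <- rep(1, length(v))
  names(w) <- names(v)
  w[names(v) %in% dup] <- 0
  up <- .uptake_reaction[[substrate]]
  w[names(v) %in% c(up, names(anchors))] <- anchor_weight
  w[names(v) %in% setdiff(names(anchors), c("ogdh", up, "acl"))] <- 1
  prov <- ifelse(names(v) %in% c(up, names(anchors)), "measured", "synthetic")
  flux_dataset(label,
               data.frame(reaction = names(v), target = unname(v),
                          weight = unname(w), provenance = prov,
                          stringsAsFactors = FALSE),
               substrate, convert_flux_set(uptake_gdw, "gdw_to_vol"))
}

#' Write synthetic pipeline inputs to a directory
#'
#' Emits the batch curves (CSV) and flux datasets (TSV) the analysis
#' chain consumes, each with a JSON sidecar recording the generating
#' ground truth.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return (invisibly) the written file paths.
#' @export
write_synthetic_inputs <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  specs <- list(
    glucose  = curve_spec(0.051, 0.65, s0 = 9, substrate = "glucose",
                          noise_cv = 0.03, seed = seed),
    glycerol = curve_spec(0.023, 0.44, s0 = 12, t_end = 200,
                          substrate = "glycerol", noise_cv = 0.03,
                          seed = seed + 1),
    ethanol  = curve_spec(0.046, 1.41, s0 = 3, substrate = "ethanol",
                          noise_cv = 0.03, seed = seed + 2)
  )
  for (s in names(specs)) {
    cur <- gen_batch_curve(specs[[s]])
    p <- file.path(dir, paste0("curve_", s, ".csv"))
    write_growth_curve(cur, p)
    sidecar <- file.path(dir, paste0("curve_", s, "_truth.json"))
    jsonlite::write_json(unclass(specs[[s]]), sidecar, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p, sidecar)
  }
  for (f in c("flux_glucose.tsv", "flux_glycerol.tsv", "flux_ethanol.tsv")) {
    src <- system.file("extdata", f, package = "dhaflux")
    if (nzchar(src)) {
      file.copy(src, file.path(dir, f), overwrite = TRUE)
      paths <- c(paths, file.path(dir, f))
    }
  }
  invisible(paths)
}
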