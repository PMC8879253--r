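#' Substrate scenarios for the kinetic model
#'
#' A scenario selects the active substrate, its concentration-independent
#' uptake rate, and the pyruvate dehydrogenase capacity: the glucose /
#' glycerol parameterisation runs with a PDH Vmax of 907 mmol min-1 L-1,
#' while the ethanol parameterisation requires PDH to be shut off
#' (Vmax 1e-6), redirecting mitochondrial pyruvate to oxaloacetate.
#'
#' @param substrate one of `"glucose"`, `"glycerol"`, `"ethanol"`.
#' @param uptake_rate substrate uptake, mmol min-1 L-1, >= 0.
#' @param pdh_vmax PDH maximal rate (mmol min-1 L-1); defaults to 907 for
#'   glucose/glycerol and 1e-6 for ethanol.
#' @return an object of class `substrate_scenario`.
#' @export
substrate_scenario <- function(substrate = c("glucose", "glycerol", "ethanol"),
                               uptake_rate, pdh_vmax = NULL) {
  substrate <- match.arg(substrate)
  stopifnot(uptake_rate >= 0)
  if (is.null(pdh_vmax))
    pdh_vmax <- if (substrate == "ethanol") 1e-6 else 907
  stopifnot(pdh_vmax >= 0)
  structure(list(substrate = substrate, uptake_rate = uptake_rate,
                 pdh_vmax = pdh_vmax), class = "substrate_scenario")
}

# reactions whose Vm is the substrate uptake rate
.uptake_reaction <- c(glucose = "glct", glycerol = "glyct", ethanol = "etoht")

# order-of-magnitude EFFECTIVE equilibrium constants (dimensionless, or
# mM for the aldolase cleavage).  Because the model lumps energy and
# redox cofactors away, each constant absorbs the in-vivo cofactor ratios
# (e.g. NAD+/NADH ~ 7e2, ATP/ADP ~ 10) on top of the standard transformed
# reaction energy; direction conventions follow the network's equations
.keq_defaults <- c(
  pgi = 0.3,       # g6p -> f6p slightly unfavourable
  ald = 0.1,       # fdp cleavage, ~1e-4 M in mM units
  tpi = 0.05,      # gra3p/dhap ~ 1/20
  gra3pdh = 40,    # unfavourable alone, driven by the NAD+/NADH ratio
  pgk = 100,       # forward with the phosphoryl transfer to ADP
  pgm = 0.15,
  eno = 5,
  g3pd = 10,       # driven by the flavin/NAD redox pool
  adh = 0.05,      # acetaldehyde formation, NAD+/NADH-driven
  aco = 0.07,      # icit/cit ~ 1/15
  ss = 2, sde = 1, fuh = 4,
  mde = 5e-3       # mal -> oaa unfavourable even with NAD+ excess
)

# Km overrides (mmol/L) where the uniform default would misplace a pool by
# orders of magnitude relative to the thermodynamically forced level
.km_overrides <- list(
  cs   = c(oaa_m = 5e-4),
  aldh = c(acald_c = 0.01),
  ide  = c(icit_m = 0.03)
)

#' Default rate laws for the kinetic network
#'
#' Uniform parameterisation: constant flux for the three uptake reactions
#' (concentration-independent uptake), irreversible Michaelis-Menten for
#' irreversible enzymatic steps and internal transports, and reversible
#' Michaelis-Menten with a Haldane constraint for reversible reactions.
#' Km defaults to 0.5 mmol/L (with a few physiologically scaled
#' exceptions) and equilibrium constants follow order-of-magnitude
#' standard thermodynamics; steady-state fluxes, the fitted observable,
#' are set by the Vm scaling factors.
#'
#' @param network the kinetic `metabolic_network`.
#' @param Vm default maximal-rate scaling (mmol min-1 L-1).
#' @param Km default Michaelis constant (mmol L-1).
#' @param Keq default equilibrium constant for reversible laws without a
#'   thermodynamic entry.
#' @return named list of [rate_law()] objects, one per reaction.
#' @export
default_rate_laws <- function(network, Vm = 50, Km = 0.5, Keq = 10) {
  laws <- list()
  boundary <- network$metabolites$id[network$metabolites$boundary]
  for (i in seq_len(nrow(network$reactions))) {
    id <- network$reactions$id[i]
    s <- network$stoichiometry[[id]]
    subs <- -s[s < 0]
    prods <- s[s > 0]
    # fixed carrier/boundary co-factors do not modulate the rate
    subs  <- subs[setdiff(names(subs), c("coa_c", "coa_m", "co2_m"))]
    prods <- prods[setdiff(names(prods), c("coa_c", "coa_m", "co2_m", "accoa_sink_e"))]
    km_for <- function(ids) {
      km <- stats::setNames(rep(Km, length(ids)), ids)
      ov <- .km_overrides[[id]]
      if (!is.null(ov)) km[intersect(names(ov), ids)] <-
          ov[intersect(names(ov), ids)]
      km
    }
    if (id %in% .uptake_reaction) {
      laws[[id]] <- rate_law("constant_flux", Vm = 0)
    } else if (network$reactions$reversible[i]) {
      keq <- if (id %in% names(.keq_defaults)) .keq_defaults[[id]] else Keq
      laws[[id]] <- rate_law("reversible_mm_haldane", Vm = Vm,
                             Km = km_for(c(names(subs), names(prods))),
                             Keq = keq, substrates = subs, products = prods)
    } else {
      laws[[id]] <- rate_law("irreversible_mm", Vm = Vm,
                             Km = km_for(names(subs)),
                             substrates = subs, products = prods)
    }
  }
  # anaplerosis must outrun the malic-enzyme drain for the oxaloacetate
  # pool to build up against PDH's large capacity, and citrate synthase
  # needs capacity headroom because the thermodynamically forced
  # oxaloacetate level sits near its (micromolar) Km; these defaults keep
  # the wild-type parameterisation convergent on every substrate (all are
  # ordinary fit targets thereafter)
  laws[["pyc"]]$Vm <- 2 * Vm
  laws[["me"]]$Vm  <- Vm / 25
  laws[["cs"]]$Vm  <- 8 * Vm
  # a strong triose-phosphate oxidation pull keeps gra3p (and with it the
  # thermodynamically coupled dhap and fdp pools) at physiological levels
  laws[["gra3pdh"]]$Vm <- 10 * Vm
  laws
}

#' Construct a pathway-scale kinetic model
#'
#' @param network kinetic-scope `metabolic_network`; defaults to
#'   [build_kinetic_network()].
#' @param rate_laws named list of [rate_law()] per reaction; defaults to
#'   [default_rate_laws()].
#' @param boundary_concentrations named vector of fixed concentrations for
#'   boundary species (mmol L-1).
#' @param scenario optional [substrate_scenario()].
#' @return an object of class `kinetic_model`.
#' @export
kinetic_model <- function(network = build_kinetic_network(),
                          rate_laws = default_rate_laws(network),
                          boundary_concentrations = NULL,
                          scenario = NULL) {
  missing_laws <- setdiff(network$reactions$id, names(rate_laws))
  if (length(missing_laws))
    stop("missing rate law for reaction(s): ",
         paste(missing_laws, collapse = ", "))
  bnd <- network$metabolites$id[network$metabolites$boundary]
  bc <- stats::setNames(rep(1, length(bnd)), bnd)
  bc[intersect(c("glucose_e", "glycerol_e", "ethanol_e"), bnd)] <- 10
  if ("accoa_sink_e" %in% bnd) bc["accoa_sink_e"] <- 0
  if (!is.null(boundary_concentrations))
    bc[names(boundary_concentrations)] <- boundary_concentrations
  vols <- stats::setNames(network$compartments$relative_volume,
                          network$compartments$id)
  m <- structure(list(network = network, rate_laws = rate_laws,
                      volumes = vols, boundary_concentrations = bc,
                      scenario = scenario),
                 class = "kinetic_model")
  m
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Pathway-scale kinetic model:", nrow(x$network$reactions), "reactions,",
      nrow(x$network$metabolites), "metabolites\n")
  if (!is.null(x$scenario))
    cat("  scenario:", x$scenario$substrate, "uptake",
        x$scenario$uptake_rate, "mmol/min/L, PDH Vmax",
        x$scenario$pdh_vmax, "\n")
  invisible(x)
}

#' Configure a substrate scenario on a kinetic model
#'
#' Sets the active substrate's uptake to `uptake_rate` (constant flux),
#' zeroes the other uptakes, and selects the PDH capacity (907 mmol
#' min-1 L-1 for glucose/glycerol, 1e-6 for ethanol, unless overridden).
#'
#' @param model a `kinetic_model`.
#' @param substrate `"glucose"`, `"glycerol"` or `"ethanol"`.
#' @param uptake_rate uptake, mmol min-1 L-1.
#' @param pdh_vmax optional explicit PDH Vmax override.
#' @return the reconfigured `kinetic_model`.
#' @export
configure_scenario <- function(model, substrate, uptake_rate, pdh_vmax = NULL) {
  sc <- substrate_scenario(substrate, uptake_rate, pdh_vmax)
  for (s in names(.uptake_reaction))
    model$rate_laws[[.uptake_reaction[[s]]]]$Vm <-
      if (s == sc$substrate) sc$uptake_rate else 0
  model$rate_laws[["pdh"]]$Vm <- sc$pdh_vmax
  model$scenario <- sc
  model
}

# Precompile the model into generated straight-line code: one arithmetic
# expression per reaction with Km/Keq constants inlined and the Vm*k_over
# vector passed as a parameter (so fitting candidates re-use the compiled
# evaluator and only swap the vmax vector).
.compile_kinetics <- function(model) {
  net <- model$network
  met_ids <- net$metabolites$id
  internal <- which(!net$metabolites$boundary)
  rxn_ids <- net$reactions$id
  laws <- model$rate_laws
  g <- function(x) sprintf("%.17g", x)
  exprs <- character(length(rxn_ids))
  vmax <- numeric(length(rxn_ids))
  for (j in seq_along(rxn_ids)) {
    law <- laws[[rxn_ids[j]]]
    if (is.null(law)) stop("missing rate law for reaction: ", rxn_ids[j])
    vmax[j] <- law$Vm * law$k_over
    si <- match(names(law$substrates), met_ids)
    pj <- match(names(law$products), met_ids)
    kms <- unname(law$Km[names(law$substrates)])
    kmp <- unname(law$Km[names(law$products)])
    sc <- unname(law$substrates); pc <- unname(law$products)
    cref <- function(i) sprintf("conc[%dL]", i)
    exprs[j] <- switch(
      law$form,
      constant_flux = sprintf("vmax[%dL]", j),
      irreversible_mm = {
        terms <- mapply(function(i, km)
          sprintf("%s/(%s+%s)", cref(i), g(km), cref(i)), si, kms)
        sprintf("vmax[%dL]*%s", j, paste(terms, collapse = "*"))
      },
      mass_action = {
        terms <- mapply(function(i, cc)
          if (cc == 1) cref(i) else sprintf("%s^%s", cref(i), g(cc)), si, sc)
        sprintf("vmax[%dL]*%s", j, paste(terms, collapse = "*"))
      },
      reversible_mm_haldane = {
        fwd <- paste(mapply(function(i, km)
          sprintf("%s*%s", cref(i), g(1 / km)), si, kms), collapse = "*")
        rev_num <- paste(mapply(function(i, cc)
          if (cc == 1) cref(i) else sprintf("%s^%s", cref(i), g(cc)),
          pj, pc), collapse = "*")
        rev <- sprintf("%s*%s", rev_num, g(1 / (prod(kms) * law$Keq)))
        ds <- paste(mapply(function(i, km)
          sprintf("(1+%s*%s)", cref(i), g(1 / km)), si, kms), collapse = "*")
        dp <- paste(mapply(function(i, km)
          sprintf("(1+%s*%s)", cref(i), g(1 / km)), pj, kmp), collapse = "*")
        sprintf("vmax[%dL]*(%s-%s)/(%s+%s-1)", j, fwd, rev, ds, dp)
      })
  }
  body_txt <- paste0("c(", paste(exprs, collapse = ",\n"), ")")
  flux_fn <- eval(parse(text = paste0("function(conc, vmax) ", body_txt)),
                  envir = baseenv())
  S <- stoich_matrix(net)
  vol_met <- model$volumes[net$metabolites$compartment]
  base <- stats::setNames(rep(0, length(met_ids)), met_ids)
  bnd <- names(model$boundary_concentrations)
  base[bnd] <- model$boundary_concentrations
  list(flux_fn = flux_fn, vmax = vmax,
       S = S, S_int = S[internal, , drop = FALSE],
       vol_int = as.numeric(vol_met[internal]),
       internal = internal, met_ids = met_ids, rxn_ids = rxn_ids,
       base = base)
}

.eval_fluxes <- function(ck, conc) ck$flux_fn(unname(conc), ck$vmax)

#' Build the ODE right-hand side for a kinetic model
#'
#' For each internal metabolite i in a compartment of relative volume V:
#' dCi/dt = (1/V) * sum_j s_ij v_j, with fluxes expressed per
#' cytosol-equivalent litre so that amounts (not concentrations) are
#' conserved across compartments.  Boundary species are held fixed.
#'
#' @param model a `kinetic_model`.
#' @return a function `(t, y, parms)` in the form deSolve expects, with
#'   attributes `state_names` (internal metabolite ids) and `flux_fn`
#'   (function of a full named concentration vector returning all fluxes).
#' @export
build_ode_system <- function(model) {
  ck <- .compile_kinetics(model)
  # The state is allowed to take tiny negative excursions (solver noise):
  # Michaelis-Menten terms are smooth there and self-correcting, whereas a
  # hard clamp at zero makes the RHS non-smooth and breaks stiff solvers.
  rhs <- function(t, y, parms) {
    conc <- ck$base
    conc[ck$internal] <- y
    v <- .eval_fluxes(ck, conc)
    list(as.numeric(ck$S_int %*% v) / ck$vol_int)
  }
  attr(rhs, "state_names") <- ck$met_ids[ck$internal]
  attr(rhs, "flux_fn") <- function(conc_full) {
    v <- .eval_fluxes(ck, conc_full)
    stats::setNames(v, ck$rxn_ids)
  }
  attr(rhs, "compiled") <- ck
  rhs
}

.initial_state <- function(ck, initial_concentrations, default = 0.1,
                           scenario = NULL) {
  y0 <- stats::setNames(rep(default, length(ck$internal)),
                        ck$met_ids[ck$internal])
  # branches that cannot carry flux under the active substrate start
  # empty: their pools are dead ends (or, for ethanol, would flush into
  # the conserved C4 backbone of the citrate loop and inflate the
  # 100x-amplified mitochondrial concentrations)
  if (!is.null(scenario)) {
    zero <- character(0)
    if (scenario$substrate != "glucose")
      zero <- c(zero, "glucose_c", "g6p_c", "f6p_c", "fdp_c")
    if (scenario$substrate != "glycerol")
      zero <- c(zero, "glycerol_c", "glyc3p_c")
    if (scenario$substrate != "ethanol")
      zero <- c(zero, "ethanol_c", "acald_c", "ac_c")
    if (scenario$substrate == "ethanol")
      zero <- c(zero, "dhap_c", "gra3p_c", "bpg_c", "gri3p_c", "gri2p_c",
                "pep_c", "pyr_c")
    y0[intersect(zero, names(y0))] <- 0
  }
  if (!is.null(initial_concentrations)) {
    keep <- intersect(names(initial_concentrations), names(y0))
    y0[keep] <- initial_concentrations[keep]
  }
  y0
}

#' Simulate a kinetic model trajectory
#'
#' Integrates the compartmental ODE system with `deSolve::lsoda`.
#' Concentrations are kept non-negative (the right-hand side clamps at
#' zero, and tight tolerances keep excursions below solver noise).
#'
#' @param model a `kinetic_model` (scenario configured).
#' @param initial_concentrations optional named vector for internal
#'   species; unspecified species start at 0.1 mmol/L.
#' @param t_end simulation horizon, minutes (> 0).
#' @param n_points number of output rows.
#' @return object of class `kinetic_trajectory`: list with `time`,
#'   `concentrations` (matrix, time x species) and `fluxes` (matrix,
#'   time x reactions).
#' @export
simulate_kinetic <- function(model, initial_concentrations = NULL,
                             t_end = 1000, n_points = 101) {
  stopifnot(t_end > 0)
  rhs <- build_ode_system(model)
  ck <- attr(rhs, "compiled")
  y0 <- .initial_state(ck, initial_concentrations, scenario = model$scenario)
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed for scenario '",
         if (!is.null(model$scenario)) model$scenario$substrate else "?",
         "'; consider smaller t_end or different initial concentrations")
  conc <- pmax(unname(sol[, -1, drop = FALSE]), 0)
  colnames(conc) <- names(y0)
  fluxes <- t(apply(conc, 1, function(row) {
    full <- ck$base; full[ck$internal] <- row
    attr(rhs, "flux_fn")(full)
  }))
  structure(list(time = sol[, 1], concentrations = conc, fluxes = fluxes,
                 model = model),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat("Kinetic trajectory:", length(x$time), "time points over",
      max(x$time), "min;", ncol(x$concentrations), "species\n")
  invisible(x)
}

#' @export
plot.kinetic_trajectory <- function(x, species = NULL, ...) {
  sp <- if (is.null(species)) colnames(x$concentrations) else species
  graphics::matplot(x$time, x$concentrations[, sp, drop = FALSE], type = "l",
                    xlab = "time [min]", ylab = "concentration [mmol/L]", ...)
  graphics::legend("topright", legend = sp, lty = seq_along(sp),
                   col = seq_along(sp), cex = 0.6, bty = "n")
  invisible(x)
}

.newton_polish <- function(f, y0, tol, max_iter = 60, use_lm = TRUE) {
  y <- y0
  fy <- f(y)
  for (it in seq_len(max_iter)) {
    res <- max(abs(fy))
    if (res <= tol) return(list(y = y, residual = res, converged = TRUE))
    n <- length(y)
    J <- matrix(0, n, n)
    # forward differences while far from the root, central once close
    central <- res < 1e-4
    h <- pmax(1e-6 * abs(y), 1e-9)
    for (k in seq_len(n)) {
      yp <- y; yp[k] <- yp[k] + h[k]
      if (central) {
        ym <- y; ym[k] <- ym[k] - h[k]
        J[, k] <- (f(yp) - f(ym)) / (2 * h[k])
      } else {
        J[, k] <- (f(yp) - fy) / h[k]
      }
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(qr.solve(J + diag(1e-12, n), -fy),
                       error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (ls in 1:40) {
      ytry <- pmax(y + lambda * step, 0)
      ftry <- f(ytry)
      if (max(abs(ftry)) < max(abs(fy))) {
        y <- ytry; fy <- ftry; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  # Levenberg-Marquardt fallback for ill-conditioned tails (slow pool
  # modes make the plain Newton direction unreliable near the solution);
  # only worth invoking once the iterate is already close
  if (use_lm && max(abs(fy)) > tol && max(abs(fy)) < 1e-3) {
    lm <- tryCatch(
      minpack.lm::nls.lm(par = y, fn = function(p) f(pmax(p, 0)),
                         lower = rep(0, length(y)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 40, ftol = 0, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(lm)) {
      ylm <- pmax(as.numeric(lm$par), 0)
      flm <- f(ylm)
      if (max(abs(flm)) < max(abs(fy))) { y <- ylm; fy <- flm }
    }
  }
  list(y = y, residual = max(abs(fy)), converged = max(abs(fy)) <= tol)
}

#' Find the steady state of a kinetic model
#'
#' Long-horizon stiff integration (with the horizon extended until the
#' state stops moving) followed by a damped Newton polish on the
#' concentration residuals.  At steady state every internal metabolite's
#' net production is zero, so flux balance holds on the kinetic
#' subnetwork.
#'
#' @param model a `kinetic_model` with a scenario configured.
#' @param initial_concentrations optional named starting concentrations
#'   (a warm start from a previous solution speeds repeated calls).
#' @param tol steady-state tolerance on max |dC/dt| (mmol L-1 min-1).
#' @param max_t integration horizon ceiling, minutes.
#' @return object of class `steady_state`: `concentrations` (all species),
#'   `fluxes` (all reactions, mmol min-1 L-1), `residual`, `converged`.
#' @export
find_steady_state <- function(model, initial_concentrations = NULL,
                              tol = 1e-8, max_t = 1e5, conc_cap = 1e4,
                              quiet = FALSE) {
  rhs <- build_ode_system(model)
  ck <- attr(rhs, "compiled")
  y <- .initial_state(ck, initial_concentrations, scenario = model$scenario)
  f <- function(yy) rhs(0, yy, NULL)[[1]]
  # cheap Newton attempt from the warm start first
  pol <- .newton_polish(f, y, tol, max_iter = 20, use_lm = FALSE)
  if (!pol$converged) {
    t_end <- 200
    repeat {
      sol <- suppressWarnings(
        deSolve::lsoda(y, c(0, t_end / 2, t_end), rhs, parms = NULL,
                       rtol = 1e-8, atol = 1e-10, maxsteps = 20000))
      if (attr(sol, "istate")[1] >= 0) {
        mid <- pmax(sol[min(2, nrow(sol)), -1], 0)
        y <- pmax(sol[nrow(sol), -1], 0)
      } else mid <- y
      # diverging pool (still rising at an already absurd level, or past
      # any physical range): no finite steady state for this candidate
      if (max(y) > 1e6 ||
          (max(y) > conc_cap && max(y) > 1.2 * max(mid))) {
        pol <- list(y = y, residual = max(abs(f(y))), converged = FALSE)
        break
      }
      pol <- .newton_polish(f, y, tol)
      if (pol$converged || t_end >= max_t) break
      t_end <- t_end * 10
    }
  }
  y <- pol$y
  full <- ck$base
  full[ck$internal] <- y
  fluxes <- attr(rhs, "flux_fn")(full)
  out <- structure(list(concentrations = full, fluxes = fluxes,
                        residual = pol$residual, converged = pol$converged,
                        scenario = model$scenario),
                   class = "steady_state")
  if (!pol$converged && !quiet)
    warning("steady state not converged: residual ",
            format(pol$residual), " > tol ", format(tol))
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Kinetic steady state (", if (x$converged) "converged" else "NOT converged",
      "), residual ", format(x$residual, digits = 3), "\n", sep = "")
  key <- intersect(c("glct", "glyct", "etoht", "pdh", "cs", "ogdh", "acl",
                     "accoa_sink"), names(x$fluxes))
  print(round(x$fluxes[key], 4))
  invisible(x)
}

#' Write / read a flux table (reaction id, flux) as delimited text
#'
#' The exchange currency between the kinetic and stoichiometric layers.
#'
#' @param fluxes named numeric vector.
#' @param path file path.
#' @return `read_flux_tsv` returns a named numeric vector.
#' @export
write_flux_tsv <- function(fluxes, path) {
  utils::write.table(data.frame(reaction = names(fluxes), flux = unname(fluxes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
read_flux_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$flux, d$reaction)
}
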