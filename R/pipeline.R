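#' Run the full substrate-comparison analysis chain
#'
#' Orchestrates the stages of the analysis: (1) synthetic batch curves are
#' generated and growth/uptake rates re-estimated from them; (2) the
#' kinetic model is fitted to the packaged flux datasets (glucose and
#' glycerol jointly with one parameter set, ethanol separately with PDH
#' shut off); (3) the fitted steady-state flux sets are validated inside
#' the stoichiometric model at the observed growth rates; (4) the
#' stoichiometric model yields maximal growth rates, optimal
#' carbon-per-biomass ratios and DHA potential scans; (5) everything is
#' assembled into the per-substrate carbon report.
#'
#' @param outdir optional directory; when given, every stage writes its
#'   inputs/outputs there (TSV/CSV/JSON).
#' @param seed integer seed controlling every stochastic stage.
#' @param fit_control an [estimation_config()] (seed is overridden by
#'   `seed`); reduce `de_pop`/`de_gens` for quick runs.
#' @param run_fit set `FALSE` to skip the (minutes-long) kinetic fitting
#'   stage; carbon accounting then uses the dataset anchor values.
#' @return list of class `dha_pipeline` with elements `rates`, `fits`,
#'   `validation`, `stoich`, `report`.
#' @export
run_pipeline <- function(outdir = NULL, seed = 1,
                         fit_control = estimation_config(),
                         run_fit = TRUE) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  save <- function(fn, ...) if (!is.null(outdir)) fn(...)
  msg <- function(...) message("[pipeline] ", ...)
  obs <- data.frame(
    substrate = c("glucose", "glycerol", "ethanol"),
    q_s_gdw_h = c(0.65, 0.44, 1.41),
    mu        = c(0.051, 0.023, 0.046),
    stringsAsFactors = FALSE)

  # -- stage 1: synthetic curves and rate estimation -----------------
  msg("stage 1: batch-curve rate estimation")
  rates <- list()
  for (i in seq_len(nrow(obs))) {
    s <- obs$substrate[i]
    spec <- curve_spec(obs$mu[i], obs$q_s_gdw_h[i],
                       s0 = c(glucose = 9, glycerol = 12, ethanol = 3)[[s]],
                       t_end = if (s == "glycerol") 200 else 120,
                       noise_cv = 0.03, seed = seed + i,
                       substrate = s)
    cur <- gen_batch_curve(spec)
    rates[[s]] <- fit_rates(cur, s)
    save(write_growth_curve, cur, file.path(outdir, paste0("curve_", s, ".csv")))
  }

  # -- stage 2: kinetic model fitting --------------------------------
  fits <- NULL
  if (run_fit) {
    msg("stage 2: kinetic parameter estimation (this takes minutes)")
    fc <- fit_control; fc$seed <- seed
    m <- kinetic_model()
    ds_glc <- read_flux_dataset(system.file("extdata", "flux_glucose.tsv",
                                            package = "dhaflux"))
    ds_gly <- read_flux_dataset(system.file("extdata", "flux_glycerol.tsv",
                                            package = "dhaflux"))
    ds_eth <- read_flux_dataset(system.file("extdata", "flux_ethanol.tsv",
                                            package = "dhaflux"))
    fits <- list(
      glucose_glycerol = fit_parameters(m, list(ds_glc, ds_gly), fc),
      ethanol = fit_parameters(m, ds_eth, fc))
  } else msg("stage 2: kinetic fitting skipped")

  # -- stage 3 + 4: stoichiometric model -----------------------------
  msg("stage 3: flux-set validation in the stoichiometric model")
  sm <- build_stoich_model()
  datasets <- list(
    glucose = read_flux_dataset(system.file("extdata", "flux_glucose.tsv",
                                            package = "dhaflux")),
    glycerol = read_flux_dataset(system.file("extdata", "flux_glycerol.tsv",
                                             package = "dhaflux")),
    ethanol = read_flux_dataset(system.file("extdata", "flux_ethanol.tsv",
                                            package = "dhaflux")))
  validation <- list()
  for (i in seq_len(nrow(obs))) {
    s <- obs$substrate[i]
    fs <- stats::setNames(datasets[[s]]$entries$target,
                          datasets[[s]]$entries$reaction)
    relax <- s != "glucose"
    spec <- scenario_validation_spec(fs, s, obs$mu[i], relax_ppp = relax)
    validation[[s]] <- validate_flux_set(sm, spec)
  }

  msg("stage 4: growth maxima and DHA potential scans")
  stoich <- list(model = sm)
  stoich$growth <- lapply(seq_len(nrow(obs)), function(i)
    max_growth(sm, obs$substrate[i], obs$q_s_gdw_h[i])$mu_max)
  names(stoich$growth) <- obs$substrate
  stoich$y_opt <- vapply(obs$substrate, function(s)
    min_carbon_per_biomass(sm, s, obs$q_s_gdw_h[match(s, obs$substrate)]),
    numeric(1))
  stoich$dha_scans <- lapply(seq_len(nrow(obs)), function(i)
    dha_potential_scan(sm, obs$substrate[i], obs$q_s_gdw_h[i]))
  names(stoich$dha_scans) <- obs$substrate

  # -- stage 5: carbon report ----------------------------------------
  msg("stage 5: carbon report")
  obs$v_acl_vol <- vapply(seq_len(nrow(obs)), function(i) {
    s <- obs$substrate[i]
    if (run_fit) {
      fit <- if (s == "ethanol") fits$ethanol else fits$glucose_glycerol
      lab <- datasets[[s]]$label
      unname(fit$steady_states[[lab]]$fluxes["acl"])
    } else {
      e <- datasets[[s]]$entries
      e$target[e$reaction == "acl"]
    }
  }, numeric(1))
  report <- carbon_report(obs, sm)
  if (!is.null(outdir)) {
    write_carbon_report(report, file.path(outdir, "carbon_report"))
    jsonlite::write_json(
      lapply(validation, function(v)
        list(feasible = v$feasible, achieved_mu = v$achieved_mu,
             target_mu = v$target_mu)),
      file.path(outdir, "validation.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(rates = rates, fits = fits, validation = validation,
                 stoich = stoich, report = report, seed = seed),
            class = "dha_pipeline")
}

#' @export
print.dha_pipeline <- function(x, ...) {
  cat("DHA production analysis pipeline (seed", x$seed, ")\n\n")
  print(x$report)
  cat("\nflux-set validation:\n")
  for (s in names(x$validation))
    cat("  ", s, ": ", if (x$validation[[s]]$feasible) "feasible"
        else "infeasible", " (mu ",
        format(x$validation[[s]]$achieved_mu, digits = 3), ")\n", sep = "")
  invisible(x)
}
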