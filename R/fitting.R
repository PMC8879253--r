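#' Flux datasets
#'
#' A flux dataset is the fitting and validation currency: a set of target
#' reaction fluxes (mmol min-1 L-1) with non-negative weights, tied to a
#' substrate scenario.
#'
#' @param label short text label.
#' @param entries data.frame with columns `reaction`, `target`, `weight`
#'   (and optionally `provenance`: `"measured"` or `"synthetic"`).
#' @param substrate scenario substrate.
#' @param uptake_rate scenario uptake, mmol min-1 L-1.
#' @return object of class `flux_dataset`.
#' @export
flux_dataset <- function(label, entries, substrate, uptake_rate) {
  stopifnot(is.data.frame(entries),
            all(c("reaction", "target", "weight") %in% names(entries)),
            all(entries$weight >= 0), uptake_rate >= 0)
  if (is.null(entries$provenance)) entries$provenance <- "synthetic"
  structure(list(label = label, entries = entries, substrate = substrate,
                 uptake_rate = uptake_rate), class = "flux_dataset")
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat("Flux dataset '", x$label, "': ", nrow(x$entries), " targets, ",
      x$substrate, " uptake ", x$uptake_rate, " mmol/min/L\n", sep = "")
  invisible(x)
}

#' Read / write a flux dataset (delimited text with header keys)
#'
#' The file format is tab-separated with `# key: value` header lines for
#' `label`, `substrate`, `uptake_rate` and `units`.
#'
#' @param path file path.
#' @return `read_flux_dataset` returns a `flux_dataset`.
#' @export
read_flux_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  d <- utils::read.delim(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  names(d)[names(d) == "flux"] <- "target"
  flux_dataset(get("label"), d, get("substrate"),
               as.numeric(get("uptake_rate")))
}

#' @rdname read_flux_dataset
#' @param dataset a `flux_dataset`.
#' @export
write_flux_dataset <- function(dataset, path) {
  hdr <- c(paste("# label:", dataset$label),
           paste("# substrate:", dataset$substrate),
           paste("# uptake_rate:", dataset$uptake_rate),
           "# units: mmol.min-1.L-1")
  d <- dataset$entries
  names(d)[names(d) == "target"] <- "flux"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimation configuration
#'
#' @param free_parameters data.frame (reaction, parameter, lower, upper) or
#'   `NULL` for the default: the Vm of every enzymatic and internal
#'   transport reaction (uptakes are fixed by the scenario; PDH is excluded
#'   when every dataset is an ethanol scenario, where its Vmax is pinned at
#'   1e-6), bounded in [1e-6, 1e4].
#' @param conc_cap steady-state concentration cap, mmol/L (default 12).
#' @param ethanol_conc_cap cap for cellular ethanol (default 32).
#' @param n_starts number of independent seeded optimisation starts.
#' @param seed integer RNG seed.
#' @param method optimizer token; `"de"` (differential-evolution-style
#'   global search followed by local refinement) is the only built-in.
#' @param de_pop,de_gens population size and generations for the global
#'   phase.
#' @param local_maxit iteration budget for the local refinement.
#' @param penalty_weight weight of the quadratic concentration-cap penalty.
#' @param vm_budget optional cap on the sum of all Vm (an enzyme-budget
#'   constraint); `NULL` (default) disables it.
#' @return object of class `estimation_config`.
#' @export
estimation_config <- function(free_parameters = NULL, conc_cap = 12,
                              ethanol_conc_cap = 32, n_starts = 1, seed = 1,
                              method = "de", de_pop = 16, de_gens = 40,
                              local_maxit = 40, penalty_weight = 1e3,
                              vm_budget = NULL, steady_tol = 1e-4) {
  stopifnot(n_starts >= 1, conc_cap > 0, ethanol_conc_cap > 0)
  structure(list(free_parameters = free_parameters, conc_cap = conc_cap,
                 ethanol_conc_cap = ethanol_conc_cap, n_starts = n_starts,
                 seed = seed, method = method, de_pop = de_pop,
                 de_gens = de_gens, local_maxit = local_maxit,
                 penalty_weight = penalty_weight, vm_budget = vm_budget,
                 steady_tol = steady_tol),
            class = "estimation_config")
}

#' Check steady-state concentrations against the caps
#'
#' Internal metabolite concentrations must stay at or below 12 mmol/L,
#' except cellular ethanol which may reach 32 mmol/L.
#'
#' @param steady_state a `steady_state`.
#' @param config an [estimation_config()].
#' @return data.frame (metabolite, concentration, cap); zero rows when all
#'   caps hold.
#' @export
check_constraints <- function(steady_state, config = estimation_config()) {
  conc <- steady_state$concentrations
  boundary <- c("glucose_e", "glycerol_e", "ethanol_e", "accoa_sink_e",
                "coa_c", "coa_m", "co2_m")
  conc <- conc[setdiff(names(conc), boundary)]
  caps <- rep(config$conc_cap, length(conc))
  names(caps) <- names(conc)
  caps[grep("^ethanol", names(caps))] <- config$ethanol_conc_cap
  over <- which(conc > caps)
  data.frame(metabolite = names(conc)[over],
             concentration = unname(conc[over]),
             cap = unname(caps[over]), stringsAsFactors = FALSE)
}

# penalty term: smooth quadratic above the caps, on a log1p scale so that
# runaway pools stay finite and ordered rather than flattening the search
# landscape
.cap_penalty <- function(conc, config) {
  boundary <- c("glucose_e", "glycerol_e", "ethanol_e", "accoa_sink_e",
                "coa_c", "coa_m", "co2_m")
  conc <- conc[setdiff(names(conc), boundary)]
  caps <- rep(config$conc_cap, length(conc))
  caps[grep("^ethanol", names(conc))] <- config$ethanol_conc_cap
  sum(log1p(pmax(conc - caps, 0)) ^ 2)
}

#' Weighted relative sum of squared flux errors
#'
#' For each dataset the model is configured to the dataset's scenario,
#' solved to steady state, and compared entry-wise:
#' `sum w * ((v_sim - v_target) / max(|v_target|, 1e-6))^2`, plus a smooth
#' quadratic penalty for every internal concentration above its cap.
#' Steady-state failures contribute a large finite penalty rather than an
#' exception.
#'
#' @param model a `kinetic_model`.
#' @param datasets a `flux_dataset` or list of them.
#' @param config an [estimation_config()].
#' @param warm_states optional environment used to cache steady states
#'   between repeated calls (as during fitting).
#' @return non-negative scalar; attribute `"details"` carries per-dataset
#'   residual tables.
#' @export
objective_sse <- function(model, datasets, config = estimation_config(),
                          warm_states = NULL) {
  if (inherits(datasets, "flux_dataset")) datasets <- list(datasets)
  total <- 0
  details <- list()
  for (ds in datasets) {
    m <- configure_scenario(model, ds$substrate, ds$uptake_rate)
    # a fitted PDH Vm (flagged on the model) overrides the scenario default
    # for glucose/glycerol; ethanol always pins PDH at 1e-6
    if (isTRUE(attr(model, "pdh_fitted")) && ds$substrate != "ethanol")
      m$rate_laws$pdh <- model$rate_laws$pdh
    init <- if (!is.null(warm_states)) warm_states[[ds$label]] else NULL
    ss <- tryCatch(find_steady_state(m, init, tol = config$steady_tol,
                                     max_t = 2e4, quiet = TRUE),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) {
      # graded failure penalty: keeps the search landscape ordered
      total <- total + 1e4 +
        (if (!is.null(ss))
           1e3 * log10(1 + ss$residual) +
           10 * log10(1 + max(ss$concentrations)) else 1e3)
      next
    }
    if (!is.null(warm_states)) warm_states[[ds$label]] <- ss$concentrations
    e <- ds$entries
    v <- ss$fluxes[e$reaction]
    rel <- (v - e$target) / pmax(abs(e$target), 1e-6)
    total <- total + sum(e$weight * rel ^ 2) +
      config$penalty_weight * .cap_penalty(ss$concentrations, config)
    details[[ds$label]] <- data.frame(
      reaction = e$reaction, target = e$target, fitted = unname(v),
      weight = e$weight, rel_error = unname(rel), stringsAsFactors = FALSE)
  }
  if (!is.null(config$vm_budget)) {
    vm_sum <- sum(vapply(model$rate_laws, function(l) l$Vm, numeric(1)))
    total <- total + config$penalty_weight * max(vm_sum - config$vm_budget, 0)^2
  }
  structure(total, details = details)
}

.default_free_parameters <- function(model, datasets) {
  ids <- model$network$reactions$id
  fixed <- unname(.uptake_reaction)
  subs <- unique(vapply(datasets, function(d) d$substrate, ""))
  # reactions that are structurally flux-free under the datasets' scenarios
  # are not estimable and only inflate the search dimension
  if (!"ethanol" %in% subs)
    fixed <- c(fixed, "adh", "aldh", "acalig")
  if (identical(subs, "ethanol"))
    fixed <- c(fixed, "pdh", "pyrt", "hk", "pgi", "pfk", "ald", "tpi",
               "gra3pdh", "pgk", "pgm", "eno", "pyk", "glyk", "g3pd")
  if (!"glucose" %in% subs)
    fixed <- c(fixed, "hk", "pgi", "pfk")
  if (!"glycerol" %in% subs)
    fixed <- c(fixed, "glyk", "g3pd")
  free <- setdiff(ids, unique(fixed))
  data.frame(reaction = free, parameter = "Vm",
             lower = 1e-4, upper = 2e3, stringsAsFactors = FALSE)
}

# initial Vm guesses: scale generously from the largest target flux a
# reaction must carry, so that at the start every consumer runs far below
# saturation, pools stay small (inside the concentration caps) and the
# search begins in the clean least-squares regime; reactions without
# targets keep their current Vm
.smart_init <- function(model, datasets, free) {
  vm0 <- vapply(free$reaction, function(r) model$rate_laws[[r]]$Vm, numeric(1))
  names(vm0) <- free$reaction
  targ <- list()
  for (ds in datasets)
    for (i in seq_len(nrow(ds$entries))) {
      r <- ds$entries$reaction[i]
      targ[[r]] <- max(abs(ds$entries$target[i]), targ[[r]] %||% 0)
    }
  subs <- vapply(datasets, function(d) d$substrate, "")
  for (r in intersect(names(targ), names(vm0))) {
    if (targ[[r]] <= 0) next
    mult <- if (model$network$reactions$reversible[
      model$network$reactions$id == r]) 20 else 8
    # structural special cases: the malic enzyme must run near half
    # saturation (a saturated drain leaves the TCA pool sizes neutrally
    # stable and lets them wander above the caps); PYC competes with PDH
    # for a pyruvate pool PDH keeps far below Km; CS works against a
    # thermodynamically micromolar oxaloacetate level
    if (r == "me")  mult <- 2
    if (r == "pyc") mult <- if (all(subs == "ethanol")) 20 else 9
    if (r == "cs")  mult <- 15
    if (r == "gra3pdh") mult <- 50
    # the citrate export step must run near saturation at the highest
    # throughput so that the citrate branch ratio can differ between
    # scenarios (otherwise the Acetyl-CoA splits are ratio-locked)
    if (r == "citt" && length(subs) > 1) mult <- 1.3
    vm0[r] <- mult * targ[[r]]
  }
  vm0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.apply_params <- function(model, params) {
  for (r in names(params)) model$rate_laws[[r]]$Vm <- params[[r]]
  if ("pdh" %in% names(params)) attr(model, "pdh_fitted") <- TRUE
  model
}

#' Fit kinetic rate-law parameters to flux datasets
#'
#' Global differential-evolution-style search over log10(Vm) followed by
#' Nelder-Mead refinement, minimising [objective_sse()].  The best result
#' over `n_starts` seeded runs is returned.  Following the two-model
#' structure of the analysis, glucose and glycerol datasets are meant to be
#' fitted jointly with one parameter set, and ethanol separately (PDH Vmax
#' pinned at 1e-6); pass the corresponding dataset groups in two calls.
#'
#' @param model a `kinetic_model`.
#' @param datasets a `flux_dataset` or list of them.
#' @param config an [estimation_config()].
#' @return object of class `kinetic_fit` with elements `parameters`
#'   (fitted Vm), `objective`, `per_dataset_residuals`,
#'   `constraint_violations`, `n_evaluations`, `seed`, `model` (updated),
#'   `steady_states`.
#' @export
fit_parameters <- function(model, datasets, config = estimation_config()) {
  if (inherits(datasets, "flux_dataset")) datasets <- list(datasets)
  free <- config$free_parameters %||% .default_free_parameters(model, datasets)
  if (!nrow(free)) stop("free parameter list is empty")
  n_eval <- 0L
  warm <- new.env(parent = emptyenv())
  obj_log10 <- function(lp) {
    params <- stats::setNames(10 ^ lp, free$reaction)
    n_eval <<- n_eval + 1L
    as.numeric(objective_sse(.apply_params(model, params), datasets, config,
                             warm_states = warm))
  }
  lo <- log10(free$lower); hi <- log10(free$upper)
  init <- pmin(pmax(log10(.smart_init(model, datasets, free)), lo), hi)

  best <- NULL
  diagnostics <- list()
  for (s in seq_len(config$n_starts)) {
    seed_s <- config$seed + 1000L * (s - 1L)
    set.seed(seed_s)
    res <- tryCatch({
      de <- .de_optim(obj_log10, init, lo, hi,
                      pop = config$de_pop, gens = config$de_gens)
      loc <- stats::nlminb(de$par, function(p)
        obj_log10(pmin(pmax(p, lo), hi)),
        lower = lo, upper = hi,
        control = list(iter.max = config$local_maxit,
                       eval.max = 10 * config$local_maxit,
                       rel.tol = 1e-10))
      par <- pmin(pmax(loc$par, lo), hi)
      list(par = par, value = obj_log10(par), seed = seed_s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics[[s]] <- conditionMessage(res)
      next
    }
    diagnostics[[s]] <- paste0("start ", s, ": objective ",
                               format(res$value, digits = 6))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed:\n",
         paste(unlist(diagnostics), collapse = "\n"))

  params <- stats::setNames(10 ^ best$par, free$reaction)
  fitted_model <- .apply_params(model, params)
  final <- objective_sse(fitted_model, datasets, config, warm_states = warm)
  sss <- list(); viol <- list()
  for (ds in datasets) {
    m <- configure_scenario(fitted_model, ds$substrate, ds$uptake_rate)
    if (isTRUE(attr(fitted_model, "pdh_fitted")) && ds$substrate != "ethanol")
      m$rate_laws$pdh <- fitted_model$rate_laws$pdh
    # record the solution at a tighter tolerance than used during search
    ss <- find_steady_state(m, warm[[ds$label]], tol = 1e-6, quiet = TRUE)
    sss[[ds$label]] <- ss
    v <- check_constraints(ss, config)
    if (nrow(v)) viol[[ds$label]] <- v
  }
  structure(list(parameters = params, objective = as.numeric(final),
                 per_dataset_residuals = attr(final, "details"),
                 constraint_violations = viol,
                 n_evaluations = n_eval, seed = config$seed,
                 diagnostics = unlist(diagnostics),
                 model = fitted_model, steady_states = sss,
                 datasets = datasets),
            class = "kinetic_fit")
}

# compact rand/1/bin differential evolution on a box
.de_optim <- function(fn, init, lo, hi, pop = 16, gens = 40,
                      F = 0.7, CR = 0.9) {
  n <- length(init)
  P <- matrix(stats::runif(pop * n, -0.6, 0.6), pop, n, byrow = TRUE)
  P <- sweep(P, 2, init, `+`)
  P[1, ] <- init
  P <- pmin(pmax(P, matrix(lo, pop, n, byrow = TRUE)),
            matrix(hi, pop, n, byrow = TRUE))
  fit <- apply(P, 1, fn)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      r <- sample(setdiff(seq_len(pop), i), 3)
      mutant <- P[r[1], ] + F * (P[r[2], ] - P[r[3], ])
      jr <- sample.int(n, 1)
      cross <- stats::runif(n) < CR
      cross[jr] <- TRUE
      trial <- ifelse(cross, mutant, P[i, ])
      trial <- pmin(pmax(trial, lo), hi)
      ft <- fn(trial)
      if (ft <= fit[i]) { P[i, ] <- trial; fit[i] <- ft }
    }
  }
  b <- which.min(fit)
  list(par = P[b, ], value = fit[b])
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit: objective", format(x$objective, digits = 6),
      "over", x$n_evaluations, "evaluations (seed", x$seed, ")\n")
  for (lbl in names(x$per_dataset_residuals)) {
    d <- x$per_dataset_residuals[[lbl]]
    cat("  ", lbl, ": max |rel error| ",
        format(max(abs(d$rel_error)), digits = 3), "\n", sep = "")
  }
  if (length(x$constraint_violations))
    cat("  concentration-cap violations in:",
        paste(names(x$constraint_violations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  cat("Fitted Vm parameters (mmol/min/L):\n")
  print(round(object$parameters, 4))
  print(object)
  invisible(object)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$parameters

#' Predict steady-state fluxes from a fitted kinetic model
#'
#' @param object a `kinetic_fit`.
#' @param substrate scenario substrate.
#' @param uptake_rate scenario uptake (mmol min-1 L-1).
#' @param ... unused.
#' @return named flux vector (mmol min-1 L-1).
#' @export
predict.kinetic_fit <- function(object, substrate, uptake_rate, ...) {
  m <- configure_scenario(object$model, substrate, uptake_rate)
  if (isTRUE(attr(object$model, "pdh_fitted")) && substrate != "ethanol")
    m$rate_laws$pdh <- object$model$rate_laws$pdh
  find_steady_state(m, quiet = TRUE)$fluxes
}
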