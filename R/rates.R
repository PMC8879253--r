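#' Batch cultivation growth curves
#'
#' @param time sampling times, hours (strictly increasing).
#' @param biomass biomass concentrations, g/L (non-negative).
#' @param substrate data.frame (or named list) of substrate
#'   concentrations, g/L, one column per substrate.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(time, biomass, substrate = NULL) {
  stopifnot(length(time) == length(biomass), all(diff(time) > 0),
            all(biomass >= 0))
  if (!is.null(substrate)) {
    substrate <- as.data.frame(substrate)
    stopifnot(nrow(substrate) == length(time), all(substrate >= 0))
  }
  structure(list(time = time, biomass = biomass, substrate = substrate),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Batch growth curve:", length(x$time), "points over",
      max(x$time), "h;",
      if (is.null(x$substrate)) "no substrate columns"
      else paste("substrates:", paste(names(x$substrate), collapse = ", ")),
      "\n")
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  plot(x$time, x$biomass, type = "b", pch = 16, xlab = "time [h]",
       ylab = "biomass [g/L]", ...)
  if (!is.null(x$substrate)) {
    graphics::par(new = TRUE)
    graphics::matplot(x$time, as.matrix(x$substrate), type = "b", pch = 1,
                      axes = FALSE, xlab = "", ylab = "", lty = 2)
    graphics::axis(4)
    graphics::mtext("substrate [g/L]", side = 4, line = 2.5)
  }
  invisible(x)
}

#' Write / read a growth curve as CSV
#'
#' Columns: time_h, biomass_gL, `<substrate>_gL` ...
#'
#' @param curve a `growth_curve`.
#' @param path file path.
#' @return `read_growth_curve` returns a `growth_curve`.
#' @export
write_growth_curve <- function(curve, path) {
  d <- data.frame(time_h = curve$time, biomass_gL = curve$biomass)
  if (!is.null(curve$substrate))
    for (s in names(curve$substrate))
      d[[paste0(s, "_gL")]] <- curve$substrate[[s]]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  d <- utils::read.csv(path)
  subs <- grep("_gL$", setdiff(names(d), "biomass_gL"), value = TRUE)
  sub <- if (length(subs)) {
    out <- d[, subs, drop = FALSE]
    names(out) <- sub("_gL$", "", names(out))
    out
  } else NULL
  growth_curve(d$time_h, d$biomass_gL, sub)
}

# longest contiguous window (>= min_pts) with ln-linear R^2 >= r2_min;
# ties broken by higher R^2.  Trailing stationary-phase points are trimmed
# first: after substrate exhaustion the biomass plateaus, and because a
# single plateau point barely moves the R^2 of a long window it would
# otherwise slip into the selected span and bias the slope downward.
.auto_window <- function(time, biomass, min_pts = 4, r2_min = 0.98) {
  n <- length(time)
  if (n > min_pts && all(biomass > 0)) {
    lx <- log(biomass)
    slopes <- diff(lx) / diff(time)
    ref <- stats::median(slopes[slopes > 0])
    if (is.finite(ref) && ref > 0) {
      # centered local slope per point (backward slope at the end): a
      # point still belongs to the exponential phase if its neighbourhood
      # grows at a substantial fraction of the typical rate
      cs <- c(slopes[1],
              (lx[-(1:2)] - lx[seq_len(n - 2)]) /
                (time[-(1:2)] - time[seq_len(n - 2)]),
              slopes[n - 1])
      while (n > min_pts && cs[n] < 0.5 * ref) n <- n - 1L
      time <- time[seq_len(n)]; biomass <- biomass[seq_len(n)]
    }
  }
  best <- NULL
  for (i in seq_len(n - min_pts + 1)) {
    for (j in seq(i + min_pts - 1, n)) {
      x <- biomass[i:j]
      if (any(x <= 0)) next
      f <- stats::lm(log(x) ~ time[i:j])
      r2 <- suppressWarnings(summary(f)$r.squared)
      if (is.na(r2)) next
      if (r2 >= r2_min) {
        len <- j - i + 1
        if (is.null(best) || len > best$len ||
            (len == best$len && r2 > best$r2))
          best <- list(i = i, j = j, len = len, r2 = r2)
      }
    }
  }
  if (is.null(best))
    stop("no contiguous window of >= ", min_pts,
         " points reaches ln-linear R^2 >= ", r2_min)
  best
}

#' Specific growth rate from a batch curve
#'
#' Slope of the least-squares line of ln(biomass) against time over the
#' window (exponential approximation).  When no window is given, the
#' longest contiguous span of at least 4 points with ln-linear R^2 >=
#' 0.98 is selected automatically.
#'
#' @param curve a `growth_curve`.
#' @param window optional `c(t_start, t_end)` in hours.
#' @return mu (h-1) with attributes `window` and `r_squared`.
#' @export
fit_specific_growth_rate <- function(curve, window = NULL) {
  if (is.null(window)) {
    w <- .auto_window(curve$time, curve$biomass)
    idx <- w$i:w$j
  } else {
    idx <- which(curve$time >= window[1] & curve$time <= window[2])
    if (length(idx) < 3) stop("fewer than 3 points in window")
  }
  x <- curve$biomass[idx]
  if (any(x <= 0)) stop("non-positive biomass inside the fitting window")
  f <- stats::lm(log(x) ~ curve$time[idx])
  mu <- max(unname(stats::coef(f)[2]), 0)
  structure(mu, window = range(curve$time[idx]),
            r_squared = suppressWarnings(summary(f)$r.squared))
}

# built-in molar masses, g/mol
.molar_mass <- c(glucose = 180.16, glycerol = 92.09, ethanol = 46.07,
                 acetate = 60.05)

# integral of biomass over time by the log-mean (piecewise-exponential)
# trapezoid: exact when biomass grows exponentially between samples
.biomass_integral <- function(time, biomass) {
  n <- length(time)
  seg <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    dt <- time[i + 1] - time[i]
    a <- biomass[i]; b <- biomass[i + 1]
    seg[i] <- if (a > 0 && b > 0 && abs(log(b / a)) > 1e-12)
      dt * (b - a) / log(b / a) else dt * (a + b) / 2
  }
  c(0, cumsum(seg))
}

#' Biomass-specific substrate uptake rate from a batch curve
#'
#' Regresses the consumed substrate (mmol/L) against the integrated
#' biomass (gDW h/L) over the exponential growth window; the slope is
#' q_s in mmol gDW-1 h-1.  The integral uses the log-mean trapezoid,
#' which is exact under exponential growth.
#'
#' @param curve a `growth_curve`.
#' @param substrate substrate column name.
#' @param molar_mass g/mol; looked up among the built-in substrates when
#'   omitted.
#' @param window optional time window (defaults to the growth window).
#' @return q_s (mmol gDW-1 h-1) with attribute `r_squared`.
#' @export
fit_uptake_rate <- function(curve, substrate, molar_mass = NULL,
                            window = NULL) {
  if (is.null(curve$substrate) || !substrate %in% names(curve$substrate))
    stop("substrate column not present: ", substrate)
  if (is.null(molar_mass)) {
    if (!substrate %in% names(.molar_mass))
      stop("no built-in molar mass for ", substrate)
    molar_mass <- .molar_mass[[substrate]]
  }
  S <- curve$substrate[[substrate]]
  if (S[length(S)] > S[1] + 1e-12)
    stop("substrate increases over the curve: ", substrate)
  if (is.null(window)) {
    w <- .auto_window(curve$time, curve$biomass)
    idx <- w$i:w$j
  } else {
    idx <- which(curve$time >= window[1] & curve$time <= window[2])
  }
  # exclude (near-)exhausted samples: once the substrate is gone the
  # consumed amount saturates and no longer reflects the uptake rate
  keep <- S[idx] > 0.05 * S[idx[1]]
  if (sum(keep) >= 3) idx <- idx[keep]
  consumed <- (S[idx[1]] - S[idx]) * 1000 / molar_mass   # mmol/L
  xint <- .biomass_integral(curve$time[idx], curve$biomass[idx])
  if (max(xint) == 0) return(structure(0, r_squared = NA_real_))
  # measurement noise is multiplicative in S, so var(consumed_i) scales
  # with S_ref^2 + S_i^2; weighting accordingly stabilises the slope
  wts <- 1 / (S[idx[1]]^2 + S[idx]^2 + (0.01 * S[idx[1]])^2)
  f <- stats::lm(consumed ~ xint, weights = wts)
  structure(max(unname(stats::coef(f)[2]), 0),
            r_squared = suppressWarnings(summary(f)$r.squared))
}

#' Growth and uptake estimates for one curve
#'
#' @param curve a `growth_curve`.
#' @param substrate substrate column name.
#' @param molar_mass optional g/mol.
#' @return object of class `rate_estimate`: `mu` (h-1), `q_s`
#'   (mmol gDW-1 h-1), `window`, `r_squared` (per fit).
#' @export
fit_rates <- function(curve, substrate, molar_mass = NULL) {
  mu <- fit_specific_growth_rate(curve)
  qs <- fit_uptake_rate(curve, substrate, molar_mass,
                        window = attr(mu, "window"))
  structure(list(mu = as.numeric(mu), q_s = as.numeric(qs),
                 window = attr(mu, "window"),
                 r_squared = c(mu = attr(mu, "r_squared"),
                               q_s = attr(qs, "r_squared")),
                 substrate = substrate),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Rate estimate (", x$substrate, "): mu = ",
      format(x$mu, digits = 4), " /h, q_s = ", format(x$q_s, digits = 4),
      " mmol/gDW/h  [window ", x$window[1], "-", x$window[2], " h]\n",
      sep = "")
  invisible(x)
}

#' Substrate uptake expressed in single-carbon (C1) moles
#'
#' @param q_s substrate uptake (mmol per gDW h or per L min).
#' @param n_carbon carbons per substrate molecule.
#' @return C1 uptake in the same unit system.
#' @export
c1_uptake <- function(q_s, n_carbon) {
  stopifnot(q_s >= 0, n_carbon >= 0)
  q_s * n_carbon
}

#' Percentage of substrate carbon routed into Acetyl-CoA
#'
#' Each Acetyl-CoA carries two substrate-derived carbons, so the share is
#' 100 * 2 * v_ACL / U_C1.
#'
#' @param v_acl cellular Acetyl-CoA production flux (ATP-citrate lyase),
#'   mmol min-1 L-1.
#' @param u_c1 C1 uptake, mmol min-1 L-1 (> 0).
#' @return percent.
#' @export
fraction_carbon_to_acetylcoa <- function(v_acl, u_c1) {
  stopifnot(u_c1 > 0)
  100 * 2 * v_acl / u_c1
}

#' Substrate carbon invested per gram of biomass
#'
#' @param u_c1_gdw_h C1 uptake, mmol gDW-1 h-1.
#' @param mu specific growth rate, h-1 (> 0).
#' @return mmol C1 per gDW.
#' @export
carbon_per_gdw_biomass <- function(u_c1_gdw_h, mu) {
  stopifnot(mu > 0)
  u_c1_gdw_h / mu
}

#' Excess carbon use relative to the model optimum
#'
#' @param y_exp experimental carbon-per-biomass, mmol C1 gDW-1.
#' @param y_opt model-optimal carbon-per-biomass (> 0).
#' @return percent excess, 100 * (y_exp / y_opt - 1).
#' @export
excess_carbon_pct <- function(y_exp, y_opt) {
  stopifnot(y_opt > 0)
  100 * (y_exp / y_opt - 1)
}

#' Convert a rate between dry-weight and volumetric unit systems
#'
#' @param value rate value (>= 0).
#' @param direction `"gdw_to_vol"` (mmol gDW-1 h-1 -> mmol min-1 L-1,
#'   multiply by 5.5) or `"vol_to_gdw"` (divide by 5.5).
#' @return converted value; the round trip is exact.
#' @export
convert_rate_units <- function(value, direction = c("gdw_to_vol", "vol_to_gdw")) {
  direction <- match.arg(direction)
  stopifnot(all(value >= 0))
  if (direction == "gdw_to_vol") value * .dw_factor else value / .dw_factor
}

#' Substrate-comparison carbon report
#'
#' Builds the per-substrate carbon-accounting table: uptake in both unit
#' systems, C1 uptake, observed growth rate, experimental carbon per gram
#' biomass, the stoichiometric-model optimum and the excess over it, and
#' the percentage of substrate carbon routed to Acetyl-CoA.
#'
#' @param scenarios data.frame with columns `substrate`, `q_s_gdw_h`
#'   (mmol gDW-1 h-1), `mu` (h-1) and `v_acl_vol` (ACL flux,
#'   mmol min-1 L-1).
#' @param stoich_model optional `stoich_model` for the optimized columns.
#' @return data.frame of class `carbon_report`.
#' @export
carbon_report <- function(scenarios, stoich_model = NULL) {
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios$substrate[i]
    nC <- carbon_count(s)
    qs_gdw <- scenarios$q_s_gdw_h[i]
    qs_vol <- convert_rate_units(qs_gdw, "gdw_to_vol")
    u1_gdw <- c1_uptake(qs_gdw, nC)
    u1_vol <- c1_uptake(qs_vol, nC)
    mu <- scenarios$mu[i]
    y_exp <- carbon_per_gdw_biomass(u1_gdw, mu)
    y_opt <- mu_opt <- NA_real_
    if (!is.null(stoich_model)) {
      g <- max_growth(stoich_model, s, qs_gdw)
      mu_opt <- g$mu_max
      y_opt <- u1_gdw / mu_opt
    }
    data.frame(
      substrate = s, q_s_gdw_h = qs_gdw, q_s_vol_min = qs_vol,
      U_C1_gdw_h = u1_gdw, U_C1_vol_min = u1_vol, mu = mu,
      Y_C1X = y_exp, mu_max_opt = mu_opt, Y_C1X_opt = y_opt,
      excess_pct = if (is.na(y_opt)) NA_real_ else excess_carbon_pct(y_exp, y_opt),
      phi_accoa_pct = if (!is.null(scenarios$v_acl_vol))
        fraction_carbon_to_acetylcoa(scenarios$v_acl_vol[i], u1_vol)
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("carbon_report", class(res))
  res
}

#' Write a carbon report as TSV and JSON
#'
#' @param report a `carbon_report`.
#' @param stem output path prefix.
#' @return invisibly, the file paths.
#' @export
write_carbon_report <- function(report, stem) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv = tsv, json = js))
}
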