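#' Kinetic rate laws
#'
#' Four functional forms cover the pathway-scale model:
#' \describe{
#'   \item{constant_flux}{`Vm * k_over` — a concentration-independent rate,
#'     used for substrate uptake.}
#'   \item{irreversible_mm}{`Vm * k_over * prod_i S_i/(Km_i + S_i)` —
#'     irreversible Michaelis-Menten for committed steps.}
#'   \item{reversible_mm_haldane}{`Vm * k_over * (prod_i S_i/Km_i) *
#'     (1 - Gamma/Keq) / D` with `Gamma` the mass-action ratio and `D` the
#'     standard denominator `prod(1 + S/Km) + prod(1 + P/Km) - 1`.}
#'   \item{mass_action}{`Vm * k_over * prod_i S_i^|s_i|`.}
#' }
#'
#' `Vm` is the maximal-rate scaling factor (mmol min-1 L-1); `k_over` is a
#' dimensionless overexpression coefficient, 1 for wild-type enzyme levels.
#'
#' @param form one of `"constant_flux"`, `"irreversible_mm"`,
#'   `"reversible_mm_haldane"`, `"mass_action"`.
#' @param Vm maximal-rate scaling factor, >= 0 (mmol min-1 L-1).
#' @param k_over overexpression coefficient, > 0 (dimensionless).
#' @param Km named vector of Michaelis constants (mmol L-1), one per
#'   participating species that the form requires.
#' @param Keq equilibrium constant (dimensionless), required > 0 for the
#'   reversible form.
#' @param substrates,products named numeric vectors of absolute
#'   stoichiometric coefficients.  When `substrates` is omitted it defaults
#'   to the `Km` names (coefficient 1 each).
#' @return an object of class `rate_law`.
#' @export
rate_law <- function(form = c("constant_flux", "irreversible_mm",
                              "reversible_mm_haldane", "mass_action"),
                     Vm = 1, k_over = 1, Km = numeric(), Keq = NA_real_,
                     substrates = NULL, products = NULL) {
  form <- match.arg(form)
  stopifnot(Vm >= 0, k_over >= 0)
  if (length(Km) && any(Km <= 0)) stop("all Km must be > 0")
  if (form == "reversible_mm_haldane" && (is.na(Keq) || Keq <= 0))
    stop("reversible form requires Keq > 0")
  if (is.null(substrates) && length(Km))
    substrates <- stats::setNames(rep(1, length(Km)), names(Km))
  if (is.null(substrates)) substrates <- numeric(0)
  if (is.null(products))  products  <- numeric(0)
  structure(list(form = form, Vm = Vm, k_over = k_over, Km = Km, Keq = Keq,
                 substrates = substrates, products = products),
            class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat("<rate_law ", x$form, ">  Vm=", format(x$Vm), " k=", format(x$k_over),
      if (!is.na(x$Keq)) paste0(" Keq=", format(x$Keq)), "\n", sep = "")
  invisible(x)
}

#' Evaluate a rate law at given concentrations
#'
#' @param law a [rate_law()].
#' @param concentrations named numeric vector (mmol L-1) containing every
#'   species the law references; all must be >= 0.
#' @return flux in mmol min-1 L-1 (signed for the reversible form).
#' @export
evaluate_rate <- function(law, concentrations) {
  need <- union(names(law$substrates), names(law$products))
  missing <- setdiff(need, names(concentrations))
  if (length(missing))
    stop("missing concentrations: ", paste(missing, collapse = ", "))
  if (length(need) && any(concentrations[need] < 0))
    stop("negative concentration for: ",
         paste(need[concentrations[need] < 0], collapse = ", "))
  vmax <- law$Vm * law$k_over
  if (law$form == "constant_flux") return(vmax)
  S <- concentrations[names(law$substrates)]
  if (law$form == "irreversible_mm") {
    km <- law$Km[names(law$substrates)]
    return(vmax * prod(S / (km + S)))
  }
  if (law$form == "mass_action")
    return(vmax * prod(S ^ law$substrates))
  # reversible_mm_haldane; all reversible reactions in the model have unit
  # substrate coefficients, for which (prod S/Km)(1 - Gamma/Keq) simplifies
  # exactly to prod(S/Km) - prod(P^p)/(prod(Km_S) * Keq) - finite at S = 0.
  P <- concentrations[names(law$products)]
  kms <- law$Km[names(law$substrates)]
  kmp <- law$Km[names(law$products)]
  D <- prod(1 + S / kms) + prod(1 + P / kmp) - 1
  num <- prod(S / kms) - prod(P ^ law$products) / (prod(kms) * law$Keq)
  vmax * num / D
}
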