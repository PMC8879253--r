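# The kinetic parameter estimations take minutes, and several test files
# examine the same fitted models; fit once and memoise for the session.
.fit_cache <- new.env(parent = emptyenv())

packaged_dataset <- function(which) {
  read_flux_dataset(system.file("extdata",
                                paste0("flux_", which, ".tsv"),
                                package = "dhaflux"))
}

get_joint_fit <- function() {
  if (is.null(.fit_cache$joint)) {
    .fit_cache$joint <- fit_parameters(
      kinetic_model(),
      list(packaged_dataset("glucose"), packaged_dataset("glycerol")),
      estimation_config(seed = 1, de_pop = 14, de_gens = 40,
                        local_maxit = 60))
  }
  .fit_cache$joint
}

get_ethanol_fit <- function() {
  if (is.null(.fit_cache$ethanol)) {
    .fit_cache$ethanol <- fit_parameters(
      kinetic_model(), packaged_dataset("ethanol"),
      estimation_config(seed = 1, de_pop = 12, de_gens = 20))
  }
  .fit_cache$ethanol
}

get_stoich_model <- function() {
  if (is.null(.fit_cache$stoich)) .fit_cache$stoich <- build_stoich_model()
  .fit_cache$stoich
}

# parameter-recovery experiment: noise-free synthetic fluxes from the
# wild-type glycerol parameterisation, refitted from scratch
get_recovery_fit <- function() {
  if (is.null(.fit_cache$recovery)) {
    ds <- gen_flux_dataset(kinetic_model(), "glycerol", 2.42, 0, seed = 1)
    fit <- fit_parameters(kinetic_model(), ds,
                          estimation_config(seed = 2, de_pop = 10,
                                            de_gens = 15, local_maxit = 60))
    .fit_cache$recovery <- list(truth = attr(ds, "truth"), fit = fit)
  }
  .fit_cache$recovery
}
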