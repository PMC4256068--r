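#' Subject-level parameter dispersion for synthetic cohorts
#'
#' Returns a parameter sampler for [simulate_cohort()] that draws each
#' subject's parameters around the model defaults: positive parameters
#' (volatility, temperature, learning-rate odds, HGF coupling/drift) are
#' jittered log-normally with standard deviation `sd`, biases and influence
#' weights receive additive Gaussian jitter with the same standard
#' deviation. This emulates mild between-subject heterogeneity while keeping
#' every subject inside the model's sensible operating range; it is the
#' dispersion used by the package's recovery studies.
#'
#' @param sd dispersion (log scale for positive parameters) per parameter.
#' @return A `function(model, subject)` suitable for the `subject_params`
#'   argument of [simulate_cohort()]; it must be called with an active RNG
#'   (as [simulate_cohort()] does) so draws are seeded.
#' @export
cohort_param_sampler <- function(sd = 0.5) {
  function(model, subject) {
    p <- default_params(model)
    for (nm in names(p)) {
      if (nm %in% c("p", "preferred")) next  # RB policy is fixed by design
      if (nm == "alpha") {
        p[[nm]] <- sigmoid(logit(p[[nm]]) + stats::rnorm(1, 0, sd))
      } else if (nm %in% c("bias", "omega", "eta1", "eta2", "eta3")) {
        p[[nm]] <- p[[nm]] + stats::rnorm(1, 0, sd)
      } else {
        p[[nm]] <- p[[nm]] * exp(stats::rnorm(1, 0, sd))
      }
    }
    p
  }
}
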