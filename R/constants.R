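#' Model constants of the Cyberslug decision core
#'
#' Returns the full set of coefficients used by the sensory, affective and
#' motor equations. The published model text fixes the learning parameters
#' (`alpha = 0.5`, `beta = 1`, `lambda = 1`), the nutrition dynamics
#' (`nutrition_decay = 0.0005` per step, `feed_gain = 0.3` per prey,
#' initial nutrition 0.8), the appetitive-state baseline (0.01) and the
#' approach-avoidance switch threshold (0.245). The remaining gain
#' coefficients `k0`--`k9` are not stated numerically in the text; the
#' defaults here were calibrated once, by simulation, to reproduce the
#' described selectivity behaviours, and are fully overridable. (`k2` does
#' not exist: the equation numbering skips it.)
#'
#' @param k0 somatic-map surround-suppression gain: steepness of the
#'   logistic gates that suppress the laterality signal of the weaker
#'   signature odor.
#' @param k1 attenuation of the innate betaine term of R+ by the learned
#'   hermi association (the divisive `1 + k1*Vh*sns_hermi` term).
#' @param k3 gain of the learned associative terms in R+ and R-.
#' @param k4 satiation shape coefficient: scales the exponential inside the
#'   squared-logistic satiation curve.
#' @param k5 incentive gain inside the appetitive-state sigmoid.
#' @param k6 satiation gain inside the appetitive-state sigmoid.
#' @param k7 gain of the transient appetitive-state suppression term
#'   `k7 * (App_State_Switch - 1)`.
#' @param k8 steepness of the approach-avoidance switch sigmoid.
#' @param k9 maximal decision turn amplitude, degrees per step.
#' @param switch_threshold appetitive-state level at which the switch
#'   crosses zero (approach above, avoidance below).
#' @param app_state_baseline additive baseline of appetitive state.
#' @param nutrition_decay fractional nutrition loss per time step.
#' @param feed_gain nutrition added per prey item consumed.
#' @param nutrition_init nutrition at trial start.
#' @param alpha Rescorla-Wagner salience of the conditioned (odor) stimulus.
#' @param beta Rescorla-Wagner associability rate of the unconditioned
#'   stimulus.
#' @param lambda Rescorla-Wagner asymptotic associative strength.
#'
#' @return A named list of class `cs_constants`.
#' @examples
#' cs <- cs_constants()
#' cs$alpha
#' cs_constants(k6 = 3) # weaker satiation influence on appetitive state
#' @export
cs_constants <- function(k0 = 2, k1 = 0.1, k3 = 1.03, k4 = 3,
                         k5 = 1.67, k6 = 80, k7 = 0.1, k8 = 40, k9 = 8,
                         switch_threshold = 0.245,
                         app_state_baseline = 0.01,
                         nutrition_decay = 0.0005,
                         feed_gain = 0.3,
                         nutrition_init = 0.8,
                         alpha = 0.5, beta = 1, lambda = 1) {
  cs <- list(
    k0 = k0, k1 = k1, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
    k8 = k8, k9 = k9,
    switch_threshold = switch_threshold,
    app_state_baseline = app_state_baseline,
    nutrition_decay = nutrition_decay,
    feed_gain = feed_gain,
    nutrition_init = nutrition_init,
    alpha = alpha, beta = beta, lambda = lambda
  )
  for (nm in names(cs)) {
    v <- cs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("constant '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  stopifnot(
    cs$switch_threshold > 0, cs$switch_threshold < 1,
    cs$nutrition_decay >= 0, cs$nutrition_decay < 1,
    cs$alpha >= 0, cs$alpha <= 1,
    cs$beta >= 0, cs$beta <= 1,
    cs$lambda >= 0
  )
  structure(cs, class = "cs_constants")
}

#' @export
print.cs_constants <- function(x, ...) {
  cat("Cyberslug model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}
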