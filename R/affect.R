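#' Prior belief over policy precision
#'
#' Precision `gamma` over expected free energy is parameterized by a rate
#' `beta = 1/gamma`. The belief records the prior rate `beta0`, the current
#' posterior rate `beta_post` and the implied `gamma`, with `beta_post`
#' clamped at `beta_min` so `gamma` stays finite.
#'
#' @param beta0 Positive prior rate (initial `gamma = 1/beta0`).
#' @param beta_min Lower clamp on the posterior rate.
#' @return Object of class `precision_belief`.
#' @export
precision_belief <- function(beta0 = 1, beta_min = 0.05) {
  stopifnot(beta0 > 0, beta_min > 0)
  structure(
    list(beta0 = beta0, beta_post = beta0, gamma = 1 / beta0, beta_min = beta_min),
    class = "precision_belief"
  )
}

#' Affective charge of a policy-belief shift
#'
#' Affective charge is the expected-free-energy-weighted shift in policy
#' beliefs, `AC = (prior - posterior) . G`. It is positive exactly when the
#' posterior moves mass toward policies with below-prior-average expected
#' free energy — i.e. positive affect signals low expected free energy — and
#' zero when the beliefs do not move or when `G` is constant across policies.
#'
#' @param prior,posterior Categorical vectors over policies (aligned).
#' @param efe_per_policy Per-policy expected free energies `G` (nats).
#' @param deadband Non-negative half-width of the neutral valence band.
#' @return Object of class `affective_charge`: list with `value` (nats) and
#'   `valence` (`"negative"`, `"neutral"` or `"positive"`).
#' @export
#' @examples
#' affective_charge(c(0.5, 0.5), c(0.9, 0.1), c(1, 3))
affective_charge <- function(prior, posterior, efe_per_policy, deadband = 0) {
  stopifnot(length(prior) == length(posterior),
            length(prior) == length(efe_per_policy))
  value <- sum((prior - posterior) * efe_per_policy)
  structure(
    list(value = value, valence = valence_label(value, deadband)),
    class = "affective_charge"
  )
}

#' Update a precision belief from an affective charge
#'
#' One-shot fixed-point assignment per decision cycle:
#' `beta_post = max(beta0 - AC, beta_min)` and `gamma = 1/beta_post`.
#' Positive affective charge therefore strictly increases confidence in the
#' expected-free-energy ranking of policies; negative charge decreases it,
#' until the clamp engages.
#'
#' @param belief A [precision_belief()].
#' @param ac An [affective_charge()] or a bare numeric value.
#' @return The updated `precision_belief`.
#' @export
update_precision <- function(belief, ac) {
  value <- if (inherits(ac, "affective_charge")) ac$value else ac
  belief$beta_post <- max(belief$beta0 - value, belief$beta_min)
  belief$gamma <- 1 / belief$beta_post
  belief
}

#' Valence label of an affective-charge value
#'
#' @param ac_value Numeric affective charge (nats).
#' @param deadband Non-negative half-width of the neutral band.
#' @return `"negative"`, `"neutral"` or `"positive"`.
#' @export
valence_label <- function(ac_value, deadband = 0) {
  stopifnot(deadband >= 0)
  if (ac_value > deadband) "positive"
  else if (ac_value < -deadband) "negative"
  else "neutral"
}

#' @export
print.affective_charge <- function(x, ...) {
  cat(sprintf("<affective_charge> %.4f nats (%s)\n", x$value, x$valence))
  invisible(x)
}

#' @export
print.precision_belief <- function(x, ...) {
  cat(sprintf("<precision_belief> beta0 = %.4g, beta_post = %.4g, gamma = %.4g\n",
              x$beta0, x$beta_post, x$gamma))
  invisible(x)
}
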