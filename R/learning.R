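#' Dirichlet concentration store shadowing a model's arrays
#'
#' Holds Dirichlet concentration parameters `a`, `b`, `d` (and optionally
#' `e`) with the same shapes as the model's `A`, `B`, `D` (`E`) arrays. The
#' store accumulates evidence over trials; the normalized concentrations are
#' the agent's learned empirical priors.
#'
#' @param model An [aif_model()] supplying shapes and initial means.
#' @param scale_a,scale_b,scale_d,scale_e Prior strength multipliers: the
#'   initial concentrations are `scale * array`. Larger values make the
#'   corresponding array harder to move by new evidence.
#' @param learn_e Whether to allocate concentrations for the habit prior `E`
#'   (habit learning is off by default).
#' @return Object of class `dirichlet_store`.
#' @export
dirichlet_store <- function(model, scale_a = 1, scale_b = 1, scale_d = 1,
                            scale_e = 1, learn_e = FALSE) {
  stopifnot(scale_a > 0, scale_b > 0, scale_d > 0, scale_e > 0)
  structure(
    list(
      a = model$A * scale_a + 1e-3,
      b = model$B * scale_b + 1e-3,
      d = model$D * scale_d + 1e-3,
      e = if (learn_e) model$E * scale_e + 1e-3 else NULL
    ),
    class = "dirichlet_store"
  )
}

#' Accumulate one trial's evidence into a Dirichlet store
#'
#' Count-based evidence accumulation: for every observed timestep the
#' likelihood concentrations gain `rate * (outcome one-hot) %o% belief`; for
#' every taken action the transition concentrations for that action gain
#' `rate * belief(tau + 1) %o% belief(tau)`; the initial-state concentrations
#' gain `rate * belief(1)`; and, if habit learning is enabled, the habit
#' concentrations gain `rate * policy_post`.
#'
#' @param store A [dirichlet_store()].
#' @param beliefs `n_states x T` matrix of (typically policy-averaged) state
#'   beliefs for the completed trial.
#' @param observations Integer outcome indices (`NA` to skip a timestep).
#' @param actions Integer vector of taken actions (length `<= T - 1`);
#'   `actions[tau]` moved the state from `tau` to `tau + 1`.
#' @param learning_rate Positive evidence weight per count.
#' @param policy_post Optional policy posterior for habit learning.
#' @return The updated `dirichlet_store` (all entries stay positive).
#' @export
update_dirichlet <- function(store, beliefs, observations = integer(),
                             actions = integer(), learning_rate = 1,
                             policy_post = NULL) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be positive", call. = FALSE)
  }
  for (tau in seq_along(observations)) {
    o <- observations[tau]
    if (!is.na(o)) {
      store$a[o, ] <- store$a[o, ] + learning_rate * beliefs[, tau]
    }
  }
  for (tau in seq_along(actions)) {
    u <- actions[tau]
    store$b[, , u] <- store$b[, , u] +
      learning_rate * tcrossprod(beliefs[, tau + 1L], beliefs[, tau])
  }
  store$d <- store$d + learning_rate * beliefs[, 1]
  if (!is.null(store$e) && !is.null(policy_post)) {
    store$e <- store$e + learning_rate * policy_post
  }
  store
}

#' Expected model arrays under a Dirichlet store
#'
#' Each conditional distribution is the normalized concentration vector (the
#' Dirichlet mean), giving valid likelihood, transition, initial-prior and
#' (optionally) habit arrays.
#'
#' @param store A [dirichlet_store()].
#' @return List with `A`, `B`, `D` and, when habit learning is on, `E`.
#' @export
expected_model <- function(store) {
  B <- store$b
  for (u in seq_len(dim(B)[3])) B[, , u] <- norm_cols(B[, , u])
  out <- list(
    A = norm_cols(store$a),
    B = B,
    D = store$d / sum(store$d)
  )
  if (!is.null(store$e)) out$E <- store$e / sum(store$e)
  out
}
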