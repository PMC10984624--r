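#' Construct a single-level discrete active-inference generative model
#'
#' Bundles the arrays of a discrete partially observed Markov decision process
#' as used in active inference: the likelihood `A`, the action-conditioned
#' transitions `B`, log-preferences `C`, the initial-state prior `D`, the habit
#' prior over policies `E`, a policy set, the planning horizon and the prior
#' rate `beta0` of the policy precision `gamma = 1/beta`.
#'
#' @param A Likelihood matrix, `n_obs x n_states`; columns are conditional
#'   outcome distributions `P(o | s)` and must each sum to one.
#' @param B Transition array, `n_states x n_states x n_actions`; `B[, , u]`
#'   has columns `P(s' | s, u)`.
#' @param C Preference vector over outcomes in natural-log space (nats).
#'   Either a length-`n_obs` vector shared by all timesteps or an
#'   `n_obs x horizon` matrix with one column per timestep. No normalization
#'   is required; the risk term of the expected free energy normalizes
#'   internally.
#' @param D Initial-state prior, length `n_states`, summing to one.
#' @param E Habit prior over policies; defaults to uniform. Must match the
#'   number of policies.
#' @param policies Integer matrix, one row per policy, `horizon` columns of
#'   action indices. Defaults to exhaustive enumeration of all
#'   `n_actions^horizon` action sequences.
#' @param horizon Planning horizon `T >= 1`. Inferred from `policies` when
#'   those are supplied.
#' @param beta0 Positive prior rate of the policy precision (`gamma0 = 1/beta0`).
#' @param labels Optional list with character vectors `states`, `outcomes`,
#'   `actions` used for pretty printing and trajectory records.
#' @return An object of class `aif_model`.
#' @seealso [infer_states()], [compute_efe()], [policy_posterior()],
#'   [enumerate_policies()], [read_model_config()]
#' @export
aif_model <- function(A, B, C, D, E = NULL, policies = NULL, horizon = NULL,
                      beta0 = 1, labels = NULL) {
  A <- as.matrix(A)
  if (is.list(B)) B <- simplify2array(B)
  if (length(dim(B)) == 2L) B <- array(B, c(dim(B), 1L))
  n_s <- ncol(A)
  n_u <- dim(B)[3]
  if (is.null(policies)) {
    if (is.null(horizon)) horizon <- 1L
    policies <- enumerate_policies(n_u, horizon)
  } else {
    policies <- as.matrix(policies)
    storage.mode(policies) <- "integer"
    horizon <- ncol(policies)
  }
  if (is.null(dim(C))) C <- matrix(C, nrow = nrow(A), ncol = horizon)
  if (is.null(E)) E <- rep(1 / nrow(policies), nrow(policies))
  model <- structure(
    list(
      A = A, B = B, C = C, D = D, E = E,
      policies = policies, horizon = as.integer(horizon),
      beta0 = beta0, labels = labels,
      n_states = n_s, n_obs = nrow(A), n_actions = n_u,
      n_policies = nrow(policies)
    ),
    class = "aif_model"
  )
  validate_aif_model(model)
}

#' Validate the mutual consistency of an active-inference model
#'
#' Checks column stochasticity of `A`, `B` and validity of `D`, `E`, the
#' policy set and the horizon, with informative errors. Called by
#' [aif_model()] and by the configuration loader.
#'
#' @param model An `aif_model`.
#' @return `model`, invisibly extended with the per-state ambiguity vector `H`
#'   (Shannon entropy of each likelihood column).
#' @export
validate_aif_model <- function(model) {
  with(model, {
    for (s in seq_len(n_states)) {
      check_categorical(A[, s], what = sprintf("A column %d", s))
    }
    if (dim(B)[1] != n_states || dim(B)[2] != n_states) {
      stop("B must be n_states x n_states x n_actions", call. = FALSE)
    }
    for (u in seq_len(n_actions)) {
      for (s in seq_len(n_states)) {
        check_categorical(B[, s, u], what = sprintf("B[, %d, %d]", s, u))
      }
    }
    if (!all(is.finite(C))) stop("C must be finite (log-preferences)", call. = FALSE)
    if (nrow(C) != n_obs || ncol(C) != horizon) {
      stop("C must be n_obs x horizon", call. = FALSE)
    }
    check_categorical(D, what = "D")
    if (length(D) != n_states) stop("D length must equal n_states", call. = FALSE)
    check_categorical(E, what = "E")
    if (length(E) != n_policies) {
      stop("E length must equal the number of policies", call. = FALSE)
    }
    if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
    if (any(policies < 1L) || any(policies > n_actions)) {
      stop("policy action indices out of range", call. = FALSE)
    }
    if (!is.numeric(beta0) || beta0 <= 0) stop("beta0 must be positive", call. = FALSE)
  })
  model$H <- ambiguity_vector(model$A)
  invisible(model)
}

#' Per-state ambiguity of a likelihood matrix
#'
#' The ambiguity vector `H` has one entry per hidden state: the Shannon
#' entropy (nats) of that state's outcome distribution. It is the second term
#' of the expected free energy.
#'
#' @param A Likelihood matrix with column-stochastic entries.
#' @return Non-negative numeric vector of length `ncol(A)`.
#' @export
ambiguity_vector <- function(A) {
  -colSums(A * lnstab(A))
}

#' Enumerate all action sequences up to a planning horizon
#'
#' Builds the exhaustive policy set: every sequence of `horizon` action
#' indices from `1:n_actions`, one policy per row.
#'
#' @param n_actions Number of available actions (>= 1).
#' @param horizon Planning horizon (>= 1).
#' @return Integer matrix `n_actions^horizon x horizon`.
#' @export
#' @examples
#' enumerate_policies(2, 2)
enumerate_policies <- function(n_actions, horizon) {
  stopifnot(n_actions >= 1, horizon >= 1)
  grid <- do.call(expand.grid, rep(list(seq_len(n_actions)), horizon))
  m <- as.matrix(grid[, rev(seq_len(horizon)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Drop policies whose habit mass is negligible
#'
#' Optional pruning of the policy set: policies with habit prior below
#' `threshold` are removed and `E` renormalized.
#'
#' @param model An `aif_model`.
#' @param threshold Minimum habit mass to keep a policy.
#' @return The pruned `aif_model`.
#' @export
prune_policies <- function(model, threshold = 1e-6) {
  keep <- model$E >= threshold
  if (!any(keep)) stop("pruning removed every policy", call. = FALSE)
  model$policies <- model$policies[keep, , drop = FALSE]
  model$E <- model$E[keep] / sum(model$E[keep])
  model$n_policies <- sum(keep)
  model
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf(
    "<aif_model> %d states, %d outcomes, %d actions, horizon %d, %d policies, beta0 = %g\n",
    x$n_states, x$n_obs, x$n_actions, x$horizon, x$n_policies, x$beta0
  ))
  invisible(x)
}
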