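#' Fixed-point state inference under a policy
#'
#' Iterates the fixed-point update for per-timestep categorical state
#' beliefs under one policy. Each belief is the softmax of three messages: a
#' past message (`ln D` at `tau = 1`, otherwise the forward message through
#' `B[, , u]`), a future message through the transposed transition, and, at
#' observed timesteps, a present message `ln A[o, ]`. Timesteps without an
#' observation simply omit the present message. Updates are synchronous over
#' all timesteps with damping on the logit scale.
#'
#' The past and future messages are *cavity-corrected*: before a belief is
#' propagated to a neighbour, the information that arrived from that
#' neighbour is divided out. This makes the converged fixed point coincide
#' with the exact smoothing marginals of the chain (damped belief
#' propagation); in particular, with an uninformative likelihood the beliefs
#' are exactly the prior-propagated chain.
#'
#' @param model An [aif_model()].
#' @param policy Either an integer vector of `horizon` action indices or a
#'   single row index into `model$policies`.
#' @param observations Integer vector of outcome indices observed so far
#'   (length `<= horizon`); use `NA` for a skipped timestep.
#' @param tol Convergence tolerance on the maximum absolute belief change.
#' @param max_iter Maximum number of fixed-point sweeps; non-convergence is
#'   flagged in the result, not an error.
#' @param damping Step size in `(0, 1]` applied on the logit scale.
#' @return List with `beliefs` (`n_states x horizon` matrix of categorical
#'   beliefs), `converged` (logical) and `iterations`.
#' @export
infer_states <- function(model, policy, observations = integer(),
                         tol = 1e-4, max_iter = 64L, damping = 0.5) {
  actions <- resolve_policy(model, policy)
  T_ <- model$horizon
  n_s <- model$n_states
  n_obs_t <- length(observations)
  if (n_obs_t > T_) stop("more observations than timesteps", call. = FALSE)

  eps <- 1e-16
  lnA <- lnstab(model$A)
  lnD <- lnstab(model$D)

  # forward-propagated initialization; unit backward messages
  q <- matrix(0, n_s, T_)
  q[, 1] <- model$D
  if (T_ > 1L) {
    for (tau in 2:T_) q[, tau] <- model$B[, , actions[tau - 1L]] %*% q[, tau - 1L]
  }
  fwd <- q            # forward (past) message into each timestep
  bwd <- matrix(1, n_s, T_) # backward (future) message into each timestep

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    q_old <- q
    for (tau in seq_len(T_)) {
      if (tau == 1L) {
        msg_f <- lnD
        fwd[, 1] <- model$D
      } else {
        # remove the backward information from the neighbour before
        # propagating it forward (alpha-recursion cavity)
        cav <- q[, tau - 1L] / pmax(bwd[, tau - 1L], eps)
        f <- model$B[, , actions[tau - 1L]] %*% (cav / sum(cav))
        fwd[, tau] <- as.numeric(f)
        msg_f <- lnstab(fwd[, tau])
      }
      msg <- msg_f
      if (tau < T_) {
        # lambda-recursion cavity: q[tau+1] / fwd[tau+1] carries the
        # present-and-future evidence at tau + 1
        lam <- q[, tau + 1L] / pmax(fwd[, tau + 1L], eps)
        b <- as.numeric(crossprod(model$B[, , actions[tau]], lam))
        bwd[, tau] <- b / sum(b)
        msg <- msg + lnstab(bwd[, tau])
      }
      if (tau <= n_obs_t && !is.na(observations[tau])) {
        msg <- msg + lnA[observations[tau], ]
      }
      logit <- (1 - damping) * lnstab(q[, tau]) + damping * msg
      q[, tau] <- softmax(logit)
    }
    if (max(abs(q - q_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beliefs = q, converged = converged, iterations = it)
}

#' @noRd
resolve_policy <- function(model, policy) {
  if (length(policy) == 1L && model$horizon > 1L) {
    actions <- model$policies[policy, ]
  } else {
    actions <- as.integer(policy)
  }
  if (length(actions) != model$horizon) {
    stop("policy length must equal the horizon", call. = FALSE)
  }
  actions
}

#' Variational free energy of beliefs given observations under a policy
#'
#' Computes `F = E_Q[ln Q - ln P(s, o | policy)]`, reported with its
#' complexity / accuracy decomposition: complexity is the divergence of the
#' beliefs from the prior-propagated state chain under the policy, accuracy
#' the expected log-likelihood of the observed outcomes.
#'
#' `beliefs` may be either an `n_states x horizon` matrix of per-timestep
#' marginals, in which case `Q` is their product (the mean-field form the
#' engine uses), or a joint distribution over whole state sequences given as
#' `list(sequences = <n_seq x horizon integer matrix>, probs = <numeric>)`,
#' in which case the expectation is taken under that joint. Evaluated at the
#' exact joint posterior, the joint form equals minus the log evidence of the
#' observations under the policy.
#'
#' @inheritParams infer_states
#' @param beliefs Belief marginals matrix or joint sequence distribution (see
#'   Details).
#' @return List with `vfe`, `complexity` and `accuracy` (all in nats;
#'   `vfe = complexity - accuracy`).
#' @export
compute_vfe <- function(model, policy, beliefs, observations = integer()) {
  actions <- resolve_policy(model, policy)
  lnA <- lnstab(model$A)
  obs_idx <- which(!is.na(observations))

  if (is.list(beliefs)) {
    seqs <- beliefs$sequences
    p <- beliefs$probs
    check_categorical(p, what = "joint belief")
    ln_prior <- lnstab(model$D)[seqs[, 1]]
    if (model$horizon > 1L) {
      for (tau in 2:model$horizon) {
        ln_prior <- ln_prior + lnstab(model$B[, , actions[tau - 1L]])[
          cbind(seqs[, tau], seqs[, tau - 1L])
        ]
      }
    }
    ln_lik <- rep(0, length(p))
    for (tau in obs_idx) {
      ln_lik <- ln_lik + lnA[observations[tau], seqs[, tau]]
    }
    e_lnq <- sum(p * lnstab(p))
    complexity <- e_lnq - sum(p * ln_prior)
    accuracy <- sum(p * ln_lik)
  } else {
    q <- beliefs
    e_lnq <- sum(q * lnstab(q))
    e_lnp <- sum(q[, 1] * lnstab(model$D))
    if (model$horizon > 1L) {
      for (tau in 2:model$horizon) {
        e_lnp <- e_lnp +
          drop(crossprod(q[, tau], lnstab(model$B[, , actions[tau - 1L]]) %*% q[, tau - 1L]))
      }
    }
    accuracy <- 0
    for (tau in obs_idx) {
      accuracy <- accuracy + sum(q[, tau] * lnA[observations[tau], ])
    }
    complexity <- e_lnq - e_lnp
  }
  list(vfe = complexity - accuracy, complexity = complexity, accuracy = accuracy)
}

#' Expected free energy of a policy (risk + ambiguity form)
#'
#' For each evaluated timestep, predicted outcomes are `o = A %*% s` and
#' `G(tau) = o . (ln o - ln softmax(C[, tau])) + s . H`: risk (divergence of
#' predicted outcomes from preferences) plus ambiguity (expected outcome
#' entropy of the believed states). Preferences are normalized through a
#' log-softmax so that predicted outcomes exactly matching `softmax(C)` under
#' a deterministic likelihood give `G = 0`.
#'
#' @inheritParams infer_states
#' @param beliefs `n_states x horizon` matrix of state beliefs under the
#'   policy (e.g. from [infer_states()]).
#' @param timesteps Timesteps over which to evaluate `G`; defaults to all.
#'   In a receding-horizon loop, pass the not-yet-observed timesteps.
#' @return List with per-timestep vectors `efe`, `risk`, `ambiguity` (named
#'   by timestep) and their sum `total`.
#' @export
compute_efe <- function(model, policy, beliefs, timesteps = NULL) {
  if (is.null(timesteps)) timesteps <- seq_len(model$horizon)
  H <- model$H %||% ambiguity_vector(model$A)
  risk <- amb <- numeric(length(timesteps))
  for (i in seq_along(timesteps)) {
    tau <- timesteps[i]
    s <- beliefs[, tau]
    o_pred <- drop(model$A %*% s)
    lnC <- model$C[, tau] - logsumexp(model$C[, tau])
    risk[i] <- sum(o_pred * (lnstab(o_pred) - lnC))
    amb[i] <- sum(s * H)
  }
  names(risk) <- names(amb) <- timesteps
  list(efe = risk + amb, risk = risk, ambiguity = amb, total = sum(risk + amb))
}

#' Posterior over policies from habits, evidence and expected free energy
#'
#' Returns `softmax(ln E - F - gamma * G)`. Prior to any observation the
#' per-policy variational free energies `F` are zero, so passing
#' `vfe_per_policy = NULL` yields the observation-free prior over policies.
#'
#' @param model An [aif_model()] (supplies the habit prior `E`).
#' @param vfe_per_policy Numeric vector of per-policy variational free
#'   energies, or `NULL` for the pre-observation prior (`F = 0`).
#' @param efe_per_policy Numeric vector of per-policy expected free energies.
#' @param gamma Non-negative precision weighting `G`.
#' @return Categorical vector over policies.
#' @export
policy_posterior <- function(model, vfe_per_policy = NULL, efe_per_policy, gamma) {
  n <- model$n_policies
  if (is.null(vfe_per_policy)) vfe_per_policy <- rep(0, n)
  stopifnot(length(vfe_per_policy) == n, length(efe_per_policy) == n)
  softmax(lnstab(model$E) - vfe_per_policy - gamma * efe_per_policy)
}

#' Select an action from a posterior over policies
#'
#' Marginalizes the policy posterior onto the action each policy prescribes
#' at position `step`, then either samples from that marginal or takes its
#' maximum (ties broken toward the lowest action index).
#'
#' @param policy_post Categorical vector over policies.
#' @param policies Integer policy matrix (rows are policies).
#' @param step Position of the next action within each policy.
#' @param mode `"sample"` (draws from the action marginal using the current
#'   RNG state, or `seed` if given) or `"map"` (argmax).
#' @param seed Optional integer seed applied before sampling.
#' @return List with `action` (integer) and `marginal` (action probabilities).
#' @export
select_action <- function(policy_post, policies, step = 1L,
                          mode = c("sample", "map"), seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(policies) == 0L) stop("empty policy set", call. = FALSE)
  n_u <- max(policies)
  marginal <- vapply(
    seq_len(n_u),
    function(u) sum(policy_post[policies[, step] == u]),
    numeric(1)
  )
  marginal <- marginal / sum(marginal)
  action <- if (mode == "map") {
    which.max(marginal)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample.int(n_u, 1L, prob = marginal)
  }
  list(action = as.integer(action), marginal = marginal)
}

#' Policy-posterior Shannon entropy (nats)
#'
#' The package's operational measure of behavioural volatility: the entropy
#' of the belief over policies.
#'
#' @param policy_post Categorical vector over policies.
#' @return Non-negative scalar in nats.
#' @export
policy_entropy <- function(policy_post) {
  entropy_cat(policy_post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
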