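#' Run a hierarchical self-esteem agent in a social niche
#'
#' The closed loop of the simulator. Each trial the agent first scores every
#' policy prospectively — prior-predictive state beliefs, expected free
#' energy, and the pre-outcome policy prior (per-policy `F` is zero before
#' any observation) — then samples an action and receives the niche's
#' feedback to it. All policies are re-evaluated against the realized
#' feedback, giving the post-outcome policy posterior; the affective charge
#' of that belief shift updates the precision, and Dirichlet evidence
#' accumulates under beliefs consistent with the taken action. The posterior
#' over the post-action state is carried forward as the next trial's prior.
#' Every `slow_horizon` trials the block of trial summaries drives one trait
#' step.
#'
#' @param agent A [hierarchical_agent()].
#' @param niche A [niche_config()] (or the result of [make_scenario()]).
#' @param n_trials Number of trials to simulate (0 gives an empty run).
#' @param seed Optional integer seed; a fixed seed makes the whole
#'   trajectory bit-identical across runs.
#' @param forced_observations Optional integer vector of length `n_trials`;
#'   non-`NA` entries override the niche's feedback at that trial (used to
#'   deliver controlled shocks).
#' @return Object of class `esteem_run`: list with `trials` (tibble, one row
#'   per planning timestep of every trial), `trait_steps` (tibble), the
#'   final `agent`, the `niche` config, `seed` and `n_trials`.
#' @export
run_agent <- function(agent, niche, n_trials, seed = NULL,
                      forced_observations = NULL) {
  if (inherits(niche, "niche_config")) {
    nstate <- niche_init(niche)
  } else {
    nstate <- niche
    niche <- nstate$config
  }
  if (length(niche$approval_given_action) != length(agent$lower$model$labels$actions)) {
    stop("niche action alphabet does not match the agent's actions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(forced_observations)) forced_observations <- rep(NA_integer_, n_trials)

  lower <- agent$lower$model
  T_ <- lower$horizon
  n_pi <- lower$n_policies
  slow <- agent$upper$model$meta$spec$slow_horizon
  trait_names <- c("low", "medium", "high")

  rec <- vector("list", n_trials)
  trait_rec <- list()
  summaries <- integer(0)
  ac_block <- numeric(0)

  for (trial in seq_len(n_trials)) {
    M <- effective_lower_model(agent)
    gamma <- agent$lower$precision$gamma

    # policies sharing the action prefix that the transitions actually use
    # (actions 1..T-1) have identical beliefs; evaluate each group once
    prefix <- if (T_ > 1L) {
      apply(M$policies[, seq_len(T_ - 1L), drop = FALSE], 1, paste, collapse = ".")
    } else {
      rep("1", n_pi)
    }
    groups <- match(prefix, unique(prefix))
    n_g <- max(groups)
    G_pi <- numeric(n_pi)
    prior_g <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      p <- which(groups == g)[1]
      acts_p <- M$policies[p, ]
      # pre-outcome (prior-predictive) beliefs: forward-propagated chain
      q <- matrix(0, M$n_states, T_)
      q[, 1] <- M$D
      for (tau in seq_len(T_ - 1L)) {
        q[, tau + 1L] <- M$B[, , acts_p[tau]] %*% q[, tau]
      }
      prior_g[[g]] <- q
      G_pi[groups == g] <- compute_efe(M, acts_p, q,
                                       timesteps = setdiff(seq_len(T_), 1L))$total
    }

    # decide before the outcome: no observations yet this trial, so F = 0
    pi_pre <- policy_posterior(M, NULL, G_pi, gamma)
    sel <- select_action(pi_pre, M$policies, step = 1L, mode = agent$action_mode)
    action <- sel$action

    step <- niche_step(nstate, action)
    nstate <- step$state
    o <- if (!is.na(forced_observations[trial])) forced_observations[trial] else step$outcome
    obs_vec <- c(rep(NA_integer_, min(1L, T_ - 1L)), o)

    # post-outcome re-evaluation of every policy against the realized feedback
    F_pi <- numeric(n_pi)
    post_g <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      p <- which(groups == g)[1]
      inf <- infer_states(M, M$policies[p, ], observations = obs_vec)
      post_g[[g]] <- inf$beliefs
      F_pi[groups == g] <- compute_vfe(M, M$policies[p, ], inf$beliefs, obs_vec)$vfe
    }
    pi_post <- policy_posterior(M, F_pi, G_pi, gamma)
    ac <- affective_charge(pi_pre, pi_post, G_pi, deadband = agent$deadband)
    if (agent$carry_precision) {
      agent$lower$precision$beta0 <- agent$lower$precision$beta_post
    }
    agent$lower$precision <- update_precision(agent$lower$precision, ac)

    # beliefs consistent with the taken action, for learning and carry-over
    w_act <- pi_post * (M$policies[, 1] == action)
    q_act <- Reduce(`+`, lapply(seq_len(n_g), function(g) {
      post_g[[g]] * sum(w_act[groups == g])
    })) / sum(w_act)

    learn <- agent$learning$learn
    agent$lower$store <- update_dirichlet(
      agent$lower$store,
      beliefs = q_act,
      observations = if (learn[["a"]]) obs_vec else rep(NA_integer_, length(obs_vec)),
      actions = if (learn[["b"]] && T_ > 1L) action else integer(),
      learning_rate = agent$learning$rate,
      policy_post = if (learn[["e"]]) pi_post else NULL
    )
    if (!learn[["d"]]) {
      agent$lower$store$d <- agent$lower$store$d - agent$learning$rate * q_act[, 1]
    }
    obs_tau <- min(2L, T_)
    agent$lower$D_current <- q_act[, obs_tau]

    si <- self_image_marginal(lower, q_act[, obs_tau])
    summ <- summarize_trial(ac$value, si, deadband = agent$deadband)
    summaries <- c(summaries, summ$index)
    ac_block <- c(ac_block, ac$value)

    ent <- policy_entropy(pi_pre)
    vfe_mean <- sum(pi_post * F_pi)
    efe_sel <- G_pi[which.max(w_act)]
    efe_spread <- max(G_pi) - min(G_pi)
    ac_value <- ac$value
    ac_valence <- ac$valence
    rec[[trial]] <- tibble::tibble(
      trial = trial,
      tau = seq_len(T_),
      observation = `[<-`(rep(NA_integer_, T_), obs_tau, o),
      action = action,
      self_image_belief = lapply(seq_len(T_), function(tt) {
        self_image_marginal(lower, q_act[, tt])
      }),
      trait_map = trait_names[agent$trait_idx],
      ac = ac_value,
      valence = ac_valence,
      gamma = agent$lower$precision$gamma,
      policy_entropy = ent,
      vfe = vfe_mean,
      efe_selected = efe_sel,
      efe_spread = efe_spread,
      p_approval = step$p_approval
    )

    agent$clock[["trial"]] <- trial
    if (trial %% slow == 0L) {
      agent <- trait_step(agent, summaries)
      trait_rec[[length(trait_rec) + 1L]] <- tibble::tibble(
        step = agent$clock[["step"]],
        trial = trial,
        p_low = agent$trait_posterior[1],
        p_medium = agent$trait_posterior[2],
        p_high = agent$trait_posterior[3],
        trait_map = trait_names[agent$trait_idx],
        omega = agent$link$omega[[agent$trait_idx]],
        mean_ac = mean(ac_block)
      )
      summaries <- integer(0)
      ac_block <- numeric(0)
    }
  }

  structure(
    list(
      trials = if (n_trials > 0) dplyr::bind_rows(rec) else empty_trials(),
      trait_steps = if (length(trait_rec)) dplyr::bind_rows(trait_rec) else empty_trait_steps(),
      agent = agent,
      niche = niche,
      seed = seed,
      n_trials = n_trials
    ),
    class = "esteem_run"
  )
}

#' @noRd
empty_trials <- function() {
  tibble::tibble(
    trial = integer(), tau = integer(), observation = integer(),
    action = integer(), self_image_belief = list(), trait_map = character(),
    ac = numeric(), valence = character(), gamma = numeric(),
    policy_entropy = numeric(), vfe = numeric(), efe_selected = numeric(),
    efe_spread = numeric(), p_approval = numeric()
  )
}

#' @noRd
empty_trait_steps <- function() {
  tibble::tibble(
    step = integer(), trial = integer(), p_low = numeric(),
    p_medium = numeric(), p_high = numeric(), trait_map = character(),
    omega = numeric(), mean_ac = numeric()
  )
}

#' @export
print.esteem_run <- function(x, ...) {
  cat(sprintf(
    "<esteem_run> %d trials (%d records), %d trait steps, niche '%s'%s\n",
    x$n_trials, nrow(x$trials), nrow(x$trait_steps), x$niche$label,
    if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""
  ))
  if (x$n_trials > 0) {
    first <- dplyr::filter(x$trials, .data$tau == 1L)
    cat(sprintf(
      "  mean AC %.3f, mean gamma %.3f, mean policy entropy %.3f nats\n",
      mean(first$ac), mean(first$gamma), mean(first$policy_entropy)
    ))
  }
  invisible(x)
}
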