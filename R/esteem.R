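#' Specification of the fast (state-level) sociometer model
#'
#' The state level infers moment-to-moment self-esteem from social feedback.
#' Its hidden state combines an *ideal image* — by default three binary
#' factors (competence, social conformity, physical attractiveness, each
#' meets / falls short) — with a *self image* factor measuring alignment with
#' that ideal on `self_image_levels` levels (misaligned / partial / aligned
#' by default). Actions are engage / conform / withdraw; observations are
#' social feedback (approval / neutral / rejection); preferences favour
#' approval and strongly dispreference rejection.
#'
#' @param self_image_levels Number of alignment levels `K >= 2`.
#' @param collapse_ideal If `TRUE`, the three binary ideal factors are
#'   collapsed to a single 3-level factor (cheap-run configuration).
#' @param preferences Named log-preference values (nats) for the feedback
#'   outcomes.
#' @param feedback_levels 3 for approval / neutral / rejection, 2 for the
#'   binary approval / rejection reduction.
#' @return Object of class `state_level_spec`.
#' @export
state_level_spec <- function(self_image_levels = 3, collapse_ideal = FALSE,
                             preferences = c(approval = 2, neutral = 0, rejection = -3),
                             feedback_levels = 3) {
  stopifnot(self_image_levels >= 2, feedback_levels %in% c(2L, 3L))
  ideal_factors <- if (collapse_ideal) {
    list(ideal = c("low", "medium", "high"))
  } else {
    list(
      competence = c("falls_short", "meets"),
      social_conformity = c("falls_short", "meets"),
      physical_attractiveness = c("falls_short", "meets")
    )
  }
  feedback <- if (feedback_levels == 3L) {
    c("approval", "neutral", "rejection")
  } else {
    c("approval", "rejection")
  }
  structure(
    list(
      ideal_factors = ideal_factors,
      self_image_levels = as.integer(self_image_levels),
      collapse_ideal = collapse_ideal,
      actions = c("engage", "conform", "withdraw"),
      feedback = feedback,
      preferences = preferences
    ),
    class = "state_level_spec"
  )
}

#' Enumerate the joint hidden-state table of a state-level spec
#'
#' The engine works on a single flattened state variable; this helper gives
#' the bijection between joint indices and factor levels, plus the fraction
#' of ideal-image components currently met for each configuration.
#'
#' @param spec A [state_level_spec()].
#' @return Tibble with one row per joint state: factor levels, `self_image`,
#'   `frac_met` and the joint `state` index.
#' @export
state_table <- function(spec) {
  lv <- c(spec$ideal_factors, list(self_image = seq_len(spec$self_image_levels)))
  grid <- do.call(expand.grid, c(rev(lapply(lv, seq_along)),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  grid <- grid[, rev(seq_along(lv)), drop = FALSE]
  names(grid) <- names(lv)
  frac <- if (spec$collapse_ideal) {
    (grid$ideal - 1) / (length(spec$ideal_factors$ideal) - 1)
  } else {
    rowMeans(grid[, names(spec$ideal_factors), drop = FALSE] - 1)
  }
  tibble::as_tibble(grid) |>
    dplyr::mutate(frac_met = frac, state = dplyr::row_number())
}

#' Build the state-level generative model
#'
#' Constructs the flattened [aif_model()] for the sociometer's fast level.
#' The likelihood maps each self-image level to a modal feedback outcome
#' (aligned -> approval, misaligned -> rejection) with reliability `noise`:
#' each column is `w * onehot + (1 - w) * uniform` with `w = 2 * noise - 1`,
#' so `noise = 1` gives noiseless one-hot columns and `noise = 0.5` a fully
#' uninformative likelihood. Transitions leave the ideal image fixed and
#' drift the self image toward alignment under engagement (more effectively
#' the more ideal components are met), mildly under conformity, and away
#' from alignment under withdrawal. The initial prior is uniform.
#'
#' @param spec A [state_level_spec()].
#' @param noise Feedback reliability in `[0.5, 1]`.
#' @param horizon Planning horizon of the level (default 2).
#' @param beta0 Prior precision rate for policy selection.
#' @return An [aif_model()] carrying the spec and state table in `$meta`.
#' @export
build_state_level <- function(spec = state_level_spec(), noise = 0.9,
                              horizon = 2, beta0 = 1) {
  if (!is.numeric(noise) || noise < 0.5 || noise > 1) {
    stop("`noise` (feedback reliability) must lie in [0.5, 1]", call. = FALSE)
  }
  st <- state_table(spec)
  n_s <- nrow(st)
  n_o <- length(spec$feedback)
  K <- spec$self_image_levels

  # likelihood: modal outcome from self-image level, reliability blend
  w <- 2 * noise - 1
  A <- matrix((1 - w) / n_o, n_o, n_s)
  for (s in seq_len(n_s)) {
    k <- st$self_image[s]
    modal <- n_o - round((k - 1) * (n_o - 1) / (K - 1))
    A[modal, s] <- A[modal, s] + w
  }

  # transitions: block-diagonal over ideal configurations, self-image drift
  drift <- function(up, down) {
    m <- matrix(0, K, K)
    for (k in seq_len(K)) {
      pu <- if (k < K) up else 0
      pd <- if (k > 1) down else 0
      if (k < K) m[k + 1, k] <- pu
      if (k > 1) m[k - 1, k] <- pd
      m[k, k] <- 1 - pu - pd
    }
    m
  }
  ideal_configs <- unique(st[, setdiff(names(st), c("self_image", "frac_met", "state"))])
  n_cfg <- n_s / K
  B <- array(0, c(n_s, n_s, length(spec$actions)))
  for (cfg in seq_len(n_cfg)) {
    rows <- ((cfg - 1) * K + 1):(cfg * K)
    frac <- st$frac_met[rows[1]]
    kernels <- list(
      engage = drift(0.5 + 0.15 * frac, 0.10),
      conform = drift(0.2 + 0.15 * frac, 0.10),
      withdraw = drift(0.02, 0.55)
    )
    for (u in seq_along(spec$actions)) {
      B[rows, rows, u] <- kernels[[spec$actions[u]]]
    }
  }

  C <- spec$preferences[spec$feedback]
  state_labels <- apply(st[, seq_len(ncol(st) - 2L), drop = FALSE], 1, paste, collapse = "/")
  model <- aif_model(
    A = A, B = B, C = unname(C), D = rep(1 / n_s, n_s),
    horizon = horizon, beta0 = beta0,
    labels = list(states = state_labels, outcomes = spec$feedback,
                  actions = spec$actions)
  )
  model$meta <- list(spec = spec, state_table = st)
  model
}

#' Marginal belief over self-image alignment
#'
#' Sums a joint-state belief vector over the ideal-image factors, returning
#' the categorical belief over self-image levels.
#'
#' @param model A state-level model from [build_state_level()].
#' @param belief Joint-state probability vector.
#' @return Numeric vector of length `self_image_levels`.
#' @export
self_image_marginal <- function(model, belief) {
  k <- model$meta$state_table$self_image
  as.numeric(tapply(belief, k, sum))
}

#' Specification of the slow (trait-level) model
#'
#' The trait level observes discretized summaries of blocks of lower-level
#' trials — a dominant valence label and a self-image bin — and infers two
#' slow hidden factors: trait self-esteem (low / medium / high) and core
#' affective valence (negative / neutral / positive). It has no actions of
#' its own (perception and learning only).
#'
#' @param slow_horizon Number of lower-level trials per trait step (>= 1).
#' @param diag_dominance Initial likelihood mass on the matching observation
#'   bin (weakly informative; learned further by Dirichlet counts).
#' @param trait_sticky Self-transition probability of the trait factor.
#' @param valence_sticky Self-transition probability of the valence factor.
#' @return Object of class `trait_level_spec`.
#' @export
trait_level_spec <- function(slow_horizon = 10, diag_dominance = 0.6,
                             trait_sticky = 0.98, valence_sticky = 0.6) {
  stopifnot(slow_horizon >= 1, diag_dominance > 1 / 3, diag_dominance <= 1)
  structure(
    list(
      traits = c("low", "medium", "high"),
      valences = c("negative", "neutral", "positive"),
      slow_horizon = as.integer(slow_horizon),
      diag_dominance = diag_dominance,
      trait_sticky = trait_sticky,
      valence_sticky = valence_sticky
    ),
    class = "trait_level_spec"
  )
}

#' Build the trait-level generative model
#'
#' Joint hidden state is (trait, valence) with valence varying fastest; the
#' observation alphabet is the product of the valence label and the
#' self-image bin emitted by [summarize_trial()]. The likelihood factorizes:
#' the valence observation reports the valence state and the self-image bin
#' reports the trait state, each with `diag_dominance` mass on the matching
#' bin. Transitions are sticky and the model has a single no-op policy.
#'
#' @param spec A [trait_level_spec()].
#' @return An [aif_model()] with `$meta` carrying the factor maps.
#' @export
build_trait_level <- function(spec = trait_level_spec()) {
  n_t <- length(spec$traits)
  n_v <- length(spec$valences)
  n_s <- n_t * n_v
  conf <- function(n, diag) {
    m <- matrix((1 - diag) / (n - 1), n, n)
    diag(m) <- diag
    m
  }
  Pv <- conf(n_v, spec$diag_dominance) # valence obs | valence state
  Pb <- conf(n_t, spec$diag_dominance) # self-image bin obs | trait state
  trait_of <- rep(seq_len(n_t), each = n_v)
  val_of <- rep(seq_len(n_v), n_t)
  A <- matrix(0, n_v * n_t, n_s)
  for (s in seq_len(n_s)) {
    for (vo in seq_len(n_v)) {
      for (bo in seq_len(n_t)) {
        A[(vo - 1) * n_t + bo, s] <- Pv[vo, val_of[s]] * Pb[bo, trait_of[s]]
      }
    }
  }
  Tt <- conf(n_t, spec$trait_sticky)
  Tv <- conf(n_v, spec$valence_sticky)
  B <- array(Tt %x% Tv, c(n_s, n_s, 1L))
  model <- aif_model(
    A = A, B = B, C = rep(0, n_v * n_t), D = rep(1 / n_s, n_s),
    policies = matrix(1L, 1L, spec$slow_horizon),
    beta0 = 1,
    labels = list(
      states = paste(spec$traits[trait_of], spec$valences[val_of], sep = "/"),
      outcomes = paste(rep(spec$valences, each = n_t),
                       paste0("bin", seq_len(n_t)), sep = "/"),
      actions = "observe"
    )
  )
  model$meta <- list(spec = spec, trait_of = trait_of, valence_of = val_of)
  model
}

#' Trait link: how trait self-esteem modulates the fast level
#'
#' `omega` is the precision exponent applied to the lower-level transition
#' columns ([apply_trait_modulation()]): higher trait self-esteem means more
#' precise expectations about the consequences of one's actions. `gamma0`
#' maps the trait to the prior policy precision, and `e_tilt` optionally
#' reweights habits toward engagement (positive) or withdrawal (negative).
#'
#' @param omega Named positive numeric vector (`low < medium < high`).
#' @param gamma0 Named positive numeric vector of initial precisions.
#' @param e_tilt Optional named numeric vector of habit tilts (log-scale).
#' @param strict Enforce the strict ordering of `omega`; set `FALSE` only
#'   for ablations that deliberately flatten the trait channel.
#' @return Object of class `trait_link`.
#' @export
trait_link <- function(omega = c(low = 0.3, medium = 1, high = 3),
                       gamma0 = c(low = 1, medium = 1, high = 1),
                       e_tilt = NULL, strict = TRUE) {
  req <- c("low", "medium", "high")
  stopifnot(all(req %in% names(omega)), all(req %in% names(gamma0)))
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  if (strict &&
      !(omega[["high"]] > omega[["medium"]] && omega[["medium"]] > omega[["low"]])) {
    stop("omega must satisfy omega(high) > omega(medium) > omega(low)", call. = FALSE)
  }
  if (any(gamma0 <= 0)) stop("gamma0 must be positive", call. = FALSE)
  structure(list(omega = omega[req], gamma0 = gamma0[req], e_tilt = e_tilt),
            class = "trait_link")
}

#' Sharpen or flatten transition columns by a precision exponent
#'
#' Every column `c` of every transition table is replaced by
#' `normalize(c ^ omega)`. `omega = 1` is the identity; large `omega`
#' sharpens columns toward their argmax; `omega -> 0` flattens them toward
#' uniform. Column stochasticity is preserved exactly and the operation
#' commutes with any permutation of states.
#'
#' @param B Transition matrix or `n x n x n_actions` array.
#' @param omega Positive precision exponent.
#' @return Object of the same shape as `B`.
#' @export
#' @examples
#' apply_trait_modulation(matrix(c(0.8, 0.2, 0.3, 0.7), 2), omega = 2)
apply_trait_modulation <- function(B, omega) {
  stopifnot(is.numeric(omega), omega > 0)
  pow <- function(m) norm_cols(m^omega)
  if (length(dim(B)) == 3L) {
    for (u in seq_len(dim(B)[3])) B[, , u] <- pow(B[, , u])
    B
  } else {
    pow(B)
  }
}

#' Summarize one lower-level trial for the trait level
#'
#' Emits the trait level's observation for a completed trial: the dominant
#' valence label (sign of the trial's mean affective charge, with a
#' deadband) and the final self-image posterior binned by its highest-mass
#' level (ties toward the lowest bin).
#'
#' @param ac_values Numeric vector of affective charges logged in the trial.
#' @param self_image_posterior Categorical vector over self-image levels at
#'   the end of the trial.
#' @param n_bins Number of trait-alphabet bins (defaults to 3).
#' @param deadband Neutral band for the valence sign.
#' @return List with `valence` (1 = negative, 2 = neutral, 3 = positive),
#'   `bin`, and the flattened observation `index` for the trait model.
#' @export
summarize_trial <- function(ac_values, self_image_posterior, n_bins = 3,
                            deadband = 0) {
  lab <- valence_label(mean(ac_values), deadband)
  v <- match(lab, c("negative", "neutral", "positive"))
  K <- length(self_image_posterior)
  k <- which.max(self_image_posterior)
  bin <- if (K == n_bins) k else ceiling(k * n_bins / K)
  list(valence = v, bin = bin, index = (v - 1L) * n_bins + bin)
}

#' Construct a two-level self-esteem agent
#'
#' Couples a fast sociometer level (state self-esteem), a slow trait level
#' and the trait link into one hierarchical agent with Dirichlet stores and
#' a precision belief. The trait level's MAP trait sets the precision
#' exponent of the lower transitions, the prior policy precision and
#' (optionally) a habit tilt for the next block of trials.
#'
#' @param state_spec A [state_level_spec()].
#' @param trait_spec A [trait_level_spec()].
#' @param link A [trait_link()].
#' @param noise Feedback reliability of the lower likelihood.
#' @param horizon Lower-level planning horizon.
#' @param learning Named list of learning settings; see [learning_config()].
#' @param fixed_trait Optional `"low"` / `"medium"` / `"high"`: clamps the
#'   trait (no upper inference), for controlled comparisons.
#' @param initial_trait Trait whose modulation is in force before the first
#'   trait step.
#' @param carry_precision If `TRUE` the posterior rate `beta` persists
#'   between trials instead of relaxing to the trait-set prior rate.
#' @param deadband Valence deadband used for labelling and summaries.
#' @param action_mode `"sample"` or `"map"` action selection.
#' @return Object of class `hierarchical_agent`.
#' @export
hierarchical_agent <- function(state_spec = state_level_spec(),
                               trait_spec = trait_level_spec(),
                               link = trait_link(),
                               noise = 0.9, horizon = 2,
                               learning = learning_config(),
                               fixed_trait = NULL,
                               initial_trait = "medium",
                               carry_precision = FALSE,
                               deadband = 0,
                               action_mode = "sample") {
  lower_model <- build_state_level(state_spec, noise = noise, horizon = horizon)
  upper_model <- build_trait_level(trait_spec)
  trait0 <- fixed_trait %||% initial_trait
  trait_idx <- match(trait0, c("low", "medium", "high"))
  if (is.na(trait_idx)) stop("trait must be 'low', 'medium' or 'high'", call. = FALSE)
  agent <- structure(
    list(
      lower = list(
        model = lower_model,
        store = dirichlet_store(lower_model,
                                scale_a = learning$scale_a,
                                scale_b = learning$scale_b,
                                scale_d = learning$scale_d,
                                learn_e = learning$learn[["e"]]),
        precision = precision_belief(1 / link$gamma0[[trait_idx]]),
        D_current = lower_model$D
      ),
      upper = list(
        model = upper_model,
        store = dirichlet_store(upper_model,
                                scale_a = learning$upper_scale_a,
                                scale_b = 1,
                                scale_d = learning$upper_scale_d),
        D_current = upper_model$D,
        # slow empirical prior over the trait: Dirichlet-style counts that
        # accumulate one unit of (soft) evidence per trait step
        trait_counts = as.numeric(tapply(upper_model$D,
                                         upper_model$meta$trait_of, sum)) *
          learning$trait_prior_strength,
        valence_prior = rep(1 / 3, 3)
      ),
      link = link,
      learning = learning,
      fixed_trait = fixed_trait,
      trait_idx = trait_idx,
      trait_posterior = {
        p <- rep(1 / 3, 3)
        if (!is.null(fixed_trait)) {
          p <- c(0, 0, 0)
          p[trait_idx] <- 1
        }
        p
      },
      carry_precision = carry_precision,
      deadband = deadband,
      action_mode = action_mode,
      clock = c(trial = 0L, step = 0L)
    ),
    class = "hierarchical_agent"
  )
  agent
}

#' Learning settings of a hierarchical agent
#'
#' @param rate Positive Dirichlet learning rate per trial at the lower level.
#' @param scale_a,scale_b,scale_d Prior-strength multipliers of the lower
#'   Dirichlet store (larger = slower learning).
#' @param learn Named logical vector over `a`, `b`, `d`, `e`: which arrays
#'   accumulate evidence (habit learning `e` is off by default).
#' @param upper_rate Learning rate of the trait level.
#' @param upper_scale_a,upper_scale_d Prior strengths of the trait level.
#' @param trait_rate Units of soft evidence the trait counts gain per trait
#'   step (each step adds `trait_rate * block trait marginal`).
#' @param trait_prior_strength Initial total mass of the trait counts;
#'   larger values make trait self-esteem slower to form.
#' @return Named list of settings.
#' @export
learning_config <- function(rate = 1, scale_a = 10, scale_b = 20, scale_d = 2,
                            learn = c(a = TRUE, b = TRUE, d = TRUE, e = FALSE),
                            upper_rate = 1, upper_scale_a = 4, upper_scale_d = 2,
                            trait_rate = 1, trait_prior_strength = 3) {
  stopifnot(rate > 0, upper_rate > 0, trait_rate > 0, trait_prior_strength > 0)
  list(rate = rate, scale_a = scale_a, scale_b = scale_b, scale_d = scale_d,
       learn = learn, upper_rate = upper_rate,
       upper_scale_a = upper_scale_a, upper_scale_d = upper_scale_d,
       trait_rate = trait_rate, trait_prior_strength = trait_prior_strength)
}

#' Effective lower-level model under the current trait
#'
#' Applies the learning and the trait link to the base state-level model:
#' the likelihood and transitions are the Dirichlet means (where learning is
#' enabled), the transitions are sharpened or flattened by the MAP trait's
#' `omega`, the initial prior is the belief carried over from the previous
#' trial, and habits receive the optional trait tilt.
#'
#' @param agent A [hierarchical_agent()].
#' @return An [aif_model()] ready for one trial.
#' @export
effective_lower_model <- function(agent) {
  m <- agent$lower$model
  exp_arrays <- expected_model(agent$lower$store)
  if (agent$learning$learn[["a"]]) m$A <- exp_arrays$A
  B <- if (agent$learning$learn[["b"]]) exp_arrays$B else m$B
  omega <- agent$link$omega[[agent$trait_idx]]
  m$B <- apply_trait_modulation(B, omega)
  m$D <- agent$lower$D_current
  m$H <- ambiguity_vector(m$A)
  if (!is.null(agent$link$e_tilt)) {
    tilt <- agent$link$e_tilt[[agent$trait_idx]]
    eng <- which(m$labels$actions == "engage")
    wdr <- which(m$labels$actions == "withdraw")
    lnE <- lnstab(m$E) +
      tilt * (m$policies[, 1] == eng) - tilt * (m$policies[, 1] == wdr)
    m$E <- softmax(lnE)
  }
  m
}

#' One slow-timescale trait update
#'
#' Runs trait-level inference over a block of trial summaries under the
#' current slow trait prior, then accumulates the block's average trait
#' marginal into the trait's Dirichlet-style counts — the trait is a slowly
#' formed empirical prior built by soft evidence counting, so a long
#' favourable history is not overturned by one ambiguous block. The upper
#' likelihood also accumulates Dirichlet evidence, the valence marginal is
#' carried forward through its sticky transition, and the lower level's
#' effective precision parameters are re-derived from the MAP trait. With a
#' clamped trait (`fixed_trait`) only the clock advances.
#'
#' @param agent A [hierarchical_agent()].
#' @param summaries Integer vector of trait-level observation indices, one
#'   per lower-level trial of the block (length = slow horizon).
#' @return The updated agent.
#' @export
trait_step <- function(agent, summaries) {
  agent$clock[["step"]] <- agent$clock[["step"]] + 1L
  if (!is.null(agent$fixed_trait)) {
    return(agent)
  }
  um <- agent$upper$model
  if (length(summaries) != um$horizon) {
    stop("summaries length must equal the slow horizon", call. = FALSE)
  }
  trait_of <- um$meta$trait_of
  val_of <- um$meta$valence_of
  trait_prior <- agent$upper$trait_counts / sum(agent$upper$trait_counts)
  um$D <- trait_prior[trait_of] * agent$upper$valence_prior[val_of]
  um$D <- um$D / sum(um$D)
  um$A <- norm_cols(agent$upper$store$a)
  inf <- infer_states(um, 1L, observations = summaries)
  q <- inf$beliefs
  agent$upper$store <- update_dirichlet(
    agent$upper$store, q, observations = summaries,
    learning_rate = agent$learning$upper_rate
  )
  # soft conjugate counting: one block contributes at most trait_rate counts
  block_marg <- rowMeans(apply(q, 2, function(col) {
    as.numeric(tapply(col, trait_of, sum))
  }))
  agent$upper$trait_counts <- agent$upper$trait_counts +
    agent$learning$trait_rate * block_marg
  agent$trait_posterior <- agent$upper$trait_counts / sum(agent$upper$trait_counts)
  agent$trait_idx <- which.max(agent$trait_posterior)
  qT <- q[, um$horizon]
  val_marg <- as.numeric(tapply(qT, val_of, sum))
  Tv <- matrix((1 - um$meta$spec$valence_sticky) / 2, 3, 3)
  diag(Tv) <- um$meta$spec$valence_sticky
  agent$upper$valence_prior <- as.numeric(Tv %*% val_marg)
  agent$upper$D_current <- agent$trait_posterior[trait_of] *
    agent$upper$valence_prior[val_of]
  agent$upper$D_current <- agent$upper$D_current / sum(agent$upper$D_current)
  agent$lower$precision$beta0 <- 1 / agent$link$gamma0[[agent$trait_idx]]
  if (!agent$carry_precision) {
    agent$lower$precision <- update_precision(agent$lower$precision, 0)
  }
  agent
}

#' @export
print.hierarchical_agent <- function(x, ...) {
  cat(sprintf(
    "<hierarchical_agent> trial %d, trait step %d, trait = %s (P = %.2f/%.2f/%.2f), gamma = %.3g\n",
    x$clock[["trial"]], x$clock[["step"]],
    c("low", "medium", "high")[x$trait_idx],
    x$trait_posterior[1], x$trait_posterior[2], x$trait_posterior[3],
    x$lower$precision$gamma
  ))
  invisible(x)
}
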