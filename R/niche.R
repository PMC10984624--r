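#' Configure a synthetic social niche
#'
#' The niche is the package's data generator: a scripted social environment
#' that returns approval / neutral / rejection feedback conditional on the
#' agent's action. `approval_given_action` encodes how well each action
#' aligns with the niche's latent norm; the controllability `kappa` mixes
#' that action-dependent channel with an action-independent base rate, so the
#' probability of approval after action `u` is
#' `kappa * approval_given_action[u] + (1 - kappa) * base_rate`. The
#' remaining probability mass is split between rejection (a `rejection_share`
#' fraction) and neutral feedback. A regime schedule changes parameters at
#' stated trial indices.
#'
#' @param approval_given_action Named numeric vector in `[0, 1]`, one entry
#'   per action (names are action labels).
#' @param kappa Controllability in `[0, 1]`: 1 makes feedback fully
#'   action-dependent, 0 fully decouples feedback from action.
#' @param base_rate Approval probability under `kappa = 0`.
#' @param rejection_share Fraction of the non-approval mass that is
#'   rejection (the rest is neutral).
#' @param schedule List of regime shifts, each `list(trial =, overrides =)`;
#'   `overrides` is a named list of the fields above. A shift scheduled at
#'   trial `k` applies from trial `k` on. Trial indices must be strictly
#'   increasing.
#' @param label Optional scenario label.
#' @return Object of class `niche_config`.
#' @seealso [make_scenario()], [niche_init()], [niche_step()]
#' @export
niche_config <- function(approval_given_action, kappa = 1, base_rate = 0.5,
                         rejection_share = 0.7, schedule = list(),
                         label = "custom") {
  stopifnot(
    all(approval_given_action >= 0), all(approval_given_action <= 1),
    kappa >= 0, kappa <= 1,
    base_rate >= 0, base_rate <= 1,
    rejection_share >= 0, rejection_share <= 1
  )
  if (length(schedule)) {
    idx <- vapply(schedule, function(s) s$trial, numeric(1))
    if (any(diff(idx) <= 0)) {
      stop("schedule trial indices must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(
      approval_given_action = approval_given_action,
      kappa = kappa, base_rate = base_rate,
      rejection_share = rejection_share,
      schedule = schedule, label = label
    ),
    class = "niche_config"
  )
}

#' Named niche scenarios
#'
#' Fully specified niche configurations for the simulated conditions:
#' \describe{
#'   \item{favorable}{Controllable (`kappa = 1`), engagement reliably
#'     approved (0.9), withdrawal rarely (0.2).}
#'   \item{adverse}{Controllable but stingy: approval at most 0.35 even for
#'     engagement.}
#'   \item{uncontrollable}{`kappa = 0` with a low base rate — feedback is
#'     independent of action, the learned-helplessness probe.}
#'   \item{shifting}{Alternating high / low approval regimes at trials 101,
#'     201 and 301 (three scheduled changes).}
#'   \item{developmental}{Alternating high / low approval epochs of 50
#'     trials, emulating successive life stages.}
#' }
#'
#' @param name Scenario name (see Details).
#' @param overrides Named list of [niche_config()] fields to override.
#' @return A [niche_config()].
#' @export
#' @examples
#' make_scenario("favorable")
make_scenario <- function(name, overrides = list()) {
  acts <- c(engage = NA_real_, conform = NA_real_, withdraw = NA_real_)
  base <- switch(name,
    favorable = list(
      approval_given_action = c(engage = 0.9, conform = 0.6, withdraw = 0.2),
      kappa = 1, base_rate = 0.5
    ),
    adverse = list(
      approval_given_action = c(engage = 0.35, conform = 0.25, withdraw = 0.05),
      kappa = 1, base_rate = 0.2
    ),
    uncontrollable = list(
      approval_given_action = c(engage = 0.35, conform = 0.25, withdraw = 0.05),
      kappa = 0, base_rate = 0.2
    ),
    shifting = list(
      approval_given_action = c(engage = 0.85, conform = 0.85, withdraw = 0.85),
      kappa = 1, base_rate = 0.5,
      schedule = list(
        list(trial = 101, overrides = list(
          approval_given_action = c(engage = 0.15, conform = 0.15, withdraw = 0.15)
        )),
        list(trial = 201, overrides = list(
          approval_given_action = c(engage = 0.85, conform = 0.85, withdraw = 0.85)
        )),
        list(trial = 301, overrides = list(
          approval_given_action = c(engage = 0.15, conform = 0.15, withdraw = 0.15)
        ))
      )
    ),
    developmental = {
      high <- c(engage = 0.9, conform = 0.7, withdraw = 0.3)
      low <- c(engage = 0.2, conform = 0.15, withdraw = 0.05)
      sched <- lapply(seq_len(7), function(k) {
        list(
          trial = 50 * k + 1,
          overrides = list(
            approval_given_action = if (k %% 2 == 1) low else high
          )
        )
      })
      list(
        approval_given_action = high, kappa = 1, base_rate = 0.5,
        schedule = sched
      )
    },
    stop(sprintf(
      "unknown scenario '%s'; valid names: favorable, adverse, uncontrollable, shifting, developmental",
      name
    ), call. = FALSE)
  )
  cfg <- utils::modifyList(base, overrides)
  cfg$label <- name
  do.call(niche_config, cfg)
}

#' Initialize niche state from a configuration
#'
#' @param config A [niche_config()].
#' @return Object of class `niche_state` holding the live parameters and a
#'   trial counter.
#' @export
niche_init <- function(config) {
  structure(
    list(params = config, config = config, trial = 0L),
    class = "niche_state"
  )
}

#' Advance the niche by one trial and emit feedback
#'
#' Applies any regime shift scheduled for the new trial index, then draws
#' feedback for the given action: approval with probability
#' `kappa * approval_given_action[action] + (1 - kappa) * base_rate`,
#' rejection with `rejection_share` of the complementary mass, neutral with
#' the rest. Uses the current RNG state (seed upstream for reproducibility).
#'
#' @param state A `niche_state` from [niche_init()].
#' @param action Integer action index (into `approval_given_action`).
#' @return List with the advanced `state`, the feedback `outcome` (1 =
#'   approval, 2 = neutral, 3 = rejection) and the approval probability
#'   `p_approval` in force for this draw.
#' @export
niche_step <- function(state, action) {
  if (action < 1L || action > length(state$params$approval_given_action)) {
    stop("invalid action index for this niche", call. = FALSE)
  }
  state$trial <- state$trial + 1L
  for (shift in state$config$schedule) {
    if (shift$trial == state$trial) {
      state$params <- utils::modifyList(state$params, shift$overrides)
    }
  }
  p <- state$params
  p_app <- p$kappa * p$approval_given_action[[action]] + (1 - p$kappa) * p$base_rate
  probs <- c(
    approval = p_app,
    neutral = (1 - p_app) * (1 - p$rejection_share),
    rejection = (1 - p_app) * p$rejection_share
  )
  u <- stats::runif(1)
  outcome <- if (u < probs[1]) 1L else if (u < probs[1] + probs[2]) 2L else 3L
  list(state = state, outcome = outcome, p_approval = unname(p_app))
}

#' Sample a feedback stream from a niche for a fixed action sequence
#'
#' Convenience wrapper used for calibration checks and inspection: draws
#' `length(actions)` feedback outcomes and returns them as a tibble.
#'
#' @param config A [niche_config()].
#' @param actions Integer vector of actions, one per trial.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `trial`, `action`, `outcome`, `outcome_label`,
#'   `p_approval`.
#' @export
niche_stream <- function(config, actions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- niche_init(config)
  out <- integer(length(actions))
  p_app <- numeric(length(actions))
  for (i in seq_along(actions)) {
    step <- niche_step(state, actions[i])
    state <- step$state
    out[i] <- step$outcome
    p_app[i] <- step$p_approval
  }
  tibble::tibble(
    trial = seq_along(actions),
    action = actions,
    outcome = out,
    outcome_label = c("approval", "neutral", "rejection")[out],
    p_approval = p_app
  )
}

#' @export
print.niche_config <- function(x, ...) {
  cat(sprintf(
    "<niche_config> '%s': kappa = %g, base_rate = %g, approval(%s), %d scheduled shift(s)\n",
    x$label, x$kappa, x$base_rate,
    paste(sprintf("%s = %g", names(x$approval_given_action), x$approval_given_action),
          collapse = ", "),
    length(x$schedule)
  ))
  invisible(x)
}
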