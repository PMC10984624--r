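#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run into one row per trial
#'
#' Returns the observed-timestep rows of the trajectory with the self-image
#' belief unpacked into `self_image_*` columns — one row per trial, ready
#' for dplyr/ggplot2 pipelines.
#'
#' @param x An `esteem_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.esteem_run <- function(x, ...) {
  fr <- dplyr::filter(x$trials, .data$tau == 1L)
  if (nrow(fr) == 0) {
    return(dplyr::select(fr, -"self_image_belief", -"tau"))
  }
  K <- length(fr$self_image_belief[[1]])
  beliefs <- do.call(rbind, fr$self_image_belief)
  colnames(beliefs) <- paste0("self_image_", seq_len(K))
  dplyr::bind_cols(
    dplyr::select(fr, -"self_image_belief", -"tau"),
    tibble::as_tibble(beliefs)
  )
}

#' One-row summary of a run
#'
#' @param x An `esteem_run`.
#' @param ... Unused.
#' @return A one-row tibble: trial count, action frequencies, mean affective
#'   charge, precision, policy entropy and the final trait posterior.
#' @export
glance.esteem_run <- function(x, ...) {
  fr <- dplyr::filter(x$trials, .data$tau == 1L)
  final_trait <- if (nrow(x$trait_steps)) {
    dplyr::slice_tail(x$trait_steps, n = 1)
  } else {
    tibble::tibble(p_low = NA_real_, p_medium = NA_real_, p_high = NA_real_)
  }
  tibble::tibble(
    n_trials = x$n_trials,
    engage_freq = mean(fr$action == 1L),
    withdraw_freq = mean(fr$action == 3L),
    mean_ac = mean(fr$ac),
    mean_gamma = mean(fr$gamma),
    mean_policy_entropy = mean(fr$policy_entropy),
    p_low = final_trait$p_low,
    p_medium = final_trait$p_medium,
    p_high = final_trait$p_high
  )
}

#' Tidy an experiment into its per-seed metric table
#'
#' @param x An `esteem_experiment`.
#' @param ... Unused.
#' @return The per-seed, per-arm metrics tibble.
#' @export
tidy.esteem_experiment <- function(x, ...) {
  x$metrics
}

#' One-row summary of an experiment
#'
#' @param x An `esteem_experiment`.
#' @param ... Unused.
#' @return Tibble with the experiment name, config digest, seed count, and
#'   the number of passing / total checks.
#' @export
glance.esteem_experiment <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    config_digest = x$config_digest,
    n_seeds = length(x$seeds),
    n_checks = nrow(x$checks),
    n_pass = sum(x$checks$pass),
    degenerate = x$degenerate
  )
}

#' Trajectory plot of a run
#'
#' Four stacked panels over trials: affective charge (coloured by valence),
#' policy precision `gamma`, the belief that the self image is aligned, and
#' policy-posterior entropy.
#'
#' @param object An `esteem_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esteem_run <- function(object, ...) {
  td <- tidy(object)
  K <- sum(startsWith(names(td), "self_image_"))
  td$aligned <- td[[paste0("self_image_", K)]]
  long <- tidyr::pivot_longer(
    dplyr::select(td, "trial", "ac", "gamma", "aligned", "policy_entropy"),
    -"trial", names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(
    long$quantity,
    levels = c("ac", "gamma", "aligned", "policy_entropy"),
    labels = c("affective charge (nats)", "precision gamma",
               "P(self image aligned)", "policy entropy (nats)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.7, colour = "#2166ac", span = 0.2) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' Metric plot of an experiment
#'
#' Boxplots of the experiment's per-seed metrics by arm.
#'
#' @param object An `esteem_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esteem_experiment <- function(object, ...) {
  m <- object$metrics
  if (nrow(m) == 0) stop("degenerate experiment: nothing to plot", call. = FALSE)
  group <- intersect(c("arm", "trait"), names(m))[1]
  long <- tidyr::pivot_longer(
    m, -dplyr::any_of(c("seed", "arm", "trait")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = object$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Trait-posterior plot of a run
#'
#' @param run An `esteem_run` with at least one trait step.
#' @return A ggplot object showing the trait posterior over trait steps.
#' @export
plot_trait_posterior <- function(run) {
  ts <- run$trait_steps
  if (nrow(ts) == 0) stop("run has no trait steps", call. = FALSE)
  long <- tidyr::pivot_longer(ts, c("p_low", "p_medium", "p_high"),
                              names_to = "trait", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$probability,
                                     colour = .data$trait)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      p_low = "#b2182b", p_medium = "grey50", p_high = "#2166ac"
    )) +
    ggplot2::labs(x = "trial", y = "trait posterior") +
    ggplot2::theme_minimal()
}
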