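test_that("state-level likelihood reflects the reliability parameterization", {
  spec <- state_level_spec(collapse_ideal = TRUE)
  m1 <- build_state_level(spec, noise = 1)
  expect_true(all(apply(m1$A, 2, max) > 1 - 1e-12))
  expect_equal(max(abs(m1$H)), 0, tolerance = 1e-12)
  # binary feedback reduction at reliability 0.5: uniform columns, H = ln 2
  m5 <- build_state_level(state_level_spec(collapse_ideal = TRUE,
                                           feedback_levels = 2,
                                           preferences = c(approval = 2, rejection = -3)),
                          noise = 0.5)
  expect_equal(m5$A, matrix(0.5, 2, ncol(m5$A)), tolerance = 1e-12)
  expect_equal(unname(m5$H), rep(log(2), ncol(m5$A)), tolerance = 1e-12)
  expect_error(build_state_level(spec, noise = 0.4), "reliability")
  expect_error(build_state_level(spec, noise = 1.1), "reliability")
})

test_that("generated models pass the engine validators in both factorizations", {
  for (collapse in c(TRUE, FALSE)) {
    m <- build_state_level(state_level_spec(collapse_ideal = collapse), noise = 0.9)
    expect_silent(validate_aif_model(m))
    expect_equal(m$n_states, if (collapse) 9L else 24L)
    expect_equal(m$n_actions, 3L)
    # flattening is bijective
    st <- state_table(m$meta$spec)
    expect_equal(nrow(st), m$n_states)
    expect_equal(anyDuplicated(st[, -ncol(st)]), 0L)
  }
})

test_that("trait modulation sharpens, flattens, and preserves stochasticity", {
  b <- matrix(c(0.8, 0.2, 0.3, 0.7), 2)
  expect_equal(apply_trait_modulation(b, 1), b, tolerance = 1e-12)
  m2 <- apply_trait_modulation(b, 2)
  expect_equal(m2[, 1], c(0.64, 0.04) / 0.68, tolerance = 1e-12)
  m0 <- apply_trait_modulation(b, 1e-3)
  expect_lt(max(abs(m0 - 0.5)), 5e-4)
  # exact column stochasticity on random arrays, and permutation equivariance
  set.seed(8)
  for (i in 1:20) {
    B <- array(0, c(4, 4, 2))
    for (u in 1:2) B[, , u] <- rand_cols(4, 4)
    om <- runif(1, 0.1, 4)
    mod <- apply_trait_modulation(B, om)
    expect_lt(max(abs(apply(mod, c(2, 3), sum) - 1)), 1e-12)
    perm <- sample(4)
    direct <- apply_trait_modulation(B[perm, perm, , drop = FALSE], om)
    expect_equal(direct, mod[perm, perm, , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("trait link validates the precision ordering", {
  expect_error(trait_link(omega = c(low = 2, medium = 1, high = 3)), "omega")
  expect_error(trait_link(omega = c(low = -1, medium = 1, high = 2)), "positive")
  flat <- trait_link(omega = c(low = 1, medium = 1, high = 1), strict = FALSE)
  expect_equal(unname(flat$omega), rep(1, 3))
})

test_that("trial summaries discretize valence and self-image correctly", {
  expect_equal(summarize_trial(c(0.2, 0.3), c(0.1, 0.2, 0.7))$valence, 3L)
  expect_equal(summarize_trial(c(-0.5, 0.5), c(0.1, 0.2, 0.7))$valence, 2L)
  s <- summarize_trial(-0.4, c(0.1, 0.2, 0.7))
  expect_equal(s$valence, 1L)
  expect_equal(s$bin, 3L)
  expect_equal(s$index, 3L)
  expect_equal(summarize_trial(0.5, c(0.7, 0.2, 0.1))$index, 2L * 3L + 1L)
})

test_that("trait step follows degenerate, symmetric and conjugate evidence", {
  link <- trait_link()
  # degenerate prior: one-hot on high with a near-noiseless upper likelihood
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE),
                           trait_spec = trait_level_spec(slow_horizon = 4,
                                                         diag_dominance = 0.95))
  ag$upper$trait_counts <- c(0, 0, 3) # degenerate prior on high
  ag2 <- trait_step(ag, rep(9L, 4)) # positive valence, top bin
  expect_equal(ag2$trait_idx, 3L)
  expect_equal(ag2$link$omega[[ag2$trait_idx]], link$omega[["high"]])

  # alternating positive/negative summaries: no systematic trait drift
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE),
                           trait_spec = trait_level_spec(slow_horizon = 10))
  prior_trait <- as.numeric(tapply(ag$upper$D_current,
                                   ag$upper$model$meta$trait_of, sum))
  alternating <- rep(c(3L, 7L), 5) # (neg, bin3), (pos, bin1)
  ag3 <- trait_step(ag, alternating)
  expect_lt(max(abs(ag3$trait_posterior - prior_trait)), 0.1)

  # sustained positive top-bin evidence pushes mass from low toward high
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE),
                           trait_spec = trait_level_spec(slow_horizon = 10))
  for (i in 1:5) ag <- trait_step(ag, rep(9L, 10))
  expect_gt(ag$trait_posterior[3], ag$trait_posterior[1])
  expect_error(trait_step(ag, rep(9L, 3)), "slow horizon")
})

test_that("the run loop respects its structural contracts", {
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE))
  r0 <- run_agent(ag, make_scenario("favorable"), 0, seed = 1)
  expect_equal(nrow(r0$trials), 0L)
  expect_equal(r0$agent$clock[["trial"]], 0L)

  r1 <- run_agent(ag, make_scenario("favorable"), 30, seed = 4)
  r2 <- run_agent(ag, make_scenario("favorable"), 30, seed = 4)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$trait_steps, r2$trait_steps)

  # nesting conservation: trials = slow horizon x trait steps
  expect_equal(nrow(r1$trait_steps),
               30 %/% ag$upper$model$meta$spec$slow_horizon)
  # every recorded belief is a valid categorical
  for (b in r1$trials$self_image_belief) expect_categorical(b, tol = 1e-8)
  # alphabet mismatch is refused at construction
  bad <- niche_config(c(a = 0.5, b = 0.5))
  expect_error(run_agent(ag, bad, 5), "alphabet")
})

test_that("agents seek preferred feedback when engagement earns approval", {
  nc <- niche_config(c(engage = 0.9, conform = 0.5, withdraw = 0.1), kappa = 1)
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE),
                           fixed_trait = "medium")
  run <- run_agent(ag, nc, 300, seed = 2)
  fr <- dplyr::filter(run$trials, tau == 1, trial > 100)
  expect_gt(mean(fr$action == 1L), mean(fr$action == 3L))
})

test_that("trait posterior persists through a short ambiguous spell (hysteresis)", {
  nc <- niche_config(c(engage = 0.9, conform = 0.7, withdraw = 0.3), kappa = 1,
                     schedule = list(list(trial = 301, overrides = list(
                       approval_given_action = c(engage = 0.5, conform = 0.5,
                                                 withdraw = 0.5)
                     ))))
  ag <- hierarchical_agent(state_spec = state_level_spec(collapse_ideal = TRUE))
  run <- run_agent(ag, nc, 350, seed = 3)
  final <- dplyr::slice_tail(run$trait_steps, n = 1)
  expect_gt(final$p_high, 1 / 3) # still above the time-zero uniform prior
})
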