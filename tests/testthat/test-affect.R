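test_that("affective charge identities: no shift, constant G, hand computation", {
  expect_equal(affective_charge(c(0.3, 0.7), c(0.3, 0.7), c(1, 5))$value, 0)
  expect_equal(affective_charge(c(0.9, 0.1), c(0.1, 0.9), c(2, 2))$value, 0,
               tolerance = 1e-12)
  ac <- affective_charge(c(0.5, 0.5), c(0.9, 0.1), c(1, 3))
  expect_equal(ac$value, 0.8, tolerance = 1e-12)
  expect_equal(ac$valence, "positive")
})

test_that("affective charge is antisymmetric in prior and posterior", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    p <- softmax(rnorm(n)); q <- softmax(rnorm(n)); G <- rnorm(n)
    expect_equal(affective_charge(p, q, G)$value,
                 -affective_charge(q, p, G)$value, tolerance = 1e-12)
  }
})

test_that("positive charge exactly when the posterior expects lower G", {
  set.seed(6)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    p <- softmax(rnorm(n)); q <- softmax(rnorm(n)); G <- rnorm(n, sd = 2)
    ac <- affective_charge(p, q, G)$value
    expect_equal(ac > 0, sum(q * G) < sum(p * G))
  }
})

test_that("precision updates follow beta_post = max(beta0 - AC, beta_min)", {
  b <- precision_belief(beta0 = 1)
  expect_equal(update_precision(b, 0)$gamma, 1)
  up <- update_precision(b, 0.5)
  expect_equal(up$beta_post, 0.5)
  expect_equal(up$gamma, 2)
  # clamp engages even for AC = beta0 and beyond
  cl <- update_precision(b, 1)
  expect_equal(cl$beta_post, b$beta_min)
  expect_equal(cl$gamma, 1 / b$beta_min)
  expect_equal(update_precision(b, 5)$beta_post, b$beta_min)
})

test_that("gamma is strictly monotone in the affective charge before the clamp", {
  b <- precision_belief(beta0 = 1, beta_min = 0.05)
  acs <- seq(-2, 0.9, by = 0.05)
  gammas <- vapply(acs, function(a) update_precision(b, a)$gamma, numeric(1))
  expect_true(all(diff(gammas) > 0))
  # internal consistency gamma = 1/beta_post
  for (a in c(-1, 0, 0.5)) {
    up <- update_precision(b, a)
    expect_lt(abs(up$gamma - 1 / up$beta_post), 1e-12)
  }
})

test_that("valence labels respect the deadband", {
  expect_equal(valence_label(0, 0.01), "neutral")
  expect_equal(valence_label(0.5, 0.01), "positive")
  expect_equal(valence_label(-0.5, 0.01), "negative")
  expect_equal(valence_label(0.005, 0.01), "neutral")
  expect_error(valence_label(0, -1))
})

test_that("richer observation streams yield higher mean affective charge", {
  # closed engine+affect loop with fixed parameters (no evidence
  # accumulation, so expectations cannot adapt to the stream): each trial
  # forms the pre-outcome policy prior, receives a stream outcome, and
  # re-scores the policies against it
  m <- build_state_level(state_level_spec(collapse_ideal = TRUE), noise = 0.9)
  mean_ac <- function(p_app, sd) {
    set.seed(sd)
    acs <- vapply(1:100, function(i) {
      G <- F_ <- numeric(m$n_policies)
      for (p in seq_len(m$n_policies)) {
        acts <- m$policies[p, ]
        q <- cbind(m$D, m$B[, , acts[1]] %*% m$D)
        G[p] <- compute_efe(m, acts, q, timesteps = 2)$total
      }
      o <- sample(3L, 1, prob = c(p_app, 0.3 * (1 - p_app), 0.7 * (1 - p_app)))
      for (p in seq_len(m$n_policies)) {
        inf <- infer_states(m, m$policies[p, ], c(NA, o))
        F_[p] <- compute_vfe(m, m$policies[p, ], inf$beliefs, c(NA, o))$vfe
      }
      pre <- policy_posterior(m, NULL, G, gamma = 1)
      post <- policy_posterior(m, F_, G, gamma = 1)
      affective_charge(pre, post, G)$value
    }, numeric(1))
    mean(acs)
  }
  seeds <- 1:6
  rich <- vapply(seeds, function(sd) mean_ac(0.9, sd), numeric(1))
  poor <- vapply(seeds, function(sd) mean_ac(0.2, sd), numeric(1))
  expect_true(all(rich > poor))
  expect_lt(stats::wilcox.test(rich, poor, alternative = "greater")$p.value, 0.05)
})
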