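test_that("state inference recovers the state under a noiseless likelihood", {
  # identity A, uniform transitions: the observation pins the state exactly
  B <- array(0.5, c(2, 2, 1))
  m <- aif_model(A = diag(2), B = B, C = c(0, 0), D = c(0.5, 0.5), horizon = 1)
  inf <- infer_states(m, 1L, observations = 2L)
  expect_equal(inf$beliefs[, 1], c(0, 1), tolerance = 1e-6)
  expect_true(inf$converged)
})

test_that("an uninformative likelihood leaves the prior-propagated chain", {
  set.seed(3)
  B <- array(0, c(3, 3, 1))
  B[, , 1] <- rand_cols(3, 3)
  D <- as.numeric(rand_cols(3, 1))
  m <- aif_model(A = matrix(1 / 2, 2, 3), B = B, C = c(0, 0), D = D, horizon = 3)
  inf <- infer_states(m, 1L, observations = c(1L, 2L, 1L))
  chain <- cbind(D, B[, , 1] %*% D, B[, , 1] %*% B[, , 1] %*% D)
  expect_equal(unname(inf$beliefs), unname(chain), tolerance = 1e-3)
})

test_that("deterministic models reproduce the true state sequence exactly", {
  # deterministic A and B, observation at every timestep
  perm <- matrix(0, 3, 3)
  perm[cbind(c(2, 3, 1), 1:3)] <- 1 # s -> s + 1 (mod 3)
  m <- aif_model(A = diag(3), B = array(perm, c(3, 3, 1)),
                 C = rep(0, 3), D = c(1, 0, 0), horizon = 3)
  inf <- infer_states(m, 1L, observations = c(1L, 2L, 3L))
  expect_equal(apply(inf$beliefs, 2, which.max), c(1L, 2L, 3L))
  expect_true(all(apply(inf$beliefs, 2, max) > 0.999))
})

test_that("fixed-point marginals agree with exhaustive enumeration", {
  set.seed(11)
  for (i in 1:40) {
    T_ <- sample(2:3, 1)
    m <- rand_model(2, 2, 2, horizon = T_)
    n_obs <- sample(1:T_, 1)
    obs <- sample(1:2, n_obs, replace = TRUE)
    pol <- sample(m$n_policies, 1)
    inf <- infer_states(m, pol, obs)
    oracle <- enum_posterior(m, pol, obs)
    tv <- apply(abs(inf$beliefs - oracle$marginals), 2, sum) / 2
    expect_true(all(tv <= 0.05))
  }
})

test_that("variational free energy at the exact joint posterior is -log evidence", {
  set.seed(12)
  for (i in 1:25) {
    m <- rand_model(2, 2, 2, horizon = sample(2:3, 1))
    obs <- sample(1:2, m$horizon, replace = TRUE)
    pol <- sample(m$n_policies, 1)
    oracle <- enum_posterior(m, pol, obs)
    v <- compute_vfe(m, pol,
                     list(sequences = oracle$sequences, probs = oracle$probs),
                     obs)
    expect_equal(v$vfe, -log(oracle$evidence), tolerance = 1e-8)
  }
})

test_that("free energy is zero when prior, likelihood and beliefs all agree", {
  m <- aif_model(A = diag(2), B = array(diag(2), c(2, 2, 1)),
                 C = c(0, 0), D = c(1, 0), horizon = 2)
  beliefs <- cbind(c(1, 0), c(1, 0))
  v <- compute_vfe(m, 1L, beliefs, observations = c(1L, 1L))
  expect_equal(v$vfe, 0, tolerance = 1e-9)
  expect_equal(v$complexity, 0, tolerance = 1e-9)
})

test_that("uniform likelihood over K outcomes costs ln K per observation", {
  for (K in 2:4) {
    m <- aif_model(A = matrix(1 / K, K, 2), B = array(0.5, c(2, 2, 1)),
                   C = rep(0, K), D = c(0.5, 0.5), horizon = 1)
    v <- compute_vfe(m, 1L, matrix(c(0.5, 0.5), 2, 1), observations = 1L)
    expect_equal(v$vfe, log(K), tolerance = 1e-9)
  }
})

test_that("expected free energy vanishes for a preference-matched deterministic model", {
  # deterministic likelihood (H = 0) and predicted outcomes equal to softmax(C)
  A <- rbind(c(1, 0), c(0, 1))
  s <- c(0.3, 0.7)
  m <- aif_model(A = A, B = array(diag(2), c(2, 2, 1)),
                 C = log(s), D = s, horizon = 1)
  g <- compute_efe(m, 1L, matrix(s, 2, 1))
  expect_equal(g$total, 0, tolerance = 1e-12)
  expect_equal(unname(g$ambiguity), 0, tolerance = 1e-12)
})

test_that("uniform likelihood gives ambiguity ln K regardless of beliefs", {
  for (K in 2:4) {
    m <- aif_model(A = matrix(1 / K, K, 3), B = array(1 / 3, c(3, 3, 1)),
                   C = rep(0, K), D = rep(1 / 3, 3), horizon = 1)
    for (b in list(c(1, 0, 0), c(0.2, 0.5, 0.3))) {
      g <- compute_efe(m, 1L, matrix(b, 3, 1))
      expect_equal(unname(g$ambiguity), log(K), tolerance = 1e-9)
    }
  }
})

test_that("risk + ambiguity agrees with the direct-expectation double sum", {
  set.seed(13)
  for (i in 1:50) {
    m <- rand_model(sample(2:3, 1), sample(2:3, 1), 1, horizon = 2)
    beliefs <- rand_cols(m$n_states, 2)
    g <- compute_efe(m, c(1L, 1L), beliefs)
    for (tau in 1:2) {
      expect_equal(unname(g$efe[tau]), efe_direct_tau(m, beliefs[, tau], tau),
                   tolerance = 1e-8)
    }
  }
})

test_that("policy posterior limits: habit-only, symmetry, and hand computation", {
  B <- array(0.5, c(2, 2, 3))
  m <- aif_model(A = diag(2), B = B, C = c(0, 0), D = c(0.5, 0.5),
                 E = c(0.5, 0.25, 0.25), horizon = 1)
  # gamma = 0 and F = 0 return the habit prior bit-for-bit
  expect_equal(policy_posterior(m, NULL, c(1, 2, 3), gamma = 0),
               c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # equal G, equal F, uniform E -> uniform
  mu <- aif_model(A = diag(2), B = B, C = c(0, 0), D = c(0.5, 0.5), horizon = 1)
  expect_equal(policy_posterior(mu, rep(2, 3), rep(5, 3), gamma = 1.7),
               rep(1 / 3, 3), tolerance = 1e-12)
  # direct exp-normalization oracle
  got <- policy_posterior(m, rep(0, 3), c(1, 2, 3), gamma = 1)
  want <- exp(log(c(0.5, 0.25, 0.25)) - c(1, 2, 3))
  expect_equal(got, want / sum(want), tolerance = 1e-9)
})

test_that("action selection marginalizes policies and respects ties and seeds", {
  pols <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L))
  # one-hot posterior picks that policy's first action in both modes
  expect_equal(select_action(c(0, 0, 1), pols, mode = "map")$action, 2L)
  expect_equal(select_action(c(0, 0, 1), pols, mode = "sample", seed = 1)$action, 2L)
  # policies sharing the first action concentrate the marginal on it
  expect_equal(select_action(c(0.6, 0.4, 0), pols, mode = "sample", seed = 1)$marginal,
               c(1, 0))
  # argmax ties resolve to the lowest index
  expect_equal(select_action(c(0.5, 0, 0.5), pols, mode = "map")$action, 1L)
})

test_that("sampled actions converge to the policy-marginal frequencies", {
  pols <- rbind(c(1L, 1L), c(2L, 1L))
  post <- c(0.7, 0.3)
  set.seed(99)
  draws <- replicate(10000, select_action(post, pols, mode = "sample")$action)
  expect_lt(abs(mean(draws == 1L) - 0.7), 0.02)
})

test_that("policy enumeration is exhaustive and pruning renormalizes habits", {
  pols <- enumerate_policies(3, 2)
  expect_equal(nrow(pols), 9L)
  expect_equal(nrow(unique(pols)), 9L)
  B <- array(1 / 2, c(2, 2, 2))
  m <- aif_model(A = diag(2), B = B, C = c(0, 0), D = c(0.5, 0.5),
                 E = c(0.5, 0.5 - 1e-9, 1e-9, 0.5e-9) / sum(c(0.5, 0.5 - 1e-9, 1e-9, 0.5e-9)),
                 policies = enumerate_policies(2, 2))
  pruned <- prune_policies(m, 1e-6)
  expect_equal(pruned$n_policies, 2L)
  expect_equal(sum(pruned$E), 1)
})
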