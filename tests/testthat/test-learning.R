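toy_model <- function() {
  set.seed(7)
  rand_model(2, 2, 2, horizon = 2)
}

test_that("one-hot evidence at rate 1 adds exactly one count per visited cell", {
  m <- toy_model()
  store <- dirichlet_store(m)
  beliefs <- cbind(c(1, 0), c(0, 1))
  upd <- update_dirichlet(store, beliefs, observations = c(2L, 1L),
                          actions = 1L, learning_rate = 1)
  expect_equal(upd$a - store$a,
               rbind(c(0, 1), c(1, 0)))
  db <- upd$b - store$b
  expect_equal(db[2, 1, 1], 1)
  expect_equal(sum(db), 1)
  expect_equal(upd$d - store$d, c(1, 0))
})

test_that("learning rate must be positive and scales counts linearly", {
  m <- toy_model()
  store <- dirichlet_store(m)
  beliefs <- cbind(c(1, 0), c(0, 1))
  expect_error(update_dirichlet(store, beliefs, 1L, 1L, learning_rate = 0),
               "positive")
  full <- update_dirichlet(store, beliefs, c(1L, NA), 1L, learning_rate = 1)
  half <- update_dirichlet(store, beliefs, c(1L, NA), 1L, learning_rate = 0.5)
  expect_equal(half$a - store$a, (full$a - store$a) / 2)
  expect_equal(half$d - store$d, (full$d - store$d) / 2)
})

test_that("repeated identical trials drive the mean transition to the empirical frequency", {
  m <- toy_model()
  store <- dirichlet_store(m, scale_b = 1)
  beliefs <- cbind(c(1, 0), c(0, 1)) # deterministic 1 -> 2 under action 1
  N <- 200
  for (i in seq_len(N)) {
    store <- update_dirichlet(store, beliefs, observations = c(NA, NA), actions = 1L)
  }
  freq <- expected_model(store)$B[, 1, 1]
  expect_lt(abs(freq[2] - 1), 1 / N + 0.05) # prior mass washes out at rate 1/N
  expect_true(all(store$b > 0))
})

test_that("expected model normalizes concentrations to valid distributions", {
  m <- toy_model()
  store <- dirichlet_store(m)
  store$a[] <- 1
  store$b[] <- 1
  store$d[] <- 1
  em <- expected_model(store)
  expect_equal(em$A, matrix(0.5, 2, 2))
  expect_equal(em$D, c(0.5, 0.5))
  store$d <- c(9, 1)
  expect_equal(expected_model(store)$D, c(0.9, 0.1))
})

test_that("one-hot evidence moves the expected model toward it monotonically", {
  m <- toy_model()
  store <- dirichlet_store(m)
  beliefs <- cbind(c(1, 0), c(1, 0))
  p_prev <- expected_model(store)$A[1, 1]
  for (n in 1:100) {
    store <- update_dirichlet(store, beliefs, observations = c(1L, NA))
    p <- expected_model(store)$A[1, 1]
    expect_gt(p, p_prev)
    p_prev <- p
  }
  expect_gt(p_prev, 0.9)
})

test_that("habit concentrations accumulate only when enabled", {
  m <- toy_model()
  s0 <- dirichlet_store(m)
  expect_null(s0$e)
  s1 <- dirichlet_store(m, learn_e = TRUE)
  upd <- update_dirichlet(s1, cbind(c(1, 0), c(0, 1)), c(1L, NA), 1L,
                          policy_post = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(upd$e - s1$e, rep(0.25, 4))
})

test_that("expected frequencies converge to the generative process", {
  # simulate a known chain with true states observed one-hot; the learned
  # means must approach the true A, B, D
  set.seed(21)
  true <- rand_model(2, 2, 2, horizon = 4)
  store <- dirichlet_store(true, scale_a = 1e-6, scale_b = 1e-6, scale_d = 1e-6)
  for (trial in 1:500) {
    s <- integer(4)
    s[1] <- sample(2, 1, prob = true$D)
    u <- sample(2, 3, replace = TRUE)
    for (tau in 2:4) s[tau] <- sample(2, 1, prob = true$B[, s[tau - 1], u[tau - 1]])
    o <- vapply(s, function(si) sample(2, 1, prob = true$A[, si]), integer(1))
    beliefs <- sapply(s, function(si) tabulate(si, 2))
    store <- update_dirichlet(store, beliefs, o, u)
  }
  em <- expected_model(store)
  expect_lt(max(abs(em$A - true$A)), 0.05)
  expect_lt(max(abs(em$B - true$B)), 0.05)
  expect_lt(max(abs(em$D - true$D)), 0.05)
})
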