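test_that("deterministic approval when fully controllable and certain", {
  nc <- niche_config(c(engage = 1, conform = 0.5, withdraw = 0), kappa = 1)
  st <- niche_init(nc)
  set.seed(1)
  for (i in 1:50) {
    step <- niche_step(st, 1L)
    st <- step$state
    expect_equal(step$outcome, 1L)
  }
})

test_that("zero controllability decouples feedback from action", {
  nc <- niche_config(c(engage = 0.9, conform = 0.5, withdraw = 0.1),
                     kappa = 0, base_rate = 0.4)
  freqs <- sapply(1:3, function(a) {
    stream <- niche_stream(nc, rep(a, 10000), seed = a)
    mean(stream$outcome == 1L)
  })
  expect_lt(max(freqs) - min(freqs), 0.02)
  expect_lt(abs(mean(freqs) - 0.4), 0.02)
})

test_that("approval probability is the kappa mixture of action and base channels", {
  nc <- niche_config(c(engage = 0.8), kappa = 0.5, base_rate = 0.2)
  stream <- niche_stream(nc, rep(1L, 10000), seed = 2)
  expect_equal(stream$p_approval[1], 0.5)
  expect_lt(abs(mean(stream$outcome == 1L) - 0.5), 0.02)
})

test_that("non-approval mass splits between rejection and neutral as configured", {
  nc <- niche_config(c(engage = 0.4), kappa = 1, rejection_share = 0.7)
  stream <- niche_stream(nc, rep(1L, 20000), seed = 3)
  expect_lt(abs(mean(stream$outcome == 3L) - 0.6 * 0.7), 0.02)
  expect_lt(abs(mean(stream$outcome == 2L) - 0.6 * 0.3), 0.02)
})

test_that("named scenarios have their documented structure", {
  fav <- make_scenario("favorable")
  expect_gte(fav$approval_given_action[["engage"]], 0.8)
  expect_equal(fav$kappa, 1)
  expect_equal(make_scenario("uncontrollable")$kappa, 0)
  expect_gte(length(make_scenario("shifting")$schedule), 2)
  dev <- make_scenario("developmental")
  expect_gte(length(dev$schedule), 2)
  expect_error(make_scenario("nope"), "favorable")
  ov <- make_scenario("favorable", list(kappa = 0.3))
  expect_equal(ov$kappa, 0.3)
})

test_that("regime shifts apply at exactly the scheduled trial index", {
  nc <- niche_config(c(engage = 1), kappa = 1,
                     schedule = list(list(trial = 5, overrides = list(
                       approval_given_action = c(engage = 0)
                     ))))
  stream <- niche_stream(nc, rep(1L, 10), seed = 4)
  expect_equal(stream$p_approval, c(rep(1, 4), rep(0, 6)))
  expect_error(
    niche_config(c(engage = 1), schedule = list(
      list(trial = 5, overrides = list()), list(trial = 5, overrides = list())
    )),
    "strictly increasing"
  )
})

test_that("feedback streams are reproducible bit-for-bit under a fixed seed", {
  nc <- make_scenario("shifting")
  a <- niche_stream(nc, rep(1:3, 100), seed = 9)
  b <- niche_stream(nc, rep(1:3, 100), seed = 9)
  expect_identical(a, b)
})

test_that("emitted frequencies converge to configured probabilities per scenario", {
  for (name in c("favorable", "adverse", "uncontrollable")) {
    nc <- make_scenario(name)
    stream <- niche_stream(nc, rep(1L, 10000), seed = 5)
    p <- stream$p_approval[1]
    expect_lt(abs(mean(stream$outcome == 1L) - p), 0.02)
  }
})
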