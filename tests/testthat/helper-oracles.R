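# Independent oracles used across the suite. These deliberately avoid the
# package's own inference code paths: posteriors and evidence come from
# exhaustive enumeration of state sequences, and the expected free energy
# oracle is a literal term-by-term double sum.

# random column-stochastic conditional table with entries bounded away from 0
rand_cols <- function(nrow, ncol) {
  m <- matrix(stats::runif(nrow * ncol, 0.1, 1), nrow, ncol)
  sweep(m, 2, colSums(m), "/")
}

# random discrete active-inference model (uses the current RNG state)
rand_model <- function(n_s = 2, n_o = 2, n_u = 2, horizon = 2) {
  B <- array(0, c(n_s, n_s, n_u))
  for (u in seq_len(n_u)) B[, , u] <- rand_cols(n_s, n_s)
  aif_model(
    A = rand_cols(n_o, n_s),
    B = B,
    C = stats::rnorm(n_o),
    D = as.numeric(rand_cols(n_s, 1)),
    horizon = horizon
  )
}

# exhaustive enumeration of P(s_{1:T}, o | policy): exact evidence, joint
# posterior over sequences and per-timestep marginals
enum_posterior <- function(model, policy, observations) {
  T_ <- model$horizon
  acts <- if (length(policy) == 1L && T_ > 1L) model$policies[policy, ] else policy
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(model$n_states)), T_)))
  dimnames(seqs) <- NULL
  p <- apply(seqs, 1, function(s) {
    pr <- model$D[s[1]]
    if (T_ > 1L) {
      for (tau in 2:T_) pr <- pr * model$B[s[tau], s[tau - 1L], acts[tau - 1L]]
    }
    for (tau in seq_along(observations)) {
      if (!is.na(observations[tau])) pr <- pr * model$A[observations[tau], s[tau]]
    }
    pr
  })
  evidence <- sum(p)
  post <- p / evidence
  marginals <- sapply(seq_len(T_), function(tau) {
    as.numeric(tapply(post, seqs[, tau], sum))
  })
  list(sequences = seqs, probs = post, evidence = evidence,
       marginals = matrix(marginals, nrow = model$n_states))
}

# direct-expectation form of the expected free energy at one timestep:
# G = sum_{s,o} q(s) A[o,s] * (ln o_pred(o) - ln A[o,s] - ln softmax(C)(o))
efe_direct_tau <- function(model, s_belief, tau) {
  o_pred <- as.numeric(model$A %*% s_belief)
  lnC <- model$C[, tau] - log(sum(exp(model$C[, tau])))
  total <- 0
  for (s in seq_len(model$n_states)) {
    for (o in seq_len(model$n_obs)) {
      total <- total + s_belief[s] * model$A[o, s] *
        (log(o_pred[o] + 1e-16) - log(model$A[o, s] + 1e-16) - lnC[o])
    }
  }
  total
}

expect_categorical <- function(p, tol = 1e-10) {
  testthat::expect_true(all(p >= -tol))
  testthat::expect_lt(abs(sum(p) - 1), tol)
}
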