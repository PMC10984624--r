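---
title: "The sociometer model: active-inference dynamics of self-esteem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sociometer model: active-inference dynamics of self-esteem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sociometer)
```

## The model in one paragraph

Sociometer theory reads self-esteem as an internal gauge of one's standing in
a social group: an inferential quantity, updated by approval and rejection,
that both reflects and regulates behaviour. This package implements that
reading as a discrete-state active-inference agent. A *fast* level infers,
trial by trial, how well the agent's self-image aligns with an ideal image
(competence, social conformity, physical attractiveness) from social
feedback, and selects actions — engage, conform, withdraw — by minimizing
expected free energy. A *slow* level accumulates block-wise summaries of
those trials into trait self-esteem and a core valence state, and the trait
feeds back by setting the precision of the fast level's expectations. A
scripted social niche supplies feedback with configurable approval
statistics, controllability and regime shifts, so every claim the package
makes is testable without human data.

## The engine

The fast level is a partially observed Markov decision process with the
standard active-inference arrays: likelihood $A$ with $P(o \mid s)$ in its
columns, action-conditioned transitions $B_u$, log-preferences $C$ over
outcomes, initial prior $D$, and a habit prior $E$ over the policy set
(exhaustive enumeration of action sequences over the planning horizon,
default $T = 2$).

**Perception.** Beliefs about states under a policy are per-timestep
categoricals updated by a damped synchronous fixed-point iteration: each
belief is the softmax of a past message, a future message and (at observed
timesteps) the log-likelihood of the outcome. The two transition messages
are *cavity-corrected*: information that arrived from a neighbour is divided
out before a belief is propagated back to it. The converged fixed point then
coincides with the exact smoothing marginals of the chain — with an
uninformative likelihood the beliefs are exactly the prior-propagated chain,
and on enumerable models the marginals match exhaustive enumeration to
iteration tolerance. Numerical knobs: damping 0.5 on the logit scale,
tolerance $10^{-4}$ on beliefs, at most 64 sweeps; non-convergence is
flagged, not fatal. All logarithms are computed as $\ln(x + 10^{-16})$, so
structural zeros stay finite.

**Evaluation.** The variational free energy of beliefs is complexity
(divergence from the prior-propagated chain) minus accuracy (expected
log-likelihood of what was observed). Evaluated at a *joint* posterior over
state sequences, it equals minus the log evidence; the engine's per-policy
$F$ uses the product of the per-timestep marginals. The expected free energy
of a policy at a future timestep is risk plus ambiguity,
$G = \mathbf{o} \cdot (\ln \mathbf{o} - \ln \sigma(C)) + \mathbf{s} \cdot H$,
with $\mathbf{o} = A\mathbf{s}$ the predicted outcomes and $H$ the per-state
outcome entropy. Preferences are stored unnormalized in log space and
normalized by a log-softmax inside the risk term, so predictions that
exactly match $\sigma(C)$ under a noiseless likelihood give $G = 0$.

**Action.** Policies are scored by $\sigma(\ln E - F - \gamma G)$. Before
any observation in a decision cycle $F = 0$, which gives the pre-outcome
policy prior; the executed action is sampled from the prior's first-action
marginal (argmax ties resolve to the lowest index, and every stochastic draw
is seeded by the caller).

**Learning.** Dirichlet concentrations shadow $A$, $B$, $D$ (and optionally
$E$): each trial adds (outcome $\otimes$ belief) to $a$, (belief$_{\tau+1}$
$\otimes$ belief$_\tau$) for the taken action to $b$, and the initial belief
to $d$, all scaled by a learning rate. The expected model is the normalized
concentration mean — plain evidence counting. Habit learning exists but is
off by default, since nothing in the model's derivation requires $E$ to be
learned.

## Affective charge and precision

Each decision cycle compares the pre-outcome policy prior $\pi_0$ with the
post-outcome posterior $\bar\pi$ re-scored against the realized feedback,
and computes the affective charge
$\mathrm{AC} = (\pi_0 - \bar\pi) \cdot G$: positive exactly when the outcome
shifted belief toward policies with below-average expected free energy —
good news about one's grip on the niche. The charge updates the policy
precision through its rate, $\bar\beta = \max(\beta_0 - \mathrm{AC},
\beta_{\min})$, $\bar\gamma = 1/\bar\beta$, with $\beta_{\min} = 0.05$
keeping $\gamma$ finite. By default the update is a one-shot assignment from
the trait-set prior rate each cycle, so affect is a fast transient on a
slowly trait-regulated baseline; a `carry_precision` flag lets $\bar\beta$
persist instead. We chose non-persistence as the default because a persistent
rate drifts monotonically to the clamp in any niche whose mean charge is
nonzero, saturating $\gamma$ and masking the trait channel.

A property worth knowing about: in the *fixed-parameter* engine+affect loop,
a stream richer in preferred outcomes yields a higher mean charge, as the
sign semantics require. In the *fully adaptive* agent the comparison can
reverse — once learning and belief carry-over adapt expectations to a poor
niche, rare approvals produce large positive charges while expected
rejections produce small negative ones. That is hedonic adaptation emerging
from the formalism, and it is why the stream-valence property is tested with
learning disabled.

## The two-level self-esteem model

**Fast level.** The hidden state is the product of the ideal image — three
binary factors (meets / falls short), collapsible to one 3-level factor for
cheap runs — and a 3-level self-image (misaligned / partial / aligned).
Feedback is approval / neutral / rejection. Each self-image level maps to a
modal outcome (aligned to approval, misaligned to rejection); the likelihood
column is $w \cdot \text{onehot} + (1 - w)/m$ with $w = 2\rho - 1$, so
reliability $\rho = 1$ is noiseless and $\rho = 0.5$ exactly uninformative
for any outcome alphabet. Actions move the self-image: engagement drifts it
toward alignment (up-move probability $0.5 + 0.15\,f$, where $f$ is the
fraction of ideal components met), conformity improves it mildly and safely,
withdrawal lets it decay (down-move 0.55). Engagement is deliberately
*movement-dominant* in every ideal configuration: precision modulation
sharpens each column toward its mode, so a stay-dominant kernel would make
high trait self-esteem homogenize the actions instead of differentiating
them. Preferences are $(+2, 0, -3)$ nats for approval, neutral, rejection —
rejection strongly dispreferred, which is where avoidance pressure comes
from. Between trials the posterior over the post-action state is carried
forward as the next prior (Bayesian filtering); without that carry-over the
sociometer could not track anything across trials.

**Trait level.** Every `slow_horizon` (default 10) trials, each trial is
summarized by its dominant valence label (sign of the trial's affective
charge, with a deadband) and the self-image posterior's highest-mass bin.
The slow level infers trait self-esteem (low / medium / high) and valence
(negative / neutral / positive) from those summaries: the valence
observation reports the valence state and the bin observation the trait
state, each with a weakly informative 0.6 diagonal that is itself learned by
Dirichlet counts. The level has no actions — it is a perception-and-learning
level, which is the natural reading of a layer whose job is to set priors
for the level below.

**Trait persistence.** The block posterior is absorbed into the trait by
Dirichlet-style *soft counting*: each block adds at most one unit of
evidence (its average trait marginal) to the trait counts, and the
normalized counts are the next block's trait prior. We first implemented
multiplicative filtering and found that a single 10-observation block
carries a likelihood ratio of order $3^{10}$ — enough to overturn 300 trials
of history, which contradicts the trait-as-attractor picture the hierarchy
is meant to capture. Counting makes evidence additive: after thirty
favourable blocks, five ambiguous ones barely move the trait. This is also
what gives the developmental experiments their primacy structure (early
epochs matter more than late ones, because early counts are added to a small
denominator).

**The trait link.** The MAP trait sets, for the next block: the precision
exponent $\omega$ applied column-wise to the fast transitions
($c \mapsto c^\omega / \|c^\omega\|_1$; identity at 1, sharpening above,
flattening below), the prior policy precision $\gamma_0 = 1/\beta_0$, and an
optional habit tilt toward engagement. Defaults: $\omega = (0.3, 1, 3)$ for
low / medium / high, $\gamma_0$ equal at 1, tilt off. The $\omega$ spacing
was chosen so that the volatility separation between adjacent trait levels
clears seed-to-seed noise at the default run length; $\gamma_0$ is equal
across traits so that the equal-$\omega$ ablation genuinely removes the
trait channel (any $\gamma_0$ ordering would leave a volatility ordering in
place and make the ablation uninterpretable).

## The synthetic niche

The niche is a scripted feedback generator, not an inferring agent: the
group's generative model is represented only through its feedback
statistics. Approval after action $u$ has probability
$\kappa \cdot p_u + (1 - \kappa) \cdot b$: `approval_given_action` $p_u$
encodes each action's alignment with the latent norm, controllability
$\kappa$ mixes in an action-independent base rate $b$, and $\kappa = 0$ is
the uncontrollable condition used to probe learned helplessness. The
non-approval mass splits 0.7 / 0.3 between rejection and neutral. A regime
schedule applies parameter overrides from stated trial indices, exactly at
the index. Named scenarios (`favorable`, `adverse`, `uncontrollable`,
`shifting`, `developmental`) fix these numbers and are documented in
`make_scenario()`.

What the niche emulates: action-contingent social evaluation with adjustable
contingency and non-stationarity. What it does not emulate: other inferring
agents, observation of others' behaviour, social comparison as a separate
modality, or any group dynamics. Passing tests therefore show that the
*agent architecture* produces the claimed phenomena under controlled
feedback statistics — not that those phenomena are calibrated to human data.

## What the experiments show — and one honest reversal

Each experiment reports per-seed metrics and labels every check as a
*direction* check (a qualitative prediction of the model) or a *threshold*
check (a simulation-chosen magnitude). Default sizes — 400 trials, slow
horizon 10, 20 seeds, with the collapsed ideal factor — keep each experiment
within a few minutes on one CPU; sign-consistency across seeds is reported
instead of p-values.

- **Volatility** (`exp_volatility`): mean policy-prior entropy orders low >
  medium > high trait, and the equal-$\omega$ ablation collapses the arms to
  bit-identical runs.
- **Tracking** (`exp_sociometer_tracking`): the windowed alignment belief
  correlates with the niche's true approval rate above 0.9 at reliability
  0.9 and near 0 at reliability 0.5 (likelihood learning disabled in these
  arms — see above).
- **Helplessness** (`exp_helplessness`): with $\kappa = 0$, engagement in
  the final third drops below the controllable arm, and the spread of
  expected free energy across policies shrinks as the non-contingency is
  learned.
- **Development** (`exp_trait_development`): favourable-early agents end
  with trait mass on high, adverse-early agents on low; occasional seeds
  flip — an agent that samples withdrawal early can talk itself into low
  self-esteem inside a favourable niche, which is the self-organizing story,
  and why the check is a median.
- **Anxiety buffering** (`exp_anxiety_buffer`): the model predicts — and we
  report — the *reverse* of the verbal expectation that high trait
  self-esteem damps the affective response to a rejection shock. The charge
  is $(\pi_0 - \bar\pi)\cdot G$, a mass-shift weighted by the spread of $G$,
  and the trait's precision exponent is precisely what creates that spread;
  so the high-trait agent, whose confident predictions a shock violates,
  registers the *larger* negative charge. Buffering does emerge if the trait
  instead (or additionally) raises $\gamma_0$, because $\gamma$ sharpens the
  policy prior without scaling the evidence term — an extreme prior simply
  has less mass to move. But a trait-ordered $\gamma_0$ would also produce a
  volatility ordering that survives the equal-$\omega$ ablation, so the two
  phenomena cannot both be carried by the defaults. We keep the B-precision
  reading, report the buffering check's honest failure, and flag the
  $\gamma_0$ route as the mechanism a buffering-first variant should use.
  The remaining checks in that experiment (no systematic charge without a
  shock; later shocks displace the accumulated trait less) behave as
  predicted.

## Degenerate inputs, ties, tolerances

Empty logit vectors, non-stochastic columns, inconsistent shapes,
out-of-range reliability and non-positive learning rates are rejected with
informative errors. Argmax ties (action selection, summary binning) resolve
to the lowest index. Categorical sums are enforced to $10^{-10}$; the
precision rate clamps at 0.05; run serialization round-trips numerics at
full precision. `n_trials = 0` produces a valid empty run.

## Known limitations

Self-esteem here is domain-general: the ideal-image factors are labels, not
calibrated constructs, and nothing is fitted to human measurements. The
niche is single-agent and scripted; multi-agent interaction is out of scope.
The trait level's observation alphabet is a hand-chosen discretization, and
several magnitudes (preference values, drift rates, $\omega$ spacing) are
model choices a different analyst could reasonably set otherwise — the
experiments' direction checks, not those magnitudes, are the claims.
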