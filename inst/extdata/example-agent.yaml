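# Example hierarchical-agent configuration (all sections optional; omitted
# fields take the package defaults). Load with read_agent_config().
state_level:
  collapse_ideal: true
  self_image_levels: 3
trait_level:
  slow_horizon: 10
  diag_dominance: 0.6
trait_link:
  omega: {low: 0.3, medium: 1.0, high: 3.0}
  gamma0: {low: 1.0, medium: 1.0, high: 1.0}
learning:
  rate: 1.0
  scale_a: 10
  scale_b: 20
agent:
  noise: 0.9
  initial_trait: medium
niche:
  scenario: favorable
  overrides:
    kappa: 0.8
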