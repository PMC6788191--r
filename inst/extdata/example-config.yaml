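# Example run configuration: the high-prevention-cost study under the
# proportional liability rule.
cc: 10      # school prevention cost
cs: 6       # student/guardian prevention cost
p: 5        # total accident loss
a: 0.5      # school's share of the loss when neither side is cautious
b: 0.5      # student prevention-cost share borne by the school
rule: parametric
integration:
  t_max: 500
sweep:
  resolution: 11
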