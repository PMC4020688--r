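# Zero-inflated Poisson scenario: GM plant, comparator and a population of
# three reference varieties compared in a randomized block design with two
# blocks. Count effects are on the log scale, structural-zero effects on
# the logit scale; reference-variety effects are drawn from normal
# distributions with the stated means and variances.
distribution:
  family: poisson
  delta: 0.0
design:
  layout: rcb
  n_replicates: 2
  block_var_count: 0.1
  block_var_zero: 0.01
varieties:
  - name: gm
    role: gm
    effect: 0.4
    zero_effect: -0.3
  - name: comparator
    role: comparator
    effect: 0.5
    zero_effect: -0.2
  - name: references
    role: reference
    n_reference: 3
    effect: 1.0
    effect_var: 1.0
    zero_effect: -0.8
    zero_effect_var: 0.5
trials:
  kind: single
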