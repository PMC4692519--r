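# Declarative prior rule table: per modality, a list of mixture components.
# String values of a/b name regions whose pooled median intensity (computed
# from training data inside atlas-style masks) is substituted at setup time;
# numeric values are used directly. beta_rel scales the prior covariance:
# the expected profile SD is beta_rel * |b - a|.
modalities:
  t1w:
    - function: step
      a: inside
      b: outside
      beta_rel: 0.2
    - function: exponential
      a: inside
      b: neighbour
      v_mm: 1.5
      beta_rel: 0.2
  t2w:
    - function: step
      a: inside
      b: outside
      beta_rel: 0.2
    - function: exponential
      a: inside
      b: neighbour
      v_mm: 1.5
      beta_rel: 0.2
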