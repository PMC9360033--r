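# Base stratum of the proposed 3-tier risk score for each molecular class,
# before FLT3-ITD shift rules are applied. KMT2A_t11x defaults to
# intermediate_p (override here if a local policy differs).
proposed_base:
  APL_t15_17: favorable_p
  inv16: favorable_p
  t8_21: favorable_p
  biCEBPA: favorable_p
  NPM1: favorable_p
  no_events: favorable_p
  sAML1: intermediate_p
  trisomies: intermediate_p
  WT1: intermediate_p
  DNMT3A_IDH: intermediate_p
  t6_9: intermediate_p
  mNOS: intermediate_p
  KMT2A_t11x: intermediate_p
  sAML2: adverse_p
  TP53_complex: adverse_p
  inv3: adverse_p
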