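# Default hierarchy for AML class assignment: rules are evaluated in order
# and the first match wins. Established WHO entities come first, then
# TP53/complex-karyotype, trisomies, the secondary-AML-like rules (sAML2
# before biCEBPA), NPM1, sAML1, DNMT3A/IDH, WT1, and the two catch-all
# classes mNOS / no_events, which must be the final two entries.
hierarchy:
  - APL_t15_17
  - inv16
  - t8_21
  - KMT2A_t11x
  - t6_9
  - inv3
  - TP53_complex
  - trisomies
  - sAML2
  - biCEBPA
  - NPM1
  - sAML1
  - DNMT3A_IDH
  - WT1
  - mNOS
  - no_events
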