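motifs:
- name: ETAS1
  pattern: TACATATTATGTATWATYGTGCAT
  max_mismatches: 4
- name: ETAS2
  pattern: ACATAGTACATWAWATCATGCWTA
  max_mismatches: 4
- name: BoxC
  pattern: TGGCATCTGGTTCTTAYTTCAGG
  max_mismatches: 4
- name: BoxD
  pattern: TCTCACGAGAAATCAGCAACCC
  max_mismatches: 4
- name: BoxF
  pattern: GTACATAGCACATTWCAGTCAA
  max_mismatches: 4
- name: CSB1
  pattern: TTAATGCTTGTAGGACATAATA
  max_mismatches: 4
- name: CSB2
  pattern: AAACCCCCCCTCCCCC
  max_mismatches: 3
- name: CSB3
  pattern: TGCCAAACCCCAAAAACAAGAC
  max_mismatches: 4
tandem:
  min_period: 10.0
  max_period: 200.0
  min_copies: 3.0
  min_identity: 0.85
at:
  min_len: 20.0
  min_copies: 3.0
  max_impurity: 0.0
domains:
  fallback:
  - 0.3333333
  - 0.6666667
  on_disorder: flag
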