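# STO-3G contracted Gaussian basis (s,p shells only).
# Format: "element <symbol>" then "shell <S|P|SP> <nprim>" followed by nprim
# lines of exponent + contraction coefficient(s); SP lines carry s then p
# coefficients. Exponents in bohr^-2, descending.
element H
shell S 3
  3.42525091   0.15432897
  0.62391373   0.53532814
  0.16885540   0.44463454
element C
shell S 3
  71.61683735  0.15432897
  13.04509632  0.53532814
  3.53051216   0.44463454
shell SP 3
  2.94124936  -0.09996723  0.15591627
  0.68348310   0.39951283  0.60768372
  0.22228992   0.70011547  0.39195739
element N
shell S 3
  99.10616896  0.15432897
  18.05231239  0.53532814
  4.88566024   0.44463454
shell SP 3
  3.78045588  -0.09996723  0.15591627
  0.87849664   0.39951283  0.60768372
  0.28571437   0.70011547  0.39195739
element O
shell S 3
  130.70932000  0.15432897
  23.80886610   0.53532814
  6.44360831    0.44463454
shell SP 3
  5.03315132  -0.09996723  0.15591627
  1.16959612   0.39951283  0.60768372
  0.38038900   0.70011547  0.39195739
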