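# STO-6G contracted Gaussian basis for hydrogen (zeta = 1.24 scaled 1s).
element H
shell S 6
  35.52322122   0.00916359628
  6.513143725   0.04936149294
  1.822142904   0.16853830490
  0.625955266   0.37056279970
  0.243076747   0.41649152980
  0.100112428   0.13033408410
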