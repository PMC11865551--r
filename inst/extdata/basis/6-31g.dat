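# 6-31G split-valence basis (s,p shells).
element H
shell S 3
  18.73113696   0.03349460434
  2.825394365   0.2347269535
  0.6401216923  0.8137573261
shell S 1
  0.1612777588  1.0
element C
shell S 6
  3047.524880   0.001834737132
  457.3695180   0.01403732281
  103.9486850   0.06884262226
  29.21015530   0.2321844432
  9.286662960   0.4679413484
  3.163926960   0.3623119853
shell SP 3
  7.868272350  -0.1193324198  0.06899906659
  1.881288540  -0.1608541517  0.3164239610
  0.5442492580  1.143456438   0.7443082909
shell SP 1
  0.1687144782  1.0  1.0
element N
shell S 6
  4173.511460   0.001834772160
  627.4579110   0.01399462700
  142.9020930   0.06858655181
  40.23432930   0.2322408730
  13.18126350   0.4690699481
  4.707006060   0.3604551991
shell SP 3
  11.86242430  -0.1149611817  0.06757974388
  2.771433980  -0.1691174786  0.3239072959
  0.7278103310  1.145851947   0.7408951398
shell SP 1
  0.2120314975  1.0  1.0
element O
shell S 6
  5484.671660   0.001831074430
  825.2349460   0.01395017220
  188.0469580   0.06844507810
  52.96450000   0.2327143360
  16.89757040   0.4701928980
  5.799635340   0.3585208530
shell SP 3
  15.53961625  -0.1107775495  0.07087426823
  3.599933586  -0.1480262627  0.3397528391
  1.013761750   1.130767015   0.7271585773
shell SP 1
  0.2700058226  1.0  1.0
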