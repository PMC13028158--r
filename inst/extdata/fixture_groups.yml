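# Isomer/adduct groups for equilibrium speciation.
# Minimal YAML subset: "label:" blocks with inline member/exchange lists.
glycolaldehyde_adducts:
  members: [6, 7, 8]
  exchange: [H2O]
trioses:
  members: [16, 17, 18, 19]
  exchange: [H2O, H2SO3]
c4_ketose_adducts:
  members: [20, 23, 24, 25]
  exchange: [H2O, H2SO3]
tetrose_adducts:
  members: [26thr, 26ery, 27thr, 28thr, 29thr, 29ery]
  exchange: [H2O, H2SO3]
pent_24_pyranoses:
  members: [31rib, 31ara, 31xyl, 31lyx]
  exchange: [H2O]
pent_25_furanoses:
  members: [33rib, 33ara, 33xyl, 33lyx]
  exchange: [H2O]
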