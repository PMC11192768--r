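# Reference staining protocol: three inlets loaded, 20 min incubation.
#   2 uL E. coli suspension in 1X PBS, 2 uL 1X SYBR Gold, 5 uL 1X PBS.
inlet_loads:
  - reservoir: R1
    reagent: ecoli_pbs
    volume_ul: 2
  - reservoir: R2
    reagent: sybr_gold
    volume_ul: 2
  - reservoir: R3
    reagent: pbs
    volume_ul: 5
incubation_ms: 1200000
script: staining.loc
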