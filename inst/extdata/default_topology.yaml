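# Default chip topology: 15 lifting-gate valves, 6 reservoirs.
# Serial mixing chain, a schematic stand-in for the published device:
#   R1,R2,R3 (inlets) -> V1,V2,V3 (inlet valves) -> V4 (junction)
#   V4,V5,V6 central mixing valves
#   V7..V13 transport chain -> V14 detection valve -> V15 output valve
#   R4,R5,R6 (outlets) at V15
n_valves: 15
detection_node: V14
valve_capacity_nl: 10
reservoirs:
  R1: INLET
  R2: INLET
  R3: INLET
  R4: OUTLET
  R5: OUTLET
  R6: OUTLET
edges:
  - [R1, V1]
  - [R2, V2]
  - [R3, V3]
  - [V1, V4]
  - [V2, V4]
  - [V3, V4]
  - [V4, V5]
  - [V5, V6]
  - [V6, V7]
  - [V7, V8]
  - [V8, V9]
  - [V9, V10]
  - [V10, V11]
  - [V11, V12]
  - [V12, V13]
  - [V13, V14]
  - [V14, V15]
  - [V15, R4]
  - [V15, R5]
  - [V15, R6]
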