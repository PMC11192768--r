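# Post-experiment device wash: flushes PBS buffer (R3) through the mixing
# and transport valves and expels it to the outlet reservoirs at V15.

main:
  call flush
  call flush
end

def flush:
  o 3
  w 100
  o 4
  w 100
  c 3
  w 100
  o 5
  w 100
  c 4
  w 100
  o 6
  w 100
  c 5
  w 100
  o 7
  w 100
  c 6
  w 100
  o 8
  w 100
  c 7
  w 100
  o 9
  w 100
  c 8
  w 100
  o 10
  w 100
  c 9
  w 100
  o 11
  w 100
  c 10
  w 100
  o 12
  w 100
  c 11
  w 100
  o 13
  w 100
  c 12
  w 100
  o 14
  w 100
  c 13
  w 100
  o 15
  w 100
  c 14
  w 100
  c 15
  w 100
end
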