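# Reference E. coli staining protocol.
# Draws bacteria suspension (R1), SYBR Gold dye (R2) and PBS buffer (R3)
# into the central mixing valves, homogenizes by rotating the parcel through
# V4-V5-V6, incubates 20 min, then carries the stained sample to the
# detection valve (V14) where the excitation waveguide crosses the channel.

main:
  call load_bacteria
  call load_dye
  call load_buffer
  call mix
  call mix
  call incubate
  call to_detection
end

def load_bacteria:
  o 1
  w 100
  o 4
  w 100
  c 1
  w 100
end

def load_dye:
  o 2
  w 100
  o 4
  w 100
  c 2
  w 100
end

def load_buffer:
  o 3
  w 100
  o 4
  w 100
  c 3
  w 100
end

# rotate the pooled parcel V4 -> V5 -> V6 -> V5 -> V4
def mix:
  o 5
  w 100
  c 4
  w 100
  o 6
  w 100
  c 5
  w 100
  o 5
  w 100
  c 6
  w 100
  o 4
  w 100
  c 5
  w 100
end

# SYBR Gold standard staining: 20 min in the central mixing valves
def incubate:
  w 1200000
end

# peristaltic hand-off along the transport chain to the detection valve
def to_detection:
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
end
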