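geometry_id: rro12
char_bit_count: 3
pos_bit_count: 3
pitch: 20.0
sites:
- x: -30.0
  'y': 20.0
  z: 0.0
  role: marker_filled
  logical_bit: ~
- x: -10.0
  'y': 20.0
  z: 0.0
  role: marker_empty
  logical_bit: ~
- x: 10.0
  'y': 20.0
  z: 0.0
  role: marker_empty
  logical_bit: ~
- x: 30.0
  'y': 20.0
  z: 0.0
  role: marker_filled
  logical_bit: ~
- x: -30.0
  'y': 0.0
  z: 0.0
  role: char_bit
  logical_bit: 1
- x: -10.0
  'y': 0.0
  z: 0.0
  role: char_bit
  logical_bit: 2
- x: 10.0
  'y': 0.0
  z: 0.0
  role: char_bit
  logical_bit: 3
- x: 30.0
  'y': 0.0
  z: 0.0
  role: marker_empty
  logical_bit: ~
- x: -30.0
  'y': -20.0
  z: 0.0
  role: pos_bit
  logical_bit: 4
- x: -10.0
  'y': -20.0
  z: 0.0
  role: pos_bit
  logical_bit: 5
- x: 10.0
  'y': -20.0
  z: 0.0
  role: pos_bit
  logical_bit: 6
- x: 30.0
  'y': -20.0
  z: 0.0
  role: marker_empty
  logical_bit: ~
character_map:
  bits_per_char: 3
  chars:
  - '@'
  - A
  - F
  - 'N'
  - S
  - U
  - E
  - T
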