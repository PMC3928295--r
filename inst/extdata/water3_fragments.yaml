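fragments:
- atoms:
  - 0
  - 3
  charge: 0
  domain: A
- atoms:
  - 3
  - 6
  charge: 0
  domain: A
- atoms:
  - 6
  - 9
  charge: 0
  domain: A
high_level: 0
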