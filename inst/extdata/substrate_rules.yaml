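# Substrate-compatibility rule table (editable). Each substrate carries one
# or more alternative condition groups; a fingerprint is `compatible` when
# any group reaches its weight threshold, `incompatible` when any disallowed
# symbol is present, and `unknown` otherwise. Positions are reference
# numbering; the hints encode the B-ring pocket observations at positions
# 79, 87/47 and 125.
substrates:
  - id: "1a"
    name: "naringenin chalcone (para-hydroxy B-ring)"
    groups:
      - threshold: 2
        conditions:
          - {position: 79, allowed: [D], weight: 1}
          - {position: 125, allowed: [R], weight: 1}
          - {position: 87, allowed: [K, R], weight: 1}
    disallowed: []
  - id: "2a"
    name: "eriodictyol chalcone (meta,para-dihydroxy B-ring)"
    groups:
      - threshold: 2
        conditions:
          - {position: 87, allowed: [K, R], weight: 1}
          - {position: 47, allowed: [D, E], weight: 1}
    disallowed: []
  - id: "4a"
    name: "hesperetin chalcone (para-methoxy B-ring)"
    groups:
      - threshold: 1
        conditions:
          - {position: 79, allowed: [P, I], weight: 1}
      - threshold: 2
        conditions:
          - {position: 79, allowed: [E], weight: 1}
          - {position: 125, allowed: [G], weight: 1}
    disallowed:
      - {position: 79, symbols: [D]}
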