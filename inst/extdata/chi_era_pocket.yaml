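# Active-pocket annotation for the bundled CHI_era reference profile.
# Positions are 1-based reference numbering. The named 20 positions plus
# position 47 (provisional: implicated via mutagenesis only) give the
# 21-residue substrate-binding pocket.
ref_id: CHI_era
catalytic:
  - {position: 33, residue: H, role: catalytic base}
  - {position: 48, residue: "Y", role: carbonyl stabilization}
pocket:
  - {position: 12,  residue: I, role: A-ring}
  - {position: 14,  residue: V, role: A-ring}
  - {position: 29,  residue: I, role: A-ring}
  - {position: 33,  residue: H, role: catalytic}
  - {position: 37,  residue: S, role: B-ring}
  - {position: 40,  residue: Q, role: B-ring}
  - {position: 41,  residue: F, role: B-ring}
  - {position: 47,  residue: D, role: B-ring, provisional: true}
  - {position: 48,  residue: "Y", role: catalytic}
  - {position: 50,  residue: F, role: A-ring}
  - {position: 69,  residue: E, role: A-ring}
  - {position: 71,  residue: T, role: A-ring}
  - {position: 73,  residue: H, role: B-ring}
  - {position: 75,  residue: W, role: B-ring}
  - {position: 79,  residue: D, role: B-ring}
  - {position: 87,  residue: K, role: B-ring}
  - {position: 91,  residue: E, role: B-ring}
  - {position: 101, residue: Q, role: A-ring}
  - {position: 122, residue: "N", role: B-ring}
  - {position: 125, residue: R, role: B-ring}
  - {position: 135, residue: F, role: A-ring}
domains:
  - {label: catalytic, start: 1, end: 140}
  - {label: solvent_exposed, start: 141, end: 210}
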