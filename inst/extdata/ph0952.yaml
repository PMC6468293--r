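# Analysis configuration for the PH0952 resting-form structure (PDB 6MFV).
#
# Domain boundaries are author-numbered residue ranges on chain A (the four
# asymmetric-unit copies are conformationally identical; superpositions are
# computed over all chains regardless).
#
# Helix tables: the arm (three TPR-like hairpins, helices a15-a20) and the
# TPR sensor (six repeats, helices a21-a32; the C-terminal capping helix is
# not part of the repeat stack and is omitted). Helix endpoints are
# ANNOTATION DATA, not code: the values below are approximate placements
# within the published domain boundaries and should be replaced by curated
# endpoints (e.g. from DSSP on the deposited model) before quantitative use.

domains:
  - {name: NBD,    chain: A, start: 102, end: 262}
  - {name: HD,     chain: A, start: 263, end: 316}
  - {name: WHD,    chain: A, start: 317, end: 393}
  - {name: arm,    chain: A, start: 394, end: 496}
  - {name: sensor, chain: A, start: 497, end: 748}

interfaces:
  - "NBD:WHD"
  - "NBD:arm"
  - "NBD:sensor"

ligand:
  resid: ADP
  chain: A
  cutoff: 4.0

probe: 1.4
n_points: 960

solenoids:
  - name: arm
    helices:
      - {chain: A, start: 398, end: 412, face: A}   # a15
      - {chain: A, start: 416, end: 430, face: B}   # a16
      - {chain: A, start: 434, end: 448, face: A}   # a17
      - {chain: A, start: 452, end: 465, face: B}   # a18
      - {chain: A, start: 469, end: 482, face: A}   # a19
      - {chain: A, start: 486, end: 496, face: B}   # a20
  - name: sensor
    helices:
      - {chain: A, start: 500, end: 512, face: A}   # a21
      - {chain: A, start: 516, end: 529, face: B}   # a22
      - {chain: A, start: 534, end: 546, face: A}   # a23
      - {chain: A, start: 550, end: 563, face: B}   # a24
      - {chain: A, start: 568, end: 580, face: A}   # a25
      - {chain: A, start: 584, end: 597, face: B}   # a26
      - {chain: A, start: 602, end: 614, face: A}   # a27
      - {chain: A, start: 618, end: 631, face: B}   # a28
      - {chain: A, start: 636, end: 648, face: A}   # a29
      - {chain: A, start: 652, end: 665, face: B}   # a30
      - {chain: A, start: 670, end: 682, face: A}   # a31
      - {chain: A, start: 686, end: 699, face: B}   # a32
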