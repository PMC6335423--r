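# Domain architecture config consumed by readDomainConfig().
# Coordinates are 1-based inclusive residue indices in the stated
# isoform numbering frame.  The PPARG LBD span matches the commonly
# used 231-505 LBD construct (gamma-2 numbering); A/B and DBD bounds
# follow standard nuclear-receptor annotation and may be overridden.
- gene: PPARG
  isoform: PPARG2
  protein_length: 505
  domains:
    - {name: "A/B", start: 1, end: 135}
    - {name: "DBD", start: 136, end: 206}
    - {name: "LBD", start: 231, end: 505}
  landmarks:
    - {name: "S112", position: 112}
    - {name: "S273", position: 273}
- gene: RXRA
  isoform: RXRA
  protein_length: 462
  domains:
    - {name: "A/B", start: 1, end: 134}
    - {name: "DBD", start: 135, end: 200}
    - {name: "LBD", start: 225, end: 462}
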