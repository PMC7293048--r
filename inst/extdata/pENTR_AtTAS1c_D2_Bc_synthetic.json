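{
  "mir173_start": 150,
  "endogenous_slots": {
    "2": "CGAGAGGTGAAGGTAGGCTCA",
    "3": "CGGGCCTGTCACGAGTTTTTG",
    "4": "TCGGCTCTCGGTTGAGACGGA",
    "5": "CGAACAACAACCCTGTTGATA"
  },
  "mir173_cassette": false,
  "note": "synthetic stand-in for the pENTR-AtTAS1c-D2-B/c vector: same layout, BsaI chemistry and 1461-bp released cassette; not the real plasmid sequence"
}
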