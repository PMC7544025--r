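# Catalytic triad of the SABP2 methylesterase (alpha/beta hydrolase fold),
# numbered on the tobacco NtSABP2 reference protein.
name: catalytic_triad
reference: NtSABP2
kind: catalytic_triad
residues:
  - {pos: 81, aa: S}
  - {pos: 210, aa: D}
  - {pos: 238, aa: H}
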