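# Cis-element consensus dictionary (editable).
# Published consensus strings in IUPAC nucleotide code; no claim of
# equivalence with any proprietary database's internal definitions.
motifs:
  - name: TATA-box
    consensus: TATAWAW
  - name: CAAT-box
    consensus: CCAAT
  - name: ABRE
    consensus: ACGTG
  - name: G-Box
    consensus: CACGTG
  - name: Box4
    consensus: ATTAAT
  - name: GATA-motif
    consensus: WGATAR
  - name: TGA-element
    consensus: AACGAC
  - name: AuxRR-core
    consensus: GGTCCAT
  - name: Sp1
    consensus: GGGCGG
  - name: circadian
    consensus: CAANNNNATC
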