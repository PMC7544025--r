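# Default species -> MeSA production group assignment for Betula.
high: [ale, len, bg, med]
low: [pen, uti, nan, aln]
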