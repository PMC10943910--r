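>pep34 34-aa homeodomain-derived amalgam peptide (AAEK + 30-mer core)
AAEKEFIKYPYPTPLQYQQLATRLKVEKKLVRRW
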