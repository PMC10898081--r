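>SPINK1_region_synthetic c.1..c.55+160 (synthetic stand-in)
ATGAAGGTAACAGGCGCTGCTGCTCTGAGCGCTTTGGCACTGTTGGCTGCTGCAGGTAAGACTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCTCCTCCAGGTAAGATCCTCTCCTCTCCT
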