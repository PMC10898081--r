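# Assay-candidate selection rules for the SPINK1 screen.
# Boundaries: all 3 SNVs at each internal exon start/end; score rule at the
# conventional 0.20 cutoff on relevance-filtered scores; top-3 donor-gain
# variants in exon 1; c.9 triple as negative controls; judgment-based
# companions at c.43 and c.84.
include_exon_boundaries true
score_cutoff 0.20
top_k_gain_per_exon 1:3
control_positions 9
extra_variants c.43T>A,c.43T>C,c.84A>C,c.84A>T
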