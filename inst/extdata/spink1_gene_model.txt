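# SPINK1 (NM_001379610.1 structure), hg19 chr5 anchors, reverse strand.
# exon <index> <cds_start> <cds_end> <genomic_start> <genomic_end>
name	SPINK1
chrom	chr5
strand	-
exon	1	1	55	147211086	147211140
exon	2	56	87	147209162	147209193
exon	3	88	194	147207585	147207691
exon	4	195	240	147204224	147204269
# splice sites used by any of the documented transcript isoforms
donor	c.55
donor	c.87
donor	c.194
acceptor	c.56
acceptor	c.88
acceptor	c.195
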