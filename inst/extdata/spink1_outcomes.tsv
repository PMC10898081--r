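variant	species	class	ratio_text
c.9A>C	normal:1.00	normal_only
c.9A>G	normal:1.00	normal_only
c.9A>T	normal:1.00	normal_only
c.11C>G	normal:1.00;retI1+140:0.05	normal_only
c.15C>T	normal:1.00	normal_only
c.26T>G	normal:1.00	normal_only
c.29G>A	normal:1.00	normal_only
c.36G>C	normal:1.00	normal_only
c.41T>C	normal:1.00	normal_only
c.41T>G	normal:1.00	normal_only
c.43T>A	normal:1.00	normal_only
c.43T>C	normal:1.00	normal_only
c.43T>G	normal:1.00	normal_only
c.55G>A	normal:9.03;retI1+140:1.00!	mixed	1/9.03
c.55G>C	normal:21.72;retI1+140:1.00!	mixed	1/21.72
c.55G>T	normal:9.38;retI1+140:1.00!	mixed	1/9.38
c.56G>A	normal:1.00	normal_only
c.56G>C	normal:1.32;skipE2:1.00!	mixed	1/1.32
c.56G>T	normal:1.00;skipE2:2.97	mixed	2.97/1
c.65G>T	normal:5.16;skipE2:1.00!	mixed	1/5.16
c.75C>T	normal:1.00	normal_only
c.80G>T	normal:1.00	normal_only
c.84A>C	normal:1.00	normal_only
c.84A>G	normal:1.00;skipE2:10.80	mixed	10.80/1
c.84A>T	normal:1.00	normal_only
c.85G>T	normal:1.00	normal_only
c.86A>C	normal:1.00	normal_only
c.86A>G	normal:1.00;skipE2:4.13	mixed	4.13/1
c.86A>T	normal:5.31;skipE2:1.00	mixed	1/5.31
c.87G>A	skipE2:1.00	aberrant_only
c.87G>C	skipE2:1.00	aberrant_only
c.87G>T	skipE2:1.00	aberrant_only
c.88G>A	normal:1.00	normal_only
c.88G>C	normal:1.00	normal_only
c.88G>T	normal:1.00	normal_only
c.101A>G	normal:1.00	normal_only
c.110A>G	normal:1.00	normal_only
c.123G>C	normal:1.00	normal_only
c.126A>G	normal:1.00	normal_only
c.133C>T	normal:1.00	normal_only
c.137T>A	normal:1.00	normal_only
c.143G>A	normal:1.00	normal_only
c.150T>G	normal:1.00	normal_only
c.160T>C	normal:1.00	normal_only
c.163C>T	normal:1.00	normal_only
c.174C>T	normal:1.00	normal_only
c.178T>G	normal:1.00	normal_only
c.190A>G	normal:1.00	normal_only
c.193C>T	normal:1.00	normal_only
c.194G>A	normal:1.00	normal_only
c.194G>C	normal:1.00	normal_only
c.194G>T	normal:1.00	normal_only
c.195G>A	normal:1.00	normal_only
c.195G>C	normal:1.00	normal_only
c.195G>T	normal:1.00	normal_only
c.198A>C	normal:1.00	normal_only
c.199C>T	normal:1.00	normal_only
c.200G>A	normal:1.00	normal_only
c.203A>G	normal:1.00	normal_only
c.206C>T	normal:1.00	normal_only
c.231G>A	normal:1.00	normal_only
c.236G>T	normal:1.00	normal_only
c.29G>T	normal:1.00	normal_only
c.37G>T	normal:1.00	normal_only
c.64G>T	normal:1.00	normal_only
c.81A>T	normal:1.00	normal_only
c.92A>G	normal:1.00	normal_only
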