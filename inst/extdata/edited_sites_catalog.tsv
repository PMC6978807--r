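mature_id	position	substitution	extent
mmu-miR-411-5p	5	A>G	heavy
mmu-miR-376b-3p	6	A>G	heavy
mmu-miR-3099-3p	7	A>G	heavy
mmu-miR-381-3p	7	A>G	slight
mmu-miR-421-3p	14	A>G	slight
mmu-miR-378a-3p	16	A>G	heavy
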