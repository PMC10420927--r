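ligand_type	count	baseline_count
III	92	81
IV	91	81
V	15	15
VI	13	10
activator	20	19
multi_site	31	26
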