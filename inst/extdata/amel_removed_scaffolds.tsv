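scaffold_id	length_bp	associated_chromosome
NW_020555794.1	40528	8
NW_020555815.1	67913	10
NW_020555816.1	40431	10
NW_020555860	311923	16
NW_020555824.1	13259	11
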