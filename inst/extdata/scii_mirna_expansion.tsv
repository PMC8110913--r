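precursor	mature
rno-miR-323	rno-miR-323-3p
rno-miR-323	rno-miR-323-5p
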