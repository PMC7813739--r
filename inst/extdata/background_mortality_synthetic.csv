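age,annual_death_probability
32,0.0007
33,0.0007
34,0.0007
35,0.0007
36,0.0007
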