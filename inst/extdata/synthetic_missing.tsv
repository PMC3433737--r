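name	richness
t25	9
t4	47
t2	236907
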