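>query
orf00001      101      403  +2     8.24
orf00002      712      500  -2     5.31
orf00003      950     1276  +1    11.02
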