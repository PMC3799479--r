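x1	GO:0000004
y1	GO:0000004
x2	GO:0000004
y2	GO:0000005
x3	GO:0000006
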